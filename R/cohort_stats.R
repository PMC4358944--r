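#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into the K^2 omnibus statistic,
#' K^2 = Z(b1)^2 + Z(b2)^2, referred to a chi-squared distribution with 2
#' degrees of freedom. The normal approximations underlying the Z
#' transforms are unreliable below n = 8, so smaller samples are rejected.
#'
#' @param values numeric sample, n >= 8, non-constant.
#' @return An object of class \code{vq_test} with the K^2 statistic, df = 2,
#'   p-value and the two component Z scores.
#' @export
dagostino_pearson <- function(values) {
  x <- as.numeric(values[is.finite(values)])
  n <- length(x)
  if (n < 8L)
    stop_vq("n = %d too small: the K^2 approximation requires n >= 8", n)
  if (pop_sd(x) == 0) stop_vq("zero variance: normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # Z for skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # Z for kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  vq_test("D'Agostino-Pearson omnibus normality test",
          statistic = c(K2 = k2), df = 2,
          p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
          extra = list(z_skewness = z1, z_kurtosis = z2, n = n))
}

#' Kruskal-Wallis H test across groups
#'
#' Rank-based omnibus comparison of two or more independent groups, with
#' the tie-corrected H statistic referred to chi-squared with k - 1 df.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length as \code{values}.
#' @return a \code{vq_test} with H, df and p-value.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  check_groups(values, g, min_groups = 2L, min_total = 3L)
  if (length(unique(values)) == 1L)
    stop_vq("all values identical: H undefined (no variation)")
  kt <- stats::kruskal.test(values, g)
  vq_test("Kruskal-Wallis H test",
          statistic = c(H = unname(kt$statistic)),
          df = unname(kt$parameter), p.value = kt$p.value,
          extra = list(n_groups = nlevels(g), n = length(values)))
}

#' Dunn's multiple-comparison post test
#'
#' Pairwise rank comparisons following a Kruskal-Wallis test. For groups i
#' and j the statistic is
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - T\right)
#'          \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with mean ranks over the pooled sample and tie term
#' \eqn{T = \sum_t (t^3 - t) / (12 (N - 1))}. Two-sided p-values are
#' Bonferroni-corrected over all pairwise comparisons (capped at 1), the
#' convention of common biostatistics software; \code{adjust = "none"}
#' returns raw p-values.
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param adjust "bonferroni" (default) or "none".
#' @return data frame with one row per group pair: \code{group1},
#'   \code{group2}, mean ranks, \code{z}, \code{p.value} and
#'   \code{p.adjusted}.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  g <- factor(groups)
  check_groups(values, g, min_groups = 2L, min_total = 3L)
  n_tot <- length(values)
  rk <- rank(values)
  mean_ranks <- tapply(rk, g, mean)
  n_g <- tabulate(g)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  pairs <- utils::combn(nlevels(g), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / n_g[i] + 1 / n_g[j]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = levels(g)[i], group2 = levels(g)[j],
               mean_rank_1 = mean_ranks[[i]], mean_rank_2 = mean_ranks[[j]],
               z = z, p.value = p)
  })
  out <- do.call(rbind, rows)
  out$p.adjusted <- if (adjust == "bonferroni") pmin(1, out$p.value * m)
                    else out$p.value
  rownames(out) <- NULL
  out
}

#' Two-group pooled-variance t test
#'
#' Classical two-sided Student's t test with pooled variance,
#' df = n_a + n_b - 2; used for the two-group isoform-abundance
#' comparisons.
#'
#' @param values_a,values_b numeric samples, each n >= 2.
#' @return a \code{vq_test} with t, df and p-value.
#' @export
two_group_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_vq("each group needs n >= 2")
  pooled_var <- (sum((values_a - mean(values_a))^2) +
                   sum((values_b - mean(values_b))^2)) /
    (length(values_a) + length(values_b) - 2)
  if (pooled_var == 0) stop_vq("zero pooled variance: t undefined")
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  vq_test("Two-sample pooled t test",
          statistic = c(t = unname(tt$statistic)),
          df = unname(tt$parameter), p.value = tt$p.value,
          extra = list(mean_a = mean(values_a), mean_b = mean(values_b)))
}

#' Median and interquartile range
#'
#' The summary format used throughout the cohort tables: median with
#' (Q1, Q3) computed by the linear-interpolation quartile rule
#' (\code{quantile} type 7).
#'
#' @param values numeric sample, n >= 1.
#' @return named numeric vector \code{median}, \code{q1}, \code{q3}.
#' @export
summarize_iqr <- function(values) {
  if (length(values) < 1L) stop_vq("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

vq_test <- function(method, statistic, df, p.value, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p.value = p.value), extra),
            class = "vq_test")
}

#' @export
print.vq_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s = %.4f, df = %s, p = %.4g\n",
              names(x$statistic)[1], x$statistic[1],
              format(x$df), x$p.value))
  invisible(x)
}

check_groups <- function(values, g, min_groups, min_total) {
  if (length(values) != length(g))
    stop_vq("values and groups differ in length")
  if (any(tabulate(g) == 0L) || nlevels(g) < min_groups)
    stop_vq("need at least %d non-empty groups", min_groups)
  if (length(values) < min_total)
    stop_vq("need at least %d observations in total", min_total)
  if (any(!is.finite(values))) stop_vq("non-finite values in input")
  invisible(TRUE)
}
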