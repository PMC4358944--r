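# Independent reference implementations used as oracles. These are written
# as plain loops over voxels/ranks, deliberately sharing no code with the
# package internals.

# Pearson and Manders coefficients by explicit voxel loops.
naive_coloc <- function(g, r, thr_g, thr_r) {
  g <- as.numeric(g); r <- as.numeric(r)
  n <- length(g)
  ga <- sum(g) / n
  ra <- sum(r) / n
  num <- 0; den_g <- 0; den_r <- 0
  g_tot <- 0; r_tot <- 0; g_col <- 0; r_col <- 0
  for (i in seq_len(n)) {
    num <- num + (g[i] - ga) * (r[i] - ra)
    den_g <- den_g + (g[i] - ga)^2
    den_r <- den_r + (r[i] - ra)^2
    if (g[i] > thr_g) {
      g_tot <- g_tot + g[i]
      if (r[i] > thr_r) g_col <- g_col + g[i]
    }
    if (r[i] > thr_r) {
      r_tot <- r_tot + r[i]
      if (g[i] > thr_g) r_col <- r_col + r[i]
    }
  }
  list(R_p = num / sqrt(den_g * den_r),
       M_G = g_col / g_tot, M_R = r_col / r_tot)
}

# Threshold rule by explicit loops (population SD, strict >).
naive_threshold <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  m <- sum(v) / n
  s2 <- 0
  for (x in v) s2 <- s2 + (x - m)^2
  thr <- m + 2 * sqrt(s2 / n)
  cnt <- 0; tot <- 0
  for (x in v) if (x > thr) { cnt <- cnt + 1; tot <- tot + x }
  list(threshold = thr, n_above = cnt, intensity_sum_above = tot)
}

# Kruskal-Wallis H with tie correction, from the textbook definition.
naive_kw_h <- function(values, groups) {
  rk <- rank(values)
  n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- rk[groups == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Pooled two-sample t from first principles.
naive_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Tiny random dual-channel stack for oracle comparisons.
random_small_stack <- function(max_side = 10L) {
  d <- c(sample(2:max_side, 1), sample(2:max_side, 1), sample(2:max_side, 1))
  g <- array(sample(0:255, prod(d), replace = TRUE), d)
  r <- array(sample(0:255, prod(d), replace = TRUE), d)
  dual_channel_stack(g, r)
}

pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))
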