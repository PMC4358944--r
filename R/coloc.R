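#' Pearson's colocalization coefficient
#'
#' Computes Pearson's correlation R_p between the green and red voxel
#' intensities of a dual-channel stack,
#' \deqn{R_p = \frac{\sum_i (G_i - G_A)(R_i - R_A)}
#'                  {\sqrt{\sum_i (G_i - G_A)^2 \sum_i (R_i - R_A)^2}},}
#' over all voxels in the (optional) ROI, with no thresholding: R_p is
#' invariant to detector gain and offset, so background subtraction is not
#' applied. A value of 1 indicates complete overlap of the two signals and
#' 0 random placement; R_p is, however, sensitive to image noise.
#'
#' @param stack a \code{\link{dual_channel_stack}}.
#' @param roi optional logical mask (same shape as each channel).
#' @return R_p as a single number in [-1, 1].
#' @export
pearson_coloc <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "dual_channel_stack"))
  g <- as.numeric(roi_values(stack$green, roi))
  r <- as.numeric(roi_values(stack$red, roi))
  if (length(g) < 2L) stop_vq("need at least 2 voxels to correlate")
  if (pop_sd(g) == 0 || pop_sd(r) == 0)
    stop_vq("undefined correlation: constant channel intensity")
  stats::cor(g, r)
}

#' Manders' colocalization coefficients
#'
#' M_G (alias M_x) is the fraction of total green intensity residing in
#' voxels whose red partner exceeds the red threshold, and symmetrically
#' M_R (alias M_y) for red:
#' \deqn{M_G = \sum G_{colocalized} / \sum G_i, \quad
#'       M_R = \sum R_{colocalized} / \sum R_i,}
#' where the sums run over above-threshold voxels of the respective channel
#' within the ROI. Thresholds normally come from
#' \code{\link{background_threshold}}. Both coefficients lie in [0, 1] and
#' are invariant to detector gain when thresholds are co-scaled, but are
#' affected by offset and noise.
#'
#' @param stack a \code{\link{dual_channel_stack}}.
#' @param threshold_green,threshold_red intensity cutoffs (strictly above).
#' @param roi optional logical mask.
#' @return list with \code{M_G}, \code{M_R}, the colocalized intensity sums
#'   \code{G_colocalized}, \code{R_colocalized} and the above-threshold
#'   totals \code{G_total}, \code{R_total}.
#' @export
manders_coeffs <- function(stack, threshold_green, threshold_red, roi = NULL) {
  stopifnot(inherits(stack, "dual_channel_stack"))
  g <- as.numeric(roi_values(stack$green, roi))
  r <- as.numeric(roi_values(stack$red, roi))
  g_pos <- g > threshold_green
  r_pos <- r > threshold_red
  g_total <- sum(g[g_pos])
  r_total <- sum(r[r_pos])
  if (g_total <= 0) stop_vq("zero above-threshold green intensity: M_G undefined")
  if (r_total <= 0) stop_vq("zero above-threshold red intensity: M_R undefined")
  g_coloc <- sum(g[g_pos & r_pos])
  r_coloc <- sum(r[r_pos & g_pos])
  list(M_G = g_coloc / g_total, M_R = r_coloc / r_total,
       G_colocalized = g_coloc, R_colocalized = r_coloc,
       G_total = g_total, R_total = r_total)
}

#' Full colocalization analysis of one stack
#'
#' Convenience wrapper: derives per-channel mean+2SD background thresholds
#' (unless supplied), then computes R_p on the unthresholded intensities and
#' the Manders coefficients on the thresholded ones.
#'
#' @param stack a \code{\link{dual_channel_stack}}.
#' @param roi optional logical mask.
#' @param threshold_green,threshold_red optional explicit thresholds;
#'   defaults to the mean+2SD rule per channel.
#' @return An object of class \code{coloc_result} with fields \code{R_p},
#'   \code{M_G}, \code{M_R}, channel means \code{G_A}, \code{R_A},
#'   colocalized intensity sums, thresholds, and \code{n_voxels}.
#' @export
coloc_analysis <- function(stack, roi = NULL, threshold_green = NULL,
                           threshold_red = NULL) {
  stopifnot(inherits(stack, "dual_channel_stack"))
  if (is.null(threshold_green))
    threshold_green <- background_threshold(stack$green, roi)$threshold
  if (is.null(threshold_red))
    threshold_red <- background_threshold(stack$red, roi)$threshold
  m <- manders_coeffs(stack, threshold_green, threshold_red, roi)
  g <- roi_values(stack$green, roi)
  r <- roi_values(stack$red, roi)
  structure(list(R_p = pearson_coloc(stack, roi),
                 M_G = m$M_G, M_R = m$M_R,
                 G_A = mean(g), R_A = mean(r),
                 G_colocalized = m$G_colocalized,
                 R_colocalized = m$R_colocalized,
                 threshold_green = threshold_green,
                 threshold_red = threshold_red,
                 n_voxels = length(g)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("colocalization analysis\n")
  cat(sprintf("  R_p = %.4f over %d voxels\n", x$R_p, x$n_voxels))
  cat(sprintf("  M_G (Mx) = %.4f   M_R (My) = %.4f\n", x$M_G, x$M_R))
  cat(sprintf("  thresholds: green %.2f, red %.2f (mean + 2 SD unless supplied)\n",
              x$threshold_green, x$threshold_red))
  invisible(x)
}

#' Joint-intensity colocalization map
#'
#' 256 x 256 count matrix of (green, red) voxel intensity pairs — the
#' scatter plot shown beside confocal overlays, with green on the x-axis
#' and red (vitronectin) on the y-axis. Quadrant totals are split by the
#' two thresholds; the grand total always equals the voxel count.
#'
#' @param stack a \code{\link{dual_channel_stack}}.
#' @param threshold_green,threshold_red quadrant-defining thresholds.
#' @param roi optional logical mask.
#' @return An object of class \code{coloc_map}: \code{counts} (256 x 256,
#'   rows = green 0..255, cols = red 0..255), \code{quadrants} and the
#'   thresholds.
#' @export
coloc_map <- function(stack, threshold_green = 0, threshold_red = 0,
                      roi = NULL) {
  stopifnot(inherits(stack, "dual_channel_stack"))
  g <- as.integer(roi_values(stack$green, roi))
  r <- as.integer(roi_values(stack$red, roi))
  counts <- matrix(tabulate(g + 256L * r + 1L, nbins = 256L * 256L),
                   nrow = 256, ncol = 256,
                   dimnames = list(green = 0:255, red = 0:255))
  g_pos <- g > threshold_green
  r_pos <- r > threshold_red
  quadrants <- c(both = sum(g_pos & r_pos),
                 green_only = sum(g_pos & !r_pos),
                 red_only = sum(!g_pos & r_pos),
                 neither = sum(!g_pos & !r_pos))
  structure(list(counts = counts, quadrants = quadrants,
                 threshold_green = threshold_green,
                 threshold_red = threshold_red,
                 n_voxels = length(g)),
            class = "coloc_map")
}

#' @export
print.coloc_map <- function(x, ...) {
  cat(sprintf("coloc_map: %d voxels binned on a 256 x 256 intensity grid\n",
              x$n_voxels))
  print(x$quadrants)
  invisible(x)
}

#' @description Plots the map as a log-count heat map with the quadrant
#'   thresholds overlaid, green intensity on x and red on y.
#' @param x a \code{coloc_map}.
#' @param ... passed to \code{image}.
#' @rdname coloc_map
#' @export
plot.coloc_map <- function(x, ...) {
  graphics::image(0:255, 0:255, log1p(x$counts),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "green intensity", ylab = "red intensity",
                  useRaster = TRUE, ...)
  graphics::abline(v = x$threshold_green, h = x$threshold_red,
                   col = "white", lty = 2)
  invisible(x)
}
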