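#' Mean + 2 SD background threshold
#'
#' Sets the lower intensity threshold of a fluorescence channel at two
#' standard deviations above the mean voxel intensity, the rule used to
#' exclude background before voxel quantification. The SD is the population
#' (divide-by-n) standard deviation, and "above" is strict, so a constant
#' channel retains no voxels.
#'
#' @param channel 2D or 3D numeric intensity array.
#' @param roi optional logical mask of the same shape restricting the
#'   computation.
#' @return An object of class \code{threshold_result}: mean, sd, threshold
#'   (= mean + 2 sd), number of voxels strictly above it, their intensity
#'   sum, and the total voxel count considered.
#' @export
background_threshold <- function(channel, roi = NULL) {
  v <- roi_values(channel, roi)
  m <- mean(v)
  s <- pop_sd(v)
  thr <- m + 2 * s
  above <- v > thr
  structure(list(mean = m, sd = s, threshold = thr,
                 n_above = sum(above),
                 intensity_sum_above = sum(v[above]),
                 n_total = length(v)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("background threshold (mean + 2 SD): %.4f\n", x$threshold))
  cat(sprintf("  mean %.4f, sd %.4f over %d voxels\n", x$mean, x$sd, x$n_total))
  cat(sprintf("  above threshold: %d voxels, intensity sum %.1f (%.2f%% retained)\n",
              x$n_above, x$intensity_sum_above, 100 * x$n_above / x$n_total))
  invisible(x)
}

roi_values <- function(channel, roi) {
  if (is.null(roi)) return(as.vector(channel))
  if (!identical(dim(roi), dim(channel)))
    stop_vq("roi shape %s does not match channel shape %s",
            paste(dim(roi), collapse = "x"), paste(dim(channel), collapse = "x"))
  v <- channel[roi]
  if (length(v) == 0L) stop_vq("empty roi")
  v
}

#' Count and sum voxels above a threshold
#'
#' @param channel numeric intensity array.
#' @param threshold finite numeric cutoff; voxels strictly above it count.
#' @param roi optional logical mask.
#' @return list with \code{count} and \code{intensity_sum}.
#' @export
voxel_summary <- function(channel, threshold, roi = NULL) {
  if (!is.finite(threshold)) stop_vq("threshold must be finite")
  v <- roi_values(channel, roi)
  above <- v > threshold
  list(count = sum(above), intensity_sum = sum(v[above]))
}

#' Above-threshold intensity per unit compartment area
#'
#' Sums the above-threshold intensity of a 2D channel inside a compartment
#' mask (e.g. surface epithelium) and normalizes by the compartment area in
#' square micrometres — the per-visual-field intensity measure.
#'
#' @param channel 2D numeric intensity array.
#' @param compartment_mask logical matrix, same shape; must be non-empty.
#' @param threshold intensity cutoff (strictly above).
#' @param pixel_size pixel edge length in micrometres.
#' @return An object of class \code{intensity_per_area}: the intensity sum,
#'   the area in um^2 and their ratio \code{value}.
#' @export
intensity_per_area <- function(channel, compartment_mask, threshold,
                               pixel_size) {
  if (!identical(dim(compartment_mask), dim(channel)))
    stop_vq("compartment_mask shape does not match channel")
  n_px <- sum(compartment_mask)
  if (n_px == 0L) stop_vq("empty compartment mask")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_vq("pixel_size must be positive")
  v <- channel[compartment_mask]
  s <- sum(v[v > threshold])
  area <- n_px * pixel_size^2
  structure(list(intensity_sum = s, area_um2 = area, value = s / area),
            class = "intensity_per_area")
}

#' @export
print.intensity_per_area <- function(x, ...) {
  cat(sprintf("intensity per area: %.4f / um^2 (sum %.1f over %.1f um^2)\n",
              x$value, x$intensity_sum, x$area_um2))
  invisible(x)
}
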