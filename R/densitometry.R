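#' Lane intensity profile
#'
#' Averages a rectangular lane region of a grayscale gel image across the
#' lane width, giving a 1D intensity profile along the migration axis
#' (image rows). For blots digitized dark-on-light, set \code{invert} so
#' that bands become peaks.
#'
#' @param gel_image numeric matrix (rows = migration axis).
#' @param lane_roi list with integer vectors \code{rows} and \code{cols}
#'   delimiting the lane.
#' @param invert if TRUE the image is inverted (max - intensity) before
#'   averaging.
#' @return numeric vector of per-row mean intensities, named by row index.
#' @export
lane_profile <- function(gel_image, lane_roi, invert = FALSE) {
  if (length(dim(gel_image)) != 2L) stop_vq("gel_image must be a matrix")
  rows <- lane_roi$rows
  cols <- lane_roi$cols
  if (is.null(rows) || is.null(cols))
    stop_vq("lane_roi must be a list with 'rows' and 'cols'")
  if (min(rows) < 1L || max(rows) > nrow(gel_image) ||
      min(cols) < 1L || max(cols) > ncol(gel_image))
    stop_vq("lane_roi exceeds the %d x %d gel image",
            nrow(gel_image), ncol(gel_image))
  region <- gel_image[rows, cols, drop = FALSE]
  if (invert) region <- max(region) - region
  profile <- rowMeans(region)
  names(profile) <- rows
  profile
}

#' Integrate a band above a baseline
#'
#' Band volume is the sum of the profile over the integration window after
#' subtracting a baseline, with the total clipped at zero. The default
#' baseline is the straight line joining the profile values at the window
#' endpoints; a flat profile therefore integrates to exactly zero.
#' Alternatively a full-length numeric baseline (e.g. from
#' \code{\link{estimate_baseline}}) can be supplied: because it pools many
#' profile samples, it is far less sensitive to noise at the window
#' endpoints than the two-point rule.
#'
#' @param profile numeric lane profile.
#' @param window integer length-2, first and last profile index of the band.
#' @param baseline "linear-endpoints" (default), "none", or a numeric
#'   vector of the same length as \code{profile} to subtract.
#' @return band volume (non-negative scalar).
#' @export
integrate_band <- function(profile, window, baseline = "linear-endpoints") {
  if (length(window) != 2L || window[1] > window[2])
    stop_vq("window must be c(first, last) with first <= last")
  if (window[1] < 1L || window[2] > length(profile))
    stop_vq("window [%d, %d] outside profile of length %d",
            window[1], window[2], length(profile))
  idx <- window[1]:window[2]
  seg <- as.numeric(profile[idx])
  base <- if (is.numeric(baseline)) {
    if (length(baseline) != length(profile))
      stop_vq("numeric baseline must match the profile length")
    baseline[idx]
  } else if (identical(baseline, "linear-endpoints")) {
    seq(seg[1], seg[length(seg)], length.out = length(seg))
  } else if (identical(baseline, "none")) {
    0
  } else stop_vq("unknown baseline model '%s'", baseline)
  max(sum(seg - base), 0)
}

#' Fit a global linear baseline to a lane profile
#'
#' Least-squares straight line through every profile sample lying outside
#' the supplied band windows, i.e. through the band-free stretches of the
#' lane. Pooling all out-of-band samples makes the baseline estimate
#' essentially noise-free compared with reading it off two endpoint
#' samples.
#'
#' @param profile numeric lane profile.
#' @param windows list of band windows (each \code{c(first, last)}) to
#'   exclude from the fit.
#' @return numeric baseline of the same length as \code{profile}.
#' @export
estimate_baseline <- function(profile, windows) {
  n <- length(profile)
  excl <- unique(unlist(lapply(windows, function(w) w[1]:w[2])))
  keep <- setdiff(seq_len(n), excl)
  if (length(keep) < 2L)
    stop_vq("windows cover the whole profile: no baseline samples left")
  fit <- stats::lm.fit(cbind(1, keep), as.numeric(profile[keep]))
  as.numeric(cbind(1, seq_len(n)) %*% fit$coefficients)
}

#' Normalize a band volume to the loading control
#'
#' @param band_volume integrated volume of the band of interest.
#' @param control_volume integrated volume of the loading-control band
#'   (beta-actin); must be strictly positive.
#' @return the band/control ratio.
#' @export
normalize_to_loading <- function(band_volume, control_volume) {
  if (!is.finite(control_volume) || control_volume <= 0)
    stop_vq("loading-control volume must be > 0")
  if (band_volume < 0) stop_vq("band volume must be >= 0")
  band_volume / control_volume
}

#' Quantify all bands of a set of lane profiles
#'
#' Integrates every configured band window in every lane and reports each
#' band's volume and its ratio to the lane's loading control. By default
#' each lane's baseline is the global linear fit over its band-free
#' samples (see \code{\link{estimate_baseline}}); "linear-endpoints"
#' switches to the per-window two-point rule.
#'
#' @param profiles named list of lane profiles.
#' @param windows named list of band windows, e.g.
#'   \code{list(kda75 = c(60, 100), kda65 = c(110, 150), beta_actin = c(180, 220))}.
#' @param control name of the loading-control band in \code{windows}.
#' @param baseline "global-linear" (default) or "linear-endpoints".
#' @return data frame with columns \code{lane}, \code{band}, \code{volume},
#'   \code{ratio_to_control}.
#' @export
quantify_gel <- function(profiles, windows, control = "beta_actin",
                         baseline = c("global-linear", "linear-endpoints")) {
  baseline <- match.arg(baseline)
  if (!control %in% names(windows))
    stop_vq("control band '%s' not among windows: %s", control,
            paste(names(windows), collapse = ", "))
  lanes <- names(profiles) %||% as.character(seq_along(profiles))
  rows <- list()
  for (i in seq_along(profiles)) {
    base_i <- if (baseline == "global-linear")
      estimate_baseline(profiles[[i]], windows) else "linear-endpoints"
    vols <- vapply(windows,
                   function(w) integrate_band(profiles[[i]], w, base_i),
                   numeric(1))
    ctrl <- vols[[control]]
    for (b in names(windows)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lane = lanes[i], band = b, volume = vols[[b]],
        ratio_to_control = if (b == control) 1
                           else normalize_to_loading(vols[[b]], ctrl))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
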