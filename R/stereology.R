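#' Stereological point grid
#'
#' Builds the point grid overlaid on each section image for Cavalieri-style
#' point counting. The default is the classical 81-point (9 x 9) systematic
#' uniform grid: the image is tiled into r x r equal rectangles and one
#' point placed per tile — at the tile centre ("centered") or at one shared
#' uniform-random offset within the tile ("random", the systematic
#' uniform-random design that makes point counting unbiased). A fully
#' random scatter of any n points is also available.
#'
#' @param image_shape integer length-2, image dimensions (rows, cols) in
#'   pixels.
#' @param n_points number of grid points; must be a perfect square for
#'   systematic placement. Default 81.
#' @param offset "centered" or "random" (systematic placement only).
#' @param placement "systematic" (default) or "random" scatter.
#' @param seed optional integer seed for the random offset/scatter; NULL
#'   uses the current RNG state.
#' @return An object of class \code{point_grid}: continuous coordinates
#'   \code{y}, \code{x} (in [0, dim)), the pixel indices \code{py},
#'   \code{px} containing each point, and the grid geometry.
#' @export
point_grid <- function(image_shape, n_points = 81,
                       offset = c("centered", "random"),
                       placement = c("systematic", "random"),
                       seed = NULL) {
  offset <- match.arg(offset)
  placement <- match.arg(placement)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L))
    stop_vq("image_shape must be two positive integers (rows, cols)")
  if (!is.null(seed)) set.seed(seed)
  if (placement == "random") {
    y <- stats::runif(n_points, 0, image_shape[1])
    x <- stats::runif(n_points, 0, image_shape[2])
    spacing <- NULL
  } else {
    r <- round(sqrt(n_points))
    if (r * r != n_points)
      stop_vq("n_points = %d is not a perfect square; systematic grids are r x r",
              n_points)
    if (r > min(image_shape))
      stop_vq("grid %d x %d larger than image %d x %d",
              r, r, image_shape[1], image_shape[2])
    spacing <- image_shape / r
    u <- if (offset == "random") stats::runif(2) * spacing else spacing / 2
    pts <- expand.grid(i = 0:(r - 1), j = 0:(r - 1))
    y <- u[1] + pts$i * spacing[1]
    x <- u[2] + pts$j * spacing[2]
  }
  py <- pmin(floor(y) + 1L, image_shape[1])
  px <- pmin(floor(x) + 1L, image_shape[2])
  structure(list(y = y, x = x, py = as.integer(py), px = as.integer(px),
                 n_points = as.integer(n_points), spacing = spacing,
                 image_shape = image_shape, placement = placement,
                 offset = offset),
            class = "point_grid")
}

#' @export
print.point_grid <- function(x, ...) {
  cat(sprintf("point_grid: %d points (%s placement, %s offset) on %d x %d image\n",
              x$n_points, x$placement, x$offset,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Classify grid points against a label map
#'
#' Each point takes the class of the pixel containing it (points live at
#' pixel resolution; boundary points are decided by the containing pixel,
#' never fractionally). Counts always sum to the number of grid points.
#'
#' @param grid a \code{\link{point_grid}}.
#' @param labelmap a \code{\link{section_labelmap}}.
#' @return named integer vector of per-class point counts, one entry per
#'   legend class.
#' @export
classify_points <- function(grid, labelmap) {
  stopifnot(inherits(grid, "point_grid"), inherits(labelmap, "section_labelmap"))
  d <- dim(labelmap$labels)
  if (any(grid$py > d[1]) || any(grid$px > d[2]))
    stop_vq("grid points fall outside the %d x %d label map", d[1], d[2])
  cls <- labelmap$labels[cbind(grid$py, grid$px)]
  counts <- table(factor(cls, levels = labelmap_classes(),
                         labels = names(labelmap_classes())))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Volume fractions from point counts
#'
#' Applies the Cavalieri point-counting estimators: the glandular volume
#' fraction G_vf is the share of tissue-hitting points that hit gland
#' (gland referenced to bronchial tissue volume, background excluded), and
#' the vitronectin volume fraction V_vf is the share of gland-hitting
#' points that hit vitronectin-positive gland. A zero denominator yields a
#' flagged missing value with a warning, never a silent zero.
#'
#' @param counts named per-class point counts from
#'   \code{\link{classify_points}}.
#' @return An object of class \code{volume_fractions}: \code{P_tissue},
#'   \code{P_gland}, \code{P_vitronectin}, \code{G_vf}, \code{V_vf}.
#' @export
volume_fractions <- function(counts) {
  need <- names(labelmap_classes())
  if (!all(need %in% names(counts)))
    stop_vq("counts must be named by the label-map legend classes")
  p_tissue <- sum(counts[c("tissue", "gland", "positive_gland",
                           "epithelium", "positive_epithelium")])
  p_gland <- sum(counts[c("gland", "positive_gland")])
  p_vitro <- unname(counts["positive_gland"])
  g_vf <- if (p_tissue > 0) p_gland / p_tissue else {
    warning("no tissue points: G_vf is missing", call. = FALSE)
    NA_real_
  }
  v_vf <- if (p_gland > 0) p_vitro / p_gland else {
    warning("no gland points: V_vf is missing", call. = FALSE)
    NA_real_
  }
  structure(list(P_tissue = unname(p_tissue), P_gland = unname(p_gland),
                 P_vitronectin = p_vitro, G_vf = unname(g_vf),
                 V_vf = unname(v_vf)),
            class = "volume_fractions")
}

#' @export
print.volume_fractions <- function(x, ...) {
  cat(sprintf("point counts: tissue %d, gland %d, vitronectin-positive %d\n",
              x$P_tissue, x$P_gland, x$P_vitronectin))
  cat(sprintf("  G_vf = %s   V_vf = %s\n",
              format(x$G_vf, digits = 4), format(x$V_vf, digits = 4)))
  invisible(x)
}

#' Pixel-based glandular area and positive area fraction
#'
#' @param labelmap a \code{\link{section_labelmap}}.
#' @return list with \code{gland_area_mm2} (gland pixel count times pixel
#'   area, in mm^2) and \code{percent_positive} (100 x positive-gland
#'   pixels / gland pixels; missing with a warning if no gland).
#' @export
area_fraction <- function(labelmap) {
  stopifnot(inherits(labelmap, "section_labelmap"))
  lab <- labelmap$labels
  n_gland <- sum(lab == 2L | lab == 3L)
  n_pos <- sum(lab == 3L)
  area_mm2 <- n_gland * labelmap$pixel_size^2 * 1e-6
  pct <- if (n_gland > 0) 100 * n_pos / n_gland else {
    warning("no gland pixels: percent positive area is missing", call. = FALSE)
    NA_real_
  }
  list(gland_area_mm2 = area_mm2, percent_positive = pct)
}

#' Per-subject medians of per-image measurements
#'
#' Collapses a long per-image results table to subject level by taking the
#' median across each subject's images for every measure — the subject is
#' the unit of analysis for all downstream group comparisons. Invariant to
#' image order.
#'
#' @param per_image data frame with columns \code{subject_id}, \code{group},
#'   \code{measure}, \code{value} (and optionally \code{image_id}).
#' @return data frame with one row per subject per measure:
#'   \code{subject_id}, \code{group}, \code{measure}, \code{value}.
#' @export
subject_summaries <- function(per_image) {
  need <- c("subject_id", "group", "measure", "value")
  missing_cols <- setdiff(need, names(per_image))
  if (length(missing_cols))
    stop_vq("per_image lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(per_image) == 0L)
    return(per_image[c("subject_id", "group", "measure", "value")])
  out <- stats::aggregate(value ~ subject_id + group + measure,
                          data = per_image,
                          FUN = function(v) stats::median(v, na.rm = TRUE))
  out[order(out$measure, out$group, out$subject_id), ]
}

#' Group-level median (IQR) summary table
#'
#' Summarizes subject-level values per group and measure as median and
#' interquartile range (linear-interpolation quartiles), the format of the
#' cohort comparison tables.
#'
#' @param per_subject data frame from \code{\link{subject_summaries}}.
#' @return data frame with columns \code{measure}, \code{group}, \code{n},
#'   \code{median}, \code{q1}, \code{q3}.
#' @export
group_summary <- function(per_subject) {
  if (nrow(per_subject) == 0L) stop_vq("empty subject table")
  split_by <- interaction(per_subject$measure, per_subject$group, drop = TRUE)
  rows <- lapply(split(per_subject, split_by), function(d) {
    s <- summarize_iqr(d$value)
    data.frame(measure = d$measure[1], group = d$group[1],
               n = nrow(d), median = s[["median"]],
               q1 = s[["q1"]], q3 = s[["q3"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$measure, out$group), ]
}
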