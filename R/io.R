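#' Dual-channel confocal stack
#'
#' Container for an aligned pair of 3D fluorescence intensity arrays, the
#' substrate of voxel quantification and colocalization analysis. By the
#' package's channel-role convention, green carries the cell-type marker
#' (lactoferrin, MUC5B/MUC5AC or a membrane marker) and red carries
#' vitronectin.
#'
#' @param green,red 3D integer arrays indexed (z, y, x), intensities 0-255.
#' @param voxel_size numeric length-3, voxel edge lengths (z, y, x) in
#'   micrometres. The default z-step of 0.3 um matches a typical confocal
#'   optical-section thickness.
#' @return An object of class \code{dual_channel_stack}: a list with
#'   \code{green}, \code{red}, \code{voxel_size} and \code{bit_depth}.
#' @export
dual_channel_stack <- function(green, red, voxel_size = c(0.3, 0.1, 0.1)) {
  if (length(dim(green)) != 3L || length(dim(red)) != 3L)
    stop_vq("channels must be 3D arrays indexed (z, y, x)")
  if (!identical(dim(green), dim(red)))
    stop_vq("channel shapes differ: green %s vs red %s",
            paste(dim(green), collapse = "x"), paste(dim(red), collapse = "x"))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop_vq("voxel_size must be 3 strictly positive numbers (z, y, x) in um")
  for (ch in list(green, red)) {
    if (any(ch < 0) || any(ch > 255))
      stop_vq("intensities must lie in [0, 255] (8-bit)")
  }
  structure(list(green = green, red = red, voxel_size = voxel_size,
                 bit_depth = 8L),
            class = "dual_channel_stack")
}

#' @export
print.dual_channel_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf("dual_channel_stack: %d x %d x %d voxels (z,y,x), 8-bit\n",
              d[1], d[2], d[3]))
  cat(sprintf("  voxel size (um): z=%g y=%g x=%g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Tissue-section label map
#'
#' 2D categorical image assigning every pixel one tissue-compartment code;
#' the substrate of stereology and area-fraction measurement. Codes:
#' 0 background, 1 non-gland tissue, 2 gland, 3 vitronectin-positive gland,
#' 4 surface epithelium, 5 vitronectin-positive epithelium. Positive-gland
#' refines gland and positive-epithelium refines epithelium: the codes are
#' mutually exclusive, so "gland" as a compartment means codes {2, 3}.
#'
#' @param labels integer matrix of class codes.
#' @param pixel_size pixel edge length in micrometres.
#' @return An object of class \code{section_labelmap}.
#' @export
section_labelmap <- function(labels, pixel_size = 1) {
  if (length(dim(labels)) != 2L) stop_vq("labels must be a 2D matrix")
  bad <- setdiff(unique(as.vector(labels)), labelmap_classes())
  if (length(bad))
    stop_vq("unknown class code(s): %s (legend: %s)",
            paste(sort(bad), collapse = ", "),
            paste(sprintf("%d=%s", labelmap_classes(),
                          names(labelmap_classes())), collapse = ", "))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_vq("pixel_size must be a single positive number (um/pixel)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size = as.numeric(pixel_size)),
            class = "section_labelmap")
}

#' @export
print.section_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("section_labelmap: %d x %d pixels at %g um/pixel\n",
              d[1], d[2], x$pixel_size))
  tab <- table(factor(x$labels, levels = labelmap_classes(),
                      labels = names(labelmap_classes())))
  print(tab)
  invisible(x)
}

#' Label-map class legend
#'
#' @return Named integer vector mapping compartment names to pixel codes.
#' @export
labelmap_classes <- function() {
  c(background = 0L, tissue = 1L, gland = 2L, positive_gland = 3L,
    epithelium = 4L, positive_epithelium = 5L)
}

sidecar_path <- function(path) paste0(path, ".yml")

#' Write / read a dual-channel stack as multi-page TIFF
#'
#' The TIFF holds one 8-bit grayscale page per z-plane: all green planes
#' first (z = 1..Z), then all red planes. Channel layout and voxel size are
#' stored in a YAML sidecar (\code{<path>.yml}) written alongside.
#'
#' @param x a \code{dual_channel_stack}.
#' @param path TIFF file path.
#' @return \code{write_stack} returns \code{path} invisibly;
#'   \code{read_stack} returns a \code{dual_channel_stack} identical
#'   voxel-for-voxel to the one written.
#' @export
write_stack <- function(x, path) {
  stopifnot(inherits(x, "dual_channel_stack"))
  nz <- dim(x$green)[1]
  pages <- vector("list", 2L * nz)
  for (z in seq_len(nz)) {
    pages[[z]]      <- x$green[z, , ] / 255
    pages[[nz + z]] <- x$red[z, , ] / 255
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  yaml::write_yaml(list(format = "dual_channel_stack",
                        channels = c("green", "red"),
                        n_z = nz,
                        voxel_size_um = as.numeric(x$voxel_size),
                        bit_depth = 8L),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_vq("file not found: %s", path)
  if (!file.exists(sidecar_path(path)))
    stop_vq("missing metadata sidecar %s: cannot determine channel layout",
            sidecar_path(path))
  meta <- yaml::read_yaml(sidecar_path(path))
  if (!identical(as.character(meta$channels), c("green", "red")))
    stop_vq("expected two channels (green, red); sidecar declares: %s",
            paste(meta$channels, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- vapply(pages, function(p) attr(p, "bits.per.sample") %||% NA_integer_,
                integer(1))
  if (any(bps != 8L))
    stop_vq("unsupported bit depth %s: expected 8-bit pages",
            paste(unique(bps[bps != 8L]), collapse = ", "))
  nz <- meta$n_z
  if (length(pages) != 2L * nz)
    stop_vq("expected two channels of %d planes (%d pages), found %d pages",
            nz, 2L * nz, length(pages))
  d2 <- dim(pages[[1]])
  green <- array(0L, c(nz, d2))
  red <- array(0L, c(nz, d2))
  for (z in seq_len(nz)) {
    if (!identical(dim(pages[[z]]), d2) || !identical(dim(pages[[nz + z]]), d2))
      stop_vq("mismatched page shapes across channels/planes")
    green[z, , ] <- pages[[z]]
    red[z, , ] <- pages[[nz + z]]
  }
  dual_channel_stack(green, red, voxel_size = meta$voxel_size_um)
}

#' Write / read a section label map as single-page TIFF
#'
#' Class codes are stored directly as 8-bit pixel values; pixel size is
#' recorded in a YAML sidecar.
#'
#' @param x a \code{section_labelmap}.
#' @param path TIFF file path.
#' @export
write_labelmap <- function(x, path) {
  stopifnot(inherits(x, "section_labelmap"))
  tiff::writeTIFF(x$labels / 255, path, bits.per.sample = 8L)
  yaml::write_yaml(list(format = "section_labelmap",
                        pixel_size_um = x$pixel_size,
                        classes = as.list(labelmap_classes())),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) stop_vq("file not found: %s", path)
  if (!file.exists(sidecar_path(path)))
    stop_vq("missing metadata sidecar %s: cannot determine pixel size",
            sidecar_path(path))
  meta <- yaml::read_yaml(sidecar_path(path))
  labels <- tiff::readTIFF(path, as.is = TRUE)
  section_labelmap(labels, pixel_size = meta$pixel_size_um)
}

results_columns <- c("subject_id", "group", "image_id", "measure", "value")

#' Write / read a long-format results table
#'
#' The package's stable CSV schema for per-image and per-subject
#' measurements: columns \code{subject_id, group, image_id, measure, value}.
#' An empty table writes a header-only CSV.
#'
#' @param table data frame with the five schema columns.
#' @param path CSV path.
#' @export
write_results <- function(table, path) {
  missing_cols <- setdiff(results_columns, names(table))
  if (length(missing_cols))
    stop_vq("results table lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  utils::write.csv(table[results_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_vq("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
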