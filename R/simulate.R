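#' Simulation spec for dual-channel confocal stacks
#'
#' Describes a synthetic two-channel z-stack with a known, controllable
#' colocalized fraction. Green objects are ellipsoidal blobs with lognormal
#' size; a fraction \code{coloc_fraction} of green-object voxels (defined
#' before blurring) also carries red signal, and an equal number of
#' red-only blobs provides non-colocalized red structure. Both channels
#' are blurred by a Gaussian point-spread approximation, then corrupted by
#' Poisson shot noise plus additive Gaussian read noise, and quantized to
#' 8-bit — a structural emulation of photomultiplier confocal acquisition,
#' not an optical model.
#'
#' @param shape integer length-3 voxel grid (z, y, x), each >= 8.
#' @param n_blobs number of green objects (and of red-only objects).
#' @param coloc_fraction target fraction in [0, 1] of green-object voxels
#'   that also carry red signal.
#' @param mean_signal,mean_background intensity levels before noise and
#'   quantization.
#' @param blob_radius median in-plane blob radius in voxels (lognormal,
#'   sdlog 0.2; the z semi-axis is halved for anisotropy).
#' @param psf_sigma Gaussian blur sigma in voxels (same in all axes).
#' @param poisson_noise apply Poisson shot noise to the blurred intensity.
#' @param read_noise_sd sd of additive Gaussian read noise (intensity units).
#' @param voxel_size voxel edge lengths (z, y, x) in um.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return object of class \code{coloc_sim_spec}.
#' @export
coloc_sim_spec <- function(shape = c(16, 64, 64), n_blobs = 6,
                           coloc_fraction = 0.5,
                           mean_signal = 150, mean_background = 10,
                           blob_radius = 6, psf_sigma = 0.7,
                           poisson_noise = TRUE, read_noise_sd = 2,
                           voxel_size = c(0.3, 0.1, 0.1), seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop_vq("shape must be 3 dimensions (z, y, x), each >= 8")
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop_vq("coloc_fraction must lie in [0, 1]")
  if (n_blobs < 1L) stop_vq("need at least one blob")
  if (mean_signal <= mean_background)
    stop_vq("mean_signal must exceed mean_background")
  structure(list(shape = shape, n_blobs = as.integer(n_blobs),
                 coloc_fraction = coloc_fraction,
                 mean_signal = mean_signal,
                 mean_background = mean_background,
                 blob_radius = blob_radius, psf_sigma = psf_sigma,
                 poisson_noise = poisson_noise,
                 read_noise_sd = read_noise_sd,
                 voxel_size = voxel_size, seed = seed),
            class = "coloc_sim_spec")
}

# Voxel indices of an axis-aligned ellipsoid, as an index matrix.
ellipsoid_voxels <- function(center, semi, shape) {
  rng <- lapply(1:3, function(d) {
    max(1L, floor(center[d] - semi[d])):min(shape[d], ceiling(center[d] + semi[d]))
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  inside <- ((g[, 1] - center[1]) / semi[1])^2 +
    ((g[, 2] - center[2]) / semi[2])^2 +
    ((g[, 3] - center[3]) / semi[3])^2 <= 1
  g[inside, , drop = FALSE]
}

# Place n non-overlapping ellipsoids, optionally avoiding an existing mask.
# Bounded retries; overcrowded specs fail loudly.
place_blobs <- function(n, shape, radius, avoid = NULL, max_tries = 200L) {
  mask <- array(FALSE, shape)
  for (b in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r_xy <- stats::rlnorm(1, log(radius), 0.2)
      semi <- c(max(1.5, r_xy / 2), r_xy, r_xy)
      lo <- 1 + semi
      hi <- shape - semi
      if (any(hi < lo)) next
      center <- lo + stats::runif(3) * (hi - lo)
      vox <- ellipsoid_voxels(center, semi, shape)
      if (nrow(vox) == 0L) next
      if (any(mask[vox])) next
      if (!is.null(avoid) && any(avoid[vox])) next
      mask[vox] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop_vq("blob placement failed after %d retries: spec is overcrowded (%d blobs of radius ~%g in %s grid)",
              max_tries, n, radius, paste(shape, collapse = "x"))
  }
  mask
}

#' Simulate a dual-channel stack with known colocalization
#'
#' @param spec a \code{\link{coloc_sim_spec}}.
#' @return list with \code{stack} (a \code{\link{dual_channel_stack}}),
#'   the pre-blur ground-truth object masks \code{green_mask} and
#'   \code{red_mask}, and \code{realized_fraction} — the post-discretization
#'   colocalized share of green-object voxels, the reference truth for
#'   recovery tests.
#' @export
sim_coloc_stack <- function(spec) {
  stopifnot(inherits(spec, "coloc_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  shape <- spec$shape
  green_mask <- place_blobs(spec$n_blobs, shape, spec$blob_radius)
  g_idx <- which(green_mask)
  n_red_in_green <- round(spec$coloc_fraction * length(g_idx))
  red_mask <- array(FALSE, shape)
  if (n_red_in_green > 0) {
    chosen <- if (n_red_in_green == length(g_idx)) g_idx
              else sample(g_idx, n_red_in_green)
    red_mask[chosen] <- TRUE
  }
  if (spec$coloc_fraction < 1) {
    red_only <- place_blobs(spec$n_blobs, shape, spec$blob_radius,
                            avoid = green_mask)
    red_mask <- red_mask | red_only
  }
  realized <- sum(red_mask & green_mask) / length(g_idx)

  render <- function(mask) {
    img <- array(spec$mean_background, shape)
    img[mask] <- spec$mean_signal
    img <- gaussian_blur(img, spec$psf_sigma)
    if (spec$poisson_noise) img <- array(stats::rpois(length(img), img), shape)
    if (spec$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$read_noise_sd)
    quantize_8bit(img)
  }
  green <- render(green_mask)
  red <- render(red_mask)
  list(stack = dual_channel_stack(green, red, voxel_size = spec$voxel_size),
       green_mask = green_mask, red_mask = red_mask,
       realized_fraction = realized)
}

#' Simulation spec for a labelled tissue section
#'
#' Describes a synthetic 2D section label map with known glandular and
#' vitronectin-positive fractions. Compartments are carved from smoothed
#' Gaussian random fields by rank thresholding, so realized fractions are
#' pixel-exact up to rounding: the gland compartment takes the top-k field
#' values among candidate tissue pixels with k chosen from the target
#' fraction, and positive sub-regions are carved the same way inside gland
#' (and epithelium).
#'
#' @param shape integer length-2 (rows, cols).
#' @param pixel_size um per pixel.
#' @param gland_fraction target gland share of all tissue pixels, in [0, 1].
#' @param positive_fraction target vitronectin-positive share of gland
#'   pixels, in [0, 1].
#' @param epithelium_fraction share of image rows forming a surface
#'   epithelium band at the top (0 disables it).
#' @param positive_fraction_epithelium positive share within epithelium.
#' @param background_fraction share of image rows forming a background band
#'   at the bottom (airway lumen / off-section).
#' @param smooth sigma (pixels) of the Gaussian field smoothing; controls
#'   compartment granularity.
#' @param seed integer seed, or NULL.
#' @return object of class \code{section_sim_spec}.
#' @export
section_sim_spec <- function(shape = c(256, 256), pixel_size = 1,
                             gland_fraction = 0.4, positive_fraction = 0.2,
                             epithelium_fraction = 0,
                             positive_fraction_epithelium = 0.3,
                             background_fraction = 0.05,
                             smooth = 8, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L))
    stop_vq("shape must be 2 dimensions, each >= 16")
  for (f in c(gland_fraction, positive_fraction, epithelium_fraction,
              positive_fraction_epithelium, background_fraction)) {
    if (f < 0 || f > 1) stop_vq("all fractions must lie in [0, 1]")
  }
  structure(list(shape = shape, pixel_size = pixel_size,
                 gland_fraction = gland_fraction,
                 positive_fraction = positive_fraction,
                 epithelium_fraction = epithelium_fraction,
                 positive_fraction_epithelium = positive_fraction_epithelium,
                 background_fraction = background_fraction,
                 smooth = smooth, seed = seed),
            class = "section_sim_spec")
}

# Rank-threshold a smoothed field: mark the k candidate pixels with the
# highest field values.
carve_topk <- function(field, candidates, k) {
  idx <- which(candidates)
  sel <- idx[order(field[idx], decreasing = TRUE)[seq_len(k)]]
  sel
}

#' Simulate a tissue-section label map
#'
#' @param spec a \code{\link{section_sim_spec}}.
#' @return list with \code{labelmap} (a \code{\link{section_labelmap}}) and
#'   \code{realized}: the pixel-exact gland fraction (gland / all tissue),
#'   positive-within-gland fraction, and positive-within-epithelium
#'   fraction, recomputed from the emitted labels.
#' @export
sim_section_labelmap <- function(spec) {
  stopifnot(inherits(spec, "section_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ny <- spec$shape[1]; nx <- spec$shape[2]
  labels <- matrix(1L, ny, nx)
  n_bg_rows <- floor(spec$background_fraction * ny)
  if (n_bg_rows > 0) labels[(ny - n_bg_rows + 1L):ny, ] <- 0L
  n_epi_rows <- floor(spec$epithelium_fraction * ny)
  if (n_epi_rows > 0) labels[seq_len(n_epi_rows), ] <- 4L

  n_tissue <- sum(labels != 0L)
  k_gland <- round(spec$gland_fraction * n_tissue)
  candidates <- labels == 1L
  if (k_gland > sum(candidates))
    stop_vq("unreachable gland fraction %.2f: only %d of %d tissue pixels available",
            spec$gland_fraction, sum(candidates), n_tissue)
  field <- gaussian_blur(matrix(stats::rnorm(ny * nx), ny, nx), spec$smooth)
  if (k_gland > 0) labels[carve_topk(field, candidates, k_gland)] <- 2L

  k_pos <- round(spec$positive_fraction * k_gland)
  if (k_pos > 0) {
    field2 <- gaussian_blur(matrix(stats::rnorm(ny * nx), ny, nx),
                            spec$smooth / 2)
    labels[carve_topk(field2, labels == 2L, k_pos)] <- 3L
  }
  n_epi <- sum(labels == 4L)
  k_pos_epi <- round(spec$positive_fraction_epithelium * n_epi)
  if (k_pos_epi > 0) {
    field3 <- gaussian_blur(matrix(stats::rnorm(ny * nx), ny, nx),
                            spec$smooth / 2)
    labels[carve_topk(field3, labels == 4L, k_pos_epi)] <- 5L
  }

  n_gland_total <- sum(labels == 2L | labels == 3L)
  n_epi_total <- sum(labels == 4L | labels == 5L)
  realized <- list(
    gland_fraction = n_gland_total / n_tissue,
    positive_fraction = if (n_gland_total > 0)
      sum(labels == 3L) / n_gland_total else NA_real_,
    positive_fraction_epithelium = if (n_epi_total > 0)
      sum(labels == 5L) / n_epi_total else NA_real_)
  list(labelmap = section_labelmap(labels, pixel_size = spec$pixel_size),
       realized = realized)
}

#' Simulation spec for a multi-group cohort
#'
#' Describes a synthetic study cohort: named groups with subject counts and
#' a beta-distributed per-subject true vitronectin volume fraction
#' (parameterized by location = mean and concentration). Defaults mirror
#' the structure of a three-group airway study — healthy controls with a
#' high vitronectin fraction and two disease groups with strongly reduced
#' fractions (locations 0.29 / 0.07 / 0.04 at n = 14 / 7 / 10) — and about
#' five section images per subject, with the per-subject image count drawn
#' as 1 + Poisson(mean - 1) rather than fixed.
#'
#' @param groups named list; each element a list with \code{n} (subjects),
#'   \code{location} (mean true fraction in (0, 1)) and optionally
#'   \code{concentration} (beta precision, default 12).
#' @param images_per_subject mean number of images per subject (>= 1).
#' @param image_shape label-map dimensions for per-image simulation.
#' @param gland_fraction mean gland fraction of the sections.
#' @param within_subject_concentration beta precision of per-image
#'   fractions around the subject's true fraction.
#' @param pixel_size um per pixel of the simulated sections.
#' @param seed integer seed, or NULL.
#' @return object of class \code{cohort_sim_spec}.
#' @export
cohort_sim_spec <- function(groups = list(
                              HC = list(n = 14, location = 0.29),
                              asthma = list(n = 7, location = 0.07),
                              COPD = list(n = 10, location = 0.04)),
                            images_per_subject = 5,
                            image_shape = c(96, 96),
                            gland_fraction = 0.39,
                            within_subject_concentration = 80,
                            pixel_size = 2, seed = 1) {
  if (length(groups) < 2L) stop_vq("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop_vq("groups must be named")
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (is.null(g$n) || g$n < 1L) stop_vq("group '%s' needs n >= 1", nm)
    if (is.null(g$location) || g$location <= 0 || g$location >= 1)
      stop_vq("group '%s' needs a location in (0, 1)", nm)
    groups[[nm]]$concentration <- g$concentration %||% 12
  }
  if (images_per_subject < 1) stop_vq("images_per_subject must be >= 1")
  structure(list(groups = groups,
                 images_per_subject = images_per_subject,
                 image_shape = as.integer(image_shape),
                 gland_fraction = gland_fraction,
                 within_subject_concentration = within_subject_concentration,
                 pixel_size = pixel_size, seed = seed),
            class = "cohort_sim_spec")
}

rbeta_loc <- function(n, location, concentration) {
  stats::rbeta(n, location * concentration, (1 - location) * concentration)
}

#' Simulate a cohort of subjects with per-image section label maps
#'
#' Draws each subject's true vitronectin fraction from the group's beta
#' distribution, an image count from 1 + Poisson(mean - 1), and for each
#' image a label map whose positive-within-gland fraction is a beta draw
#' around the subject's truth. The truth table and realized per-image
#' fractions are returned for parameter-recovery tests. Quantification
#' consumes only the label maps; group labels live solely in the truth
#' table, mirroring observer blinding.
#'
#' @param spec a \code{\link{cohort_sim_spec}}.
#' @param generate_images if FALSE, skip label-map rendering and return the
#'   truth table plus per-image target fractions only.
#' @return list with \code{truth} (data frame: subject_id, group,
#'   true_fraction, n_images) and \code{images} (list of per-image records:
#'   subject_id, image_id, labelmap, realized fractions).
#' @export
sim_cohort <- function(spec, generate_images = TRUE) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  truth <- list()
  images <- list()
  sid <- 0L
  for (nm in names(spec$groups)) {
    g <- spec$groups[[nm]]
    for (s in seq_len(g$n)) {
      sid <- sid + 1L
      subject_id <- sprintf("S%03d", sid)
      p_true <- rbeta_loc(1, g$location, g$concentration)
      n_img <- 1L + stats::rpois(1, spec$images_per_subject - 1)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = subject_id, group = nm,
        true_fraction = p_true, n_images = n_img)
      for (im in seq_len(n_img)) {
        p_img <- rbeta_loc(1, p_true, spec$within_subject_concentration)
        rec <- list(subject_id = subject_id, group = nm,
                    image_id = sprintf("%s_img%02d", subject_id, im),
                    target_fraction = p_img)
        if (generate_images) {
          sec <- sim_section_labelmap(section_sim_spec(
            shape = spec$image_shape, pixel_size = spec$pixel_size,
            gland_fraction = min(0.9, max(0.05, rbeta_loc(
              1, spec$gland_fraction, 60))),
            positive_fraction = p_img,
            smooth = max(3, round(min(spec$image_shape) / 16)),
            seed = NULL))
          rec$labelmap <- sec$labelmap
          rec$realized <- sec$realized
        }
        images[[length(images) + 1L]] <- rec
      }
    }
  }
  list(truth = do.call(rbind, truth), images = images)
}

#' Simulation spec for western-blot lanes
#'
#' Each lane carries non-overlapping Gaussian bands (by default the 75-kDa
#' and 65-kDa vitronectin isoforms and the beta-actin loading control)
#' whose integrated area is proportional to true abundance, on a linear
#' baseline drift with additive Gaussian noise.
#'
#' @param lanes list of lanes; each lane a list of bands, each band a list
#'   with \code{label}, \code{abundance} (> 0, or 0 for an absent band),
#'   \code{center} (profile index) and \code{width} (Gaussian sd, profile
#'   units).
#' @param profile_length samples per lane profile.
#' @param baseline,baseline_drift constant and linear baseline components.
#' @param noise_sd sd of additive profile noise.
#' @param peak_scale intensity units per unit abundance (peak integral =
#'   abundance x peak_scale).
#' @param seed integer seed, or NULL.
#' @return object of class \code{gel_sim_spec}.
#' @export
gel_sim_spec <- function(lanes, profile_length = 256, baseline = 5,
                         baseline_drift = 3, noise_sd = 0.3,
                         peak_scale = 300, seed = 1) {
  if (length(lanes) < 1L) stop_vq("need at least one lane")
  for (li in seq_along(lanes)) {
    bands <- lanes[[li]]
    for (b in bands) {
      if (is.null(b$label) || is.null(b$abundance) || is.null(b$center) ||
          is.null(b$width))
        stop_vq("each band needs label, abundance, center, width")
      if (b$abundance < 0) stop_vq("abundances must be >= 0")
      if (b$center < 1 || b$center > profile_length)
        stop_vq("band center outside profile")
    }
    if (length(bands) > 1L) {
      for (i in seq_len(length(bands) - 1L)) for (j in (i + 1L):length(bands)) {
        sep <- abs(bands[[i]]$center - bands[[j]]$center)
        if (sep < 3 * (bands[[i]]$width + bands[[j]]$width))
          stop_vq("overlapping bands in lane %d: '%s' and '%s' are %g apart",
                  li, bands[[i]]$label, bands[[j]]$label, sep)
      }
    }
  }
  structure(list(lanes = lanes, profile_length = as.integer(profile_length),
                 baseline = baseline, baseline_drift = baseline_drift,
                 noise_sd = noise_sd, peak_scale = peak_scale, seed = seed),
            class = "gel_sim_spec")
}

#' Default three-band lane layout
#'
#' Convenience constructor for a lane with 75-kDa, 65-kDa and beta-actin
#' bands at standard positions on a 256-sample profile.
#'
#' @param abundance_75,abundance_65,abundance_actin band abundances.
#' @return list of three band specs for \code{\link{gel_sim_spec}}.
#' @export
standard_lane <- function(abundance_75 = 1, abundance_65 = 1,
                          abundance_actin = 1) {
  list(list(label = "75kDa", abundance = abundance_75, center = 70, width = 5),
       list(label = "65kDa", abundance = abundance_65, center = 120, width = 5),
       list(label = "beta_actin", abundance = abundance_actin, center = 200,
            width = 5))
}

#' Simulate western-blot lane profiles
#'
#' @param spec a \code{\link{gel_sim_spec}}.
#' @return list with \code{profiles} (named list of numeric profiles,
#'   bands as upward peaks), \code{truth} (data frame: lane, label,
#'   abundance, center, width, true integral) and \code{windows} (band
#'   integration windows at center +- 4 width, named by band label of the
#'   first lane).
#' @export
sim_gel <- function(spec) {
  stopifnot(inherits(spec, "gel_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  t_axis <- seq_len(spec$profile_length)
  profiles <- list()
  truth <- list()
  for (li in seq_along(spec$lanes)) {
    prof <- spec$baseline +
      spec$baseline_drift * (t_axis - 1) / (spec$profile_length - 1)
    for (b in spec$lanes[[li]]) {
      prof <- prof + b$abundance * spec$peak_scale *
        stats::dnorm(t_axis, b$center, b$width)
      truth[[length(truth) + 1L]] <- data.frame(
        lane = sprintf("lane%02d", li), label = b$label,
        abundance = b$abundance, center = b$center, width = b$width,
        true_integral = b$abundance * spec$peak_scale)
    }
    if (spec$noise_sd > 0)
      prof <- prof + stats::rnorm(spec$profile_length, 0, spec$noise_sd)
    prof <- pmax(prof, 0)
    profiles[[sprintf("lane%02d", li)]] <- prof
  }
  first <- spec$lanes[[1]]
  windows <- stats::setNames(
    lapply(first, function(b) {
      c(max(1L, round(b$center - 4 * b$width)),
        min(spec$profile_length, round(b$center + 4 * b$width)))
    }),
    vapply(first, `[[`, "", "label"))
  list(profiles = profiles, truth = do.call(rbind, truth), windows = windows)
}
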