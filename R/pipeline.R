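#' Study configuration
#'
#' Bundles the simulation specs, grid settings and seed that fully
#' determine a synthetic study run. Every run writes the resolved
#' configuration next to its outputs, so any results directory can be
#' regenerated from its own config alone.
#'
#' @param cohort a \code{\link{cohort_sim_spec}} (stereology studies).
#' @param coloc_groups named list as in \code{cohort_sim_spec} groups, the
#'   per-group distribution of true colocalized fraction (coloc studies).
#' @param coloc_stack a \code{\link{coloc_sim_spec}} used as the per-image
#'   template (its seed and coloc_fraction are overridden per image).
#' @param images_per_subject mean images per subject for coloc studies.
#' @param n_points grid points for stereology.
#' @param grid_offset "random" (systematic uniform-random, default) or
#'   "centered".
#' @param alpha significance level for the group tests.
#' @param seed master seed; all randomness in a run derives from it.
#' @return object of class \code{study_config}.
#' @export
study_config <- function(cohort = cohort_sim_spec(),
                         coloc_groups = list(
                           serous = list(n = 10, location = 0.7),
                           mucous = list(n = 10, location = 0.2)),
                         coloc_stack = coloc_sim_spec(shape = c(8, 48, 48),
                                                      n_blobs = 4,
                                                      blob_radius = 5,
                                                      seed = NULL),
                         images_per_subject = 5,
                         n_points = 81,
                         grid_offset = c("random", "centered"),
                         alpha = 0.05, seed = 1) {
  grid_offset <- match.arg(grid_offset)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_sim_spec"))
  stopifnot(inherits(coloc_stack, "coloc_sim_spec"))
  if (length(coloc_groups) < 2L) stop_vq("need at least 2 coloc groups")
  n_subj <- vapply(coloc_groups, function(g) g$n %||% 0, numeric(1))
  if (any(n_subj < 1)) stop_vq("every group needs at least one subject")
  structure(list(cohort = cohort, coloc_groups = coloc_groups,
                 coloc_stack = coloc_stack,
                 images_per_subject = images_per_subject,
                 n_points = as.integer(n_points),
                 grid_offset = grid_offset, alpha = alpha,
                 seed = as.integer(seed)),
            class = "study_config")
}

persist_outputs <- function(results, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(results$per_image_long, file.path(out_dir, "per_image.csv"))
  write_results(results$per_subject_long, file.path(out_dir, "per_subject.csv"))
  utils::write.csv(results$group_summary,
                   file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  utils::write.csv(results$tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config_to_list(config), file.path(out_dir, "config.yml"))
  invisible(out_dir)
}

config_to_list <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

run_group_tests <- function(per_subject, alpha) {
  rows <- list()
  for (ms in unique(per_subject$measure)) {
    d <- per_subject[per_subject$measure == ms & is.finite(per_subject$value), ]
    if (length(unique(d$group)) < 2L || length(unique(d$value)) == 1L) next
    kw <- kruskal_wallis(d$value, d$group)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = ms, test = "kruskal_wallis", comparison = "omnibus",
      statistic = unname(kw$statistic), p.value = kw$p.value,
      significant = kw$p.value < alpha)
    dn <- dunn_posthoc(d$value, d$group)
    for (i in seq_len(nrow(dn))) {
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, test = "dunn",
        comparison = paste(dn$group1[i], "vs", dn$group2[i]),
        statistic = dn$z[i], p.value = dn$p.adjusted[i],
        significant = dn$p.adjusted[i] < alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

long_rows <- function(recs, measures) {
  do.call(rbind, lapply(recs, function(r) {
    data.frame(subject_id = r$subject_id, group = r$group,
               image_id = r$image_id,
               measure = names(measures(r)),
               value = unname(unlist(measures(r))))
  }))
}

#' Run a full synthetic stereology study
#'
#' Generates a cohort of subjects with per-image section label maps, point
#' counts each image with a fresh systematic (uniform-random offset) grid,
#' computes G_vf, V_vf, glandular area and percent positive area, collapses
#' to subject medians, and compares groups with Kruskal-Wallis plus Dunn's
#' post test. Quantification stages see only label maps; diagnosis labels
#' join the data only at the statistics stage.
#'
#' @param config a \code{\link{study_config}}.
#' @param out_dir optional directory; when given, per-image and per-subject
#'   CSVs, the group summary, the test table and the resolved config are
#'   written there.
#' @return list with \code{per_image_long}, \code{per_subject_long},
#'   \code{group_summary}, \code{tests} and the cohort \code{truth} table.
#' @export
run_stereology_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(config$cohort)) stop_vq("config has no cohort spec")
  set.seed(config$seed)
  cohort <- spec_reseeded(config$cohort)
  cohort <- sim_cohort(cohort)
  per_image <- long_rows(cohort$images, function(r) {
    grid <- point_grid(dim(r$labelmap$labels), n_points = config$n_points,
                       offset = config$grid_offset)
    vf <- suppressWarnings(volume_fractions(classify_points(grid, r$labelmap)))
    af <- suppressWarnings(area_fraction(r$labelmap))
    list(G_vf = vf$G_vf, V_vf = vf$V_vf,
         gland_area_mm2 = af$gland_area_mm2,
         percent_positive = af$percent_positive)
  })
  finalize_study(per_image, cohort$truth, config, out_dir)
}

#' Run a full synthetic colocalization study
#'
#' Generates per-subject true colocalized fractions from the configured
#' group distributions, simulates about five dual-channel stacks per
#' subject, computes mean+2SD thresholds, R_p and Manders coefficients per
#' stack, collapses to subject medians, and runs the group tests.
#'
#' @inheritParams run_stereology_study
#' @return as \code{\link{run_stereology_study}}, with measures \code{R_p},
#'   \code{M_G}, \code{M_R}.
#' @export
run_coloc_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  recs <- list()
  truth <- list()
  sid <- 0L
  for (nm in names(config$coloc_groups)) {
    g <- config$coloc_groups[[nm]]
    conc <- g$concentration %||% 12
    for (s in seq_len(g$n)) {
      sid <- sid + 1L
      subject_id <- sprintf("S%03d", sid)
      f_true <- rbeta_loc(1, g$location, conc)
      n_img <- 1L + stats::rpois(1, config$images_per_subject - 1)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = subject_id, group = nm, true_fraction = f_true,
        n_images = n_img)
      for (im in seq_len(n_img)) {
        tmpl <- config$coloc_stack
        tmpl$coloc_fraction <- f_true
        tmpl$seed <- NULL
        sim <- sim_coloc_stack(tmpl)
        cr <- coloc_analysis(sim$stack)
        recs[[length(recs) + 1L]] <- list(
          subject_id = subject_id, group = nm,
          image_id = sprintf("%s_img%02d", subject_id, im),
          values = list(R_p = cr$R_p, M_G = cr$M_G, M_R = cr$M_R))
      }
    }
  }
  per_image <- long_rows(recs, function(r) r$values)
  finalize_study(per_image, do.call(rbind, truth), config, out_dir)
}

spec_reseeded <- function(spec) {
  # derive the sub-spec seed from the master-seeded RNG stream
  spec$seed <- sample.int(.Machine$integer.max, 1)
  spec
}

finalize_study <- function(per_image, truth, config, out_dir) {
  per_subject <- subject_summaries(per_image)
  per_subject$image_id <- "median"
  results <- list(
    per_image_long = per_image,
    per_subject_long = per_subject,
    group_summary = group_summary(per_subject),
    tests = run_group_tests(per_subject, config$alpha),
    truth = truth)
  if (!is.null(out_dir)) persist_outputs(results, config, out_dir)
  results
}
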