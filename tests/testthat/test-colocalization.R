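as_stack <- function(g, r) {
  d <- c(1, 1, length(g))
  dual_channel_stack(array(g, d), array(r, d))
}

test_that("Pearson coefficient hits the constructed reference cases", {
  g <- array(sample(0:200, 64, replace = TRUE), c(4, 4, 4))
  expect_equal(pearson_coloc(dual_channel_stack(g, g)), 1.0)
  expect_equal(pearson_coloc(dual_channel_stack(g, 255L - g)), -1.0)
  expect_equal(pearson_coloc(as_stack(c(0, 0, 1, 1), c(0, 1, 0, 1))), 0.0)
})

test_that("constant channels raise an undefined-correlation error", {
  g <- array(sample(0:200, 27, replace = TRUE), c(3, 3, 3))
  expect_error(pearson_coloc(dual_channel_stack(g, array(7L, dim(g)))),
               "undefined correlation")
  expect_error(pearson_coloc(dual_channel_stack(array(7L, dim(g)), g)),
               "undefined correlation")
})

test_that("Manders coefficients follow the intensity-ratio definition", {
  st <- as_stack(c(10, 0, 5), c(0, 0, 7))
  m <- manders_coeffs(st, threshold_green = 0, threshold_red = 0)
  expect_equal(m$M_G, 5 / 15)
  expect_equal(m$M_R, 1.0)
  expect_equal(m$G_colocalized, 5)
  expect_equal(m$R_colocalized, 7)

  # full overlap of supports
  st2 <- as_stack(c(10, 20, 0), c(5, 9, 0))
  m2 <- manders_coeffs(st2, 0, 0)
  expect_equal(m2$M_G, 1.0)
  expect_equal(m2$M_R, 1.0)

  # disjoint supports
  st3 <- as_stack(c(10, 0, 0), c(0, 0, 7))
  m3 <- manders_coeffs(st3, 0, 0)
  expect_equal(m3$M_G, 0.0)
  expect_equal(m3$M_R, 0.0)

  expect_error(manders_coeffs(st3, 10, 0), "green")
  expect_error(manders_coeffs(st3, 0, 7), "red")
})

test_that("coefficients match the loop oracle to 1e-12 on random stacks", {
  set.seed(31)
  for (i in 1:40) {
    st <- random_small_stack()
    thr_g <- runif(1, 0, 200)
    thr_r <- runif(1, 0, 200)
    or <- naive_coloc(st$green, st$red, thr_g, thr_r)
    expect_equal(pearson_coloc(st), or$R_p, tolerance = 1e-12)
    if (is.finite(or$M_G) && is.finite(or$M_R) &&
        sum(st$green[st$green > thr_g]) > 0 &&
        sum(st$red[st$red > thr_r]) > 0) {
      m <- manders_coeffs(st, thr_g, thr_r)
      expect_equal(m$M_G, or$M_G, tolerance = 1e-12)
      expect_equal(m$M_R, or$M_R, tolerance = 1e-12)
    }
  }
})

test_that("R_p is invariant under affine intensity rescaling", {
  set.seed(32)
  g <- array(sample(0:100, 125, replace = TRUE), c(5, 5, 5))
  r <- array(sample(0:100, 125, replace = TRUE), c(5, 5, 5))
  base <- pearson_coloc(dual_channel_stack(g, r))
  # a*I + b with a > 0 on either channel (kept inside 8-bit range)
  expect_equal(pearson_coloc(dual_channel_stack(2L * g + 30L, r)), base,
               tolerance = 1e-12)
  expect_equal(pearson_coloc(dual_channel_stack(g, 2L * r + 11L)), base,
               tolerance = 1e-12)
})

test_that("Manders coefficients are gain-invariant with co-scaled thresholds", {
  set.seed(33)
  g <- array(sample(0:120, 64, replace = TRUE), c(4, 4, 4))
  r <- array(sample(0:120, 64, replace = TRUE), c(4, 4, 4))
  m1 <- manders_coeffs(dual_channel_stack(g, r), 40, 50)
  m2 <- manders_coeffs(dual_channel_stack(2L * g, 2L * r), 80, 100)
  expect_equal(m1$M_G, m2$M_G, tolerance = 1e-12)
  expect_equal(m1$M_R, m2$M_R, tolerance = 1e-12)
  expect_true(m1$M_G >= 0 && m1$M_G <= 1)
  expect_true(m1$M_R >= 0 && m1$M_R <= 1)
})

test_that("coloc_map conserves voxels and places mass correctly", {
  g <- array(0L, c(2, 4, 4))
  st0 <- dual_channel_stack(g, g)
  cm0 <- coloc_map(st0)
  expect_equal(cm0$counts[1, 1], 32)
  expect_equal(sum(cm0$counts), 32)

  set.seed(34)
  gg <- array(sample(0:255, 250, replace = TRUE), c(10, 5, 5))
  cm1 <- coloc_map(dual_channel_stack(gg, gg))
  expect_equal(sum(cm1$counts), 250)
  # identical channels put all mass on the diagonal
  expect_equal(sum(diag(cm1$counts)), 250)

  rr <- array(sample(0:255, 250, replace = TRUE), c(10, 5, 5))
  cm2 <- coloc_map(dual_channel_stack(gg, rr), 100, 100)
  expect_equal(sum(cm2$counts), 250)
  expect_equal(sum(cm2$quadrants), 250)
})

test_that("coloc_analysis bundles thresholds and coefficients coherently", {
  sim <- sim_coloc_stack(coloc_sim_spec(shape = c(8, 32, 32), n_blobs = 3,
                                        blob_radius = 4, coloc_fraction = 0.6,
                                        seed = 35))
  cr <- coloc_analysis(sim$stack)
  expect_s3_class(cr, "coloc_result")
  expect_true(cr$R_p >= -1 && cr$R_p <= 1)
  expect_true(cr$M_G >= 0 && cr$M_G <= 1)
  expect_true(cr$M_R >= 0 && cr$M_R <= 1)
  expect_lte(cr$G_colocalized, sum(sim$stack$green))
  expect_lte(cr$R_colocalized, sum(sim$stack$red))
  expect_equal(cr$threshold_green,
               background_threshold(sim$stack$green)$threshold)
  expect_equal(cr$n_voxels, length(sim$stack$green))
})

test_that("group summaries use subject medians and interpolated quartiles", {
  per_image <- data.frame(
    subject_id = rep(c("S1", "S2", "S3"), each = 2),
    group = "HC",
    image_id = paste0("img", 1:6),
    measure = "R_p",
    value = c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3))
  subj <- subject_summaries(per_image)
  expect_equal(sort(subj$value), c(0.1, 0.2, 0.3))
  gs <- group_summary(subj)
  expect_equal(gs$median, 0.2)
  expect_equal(gs$q1, 0.15)
  expect_equal(gs$q3, 0.25)

  # one subject, one image: the group median is that image's value
  single <- data.frame(subject_id = "S1", group = "HC", image_id = "i",
                       measure = "R_p", value = 0.42)
  expect_equal(group_summary(subject_summaries(single))$median, 0.42)

  # identical groups summarize identically
  two <- rbind(transform(per_image, group = "A"),
               transform(per_image, group = "B"))
  gs2 <- group_summary(subject_summaries(two))
  expect_equal(gs2$median[1], gs2$median[2])
  expect_equal(gs2$q1[1], gs2$q1[2])
})
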