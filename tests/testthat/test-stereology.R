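test_that("systematic grids tile the image as expected", {
  g <- point_grid(c(900, 900), n_points = 81, offset = "centered")
  expect_equal(sort(unique(g$y)), 50 + 100 * (0:8))
  expect_equal(sort(unique(g$x)), 50 + 100 * (0:8))
  expect_equal(g$n_points, 81L)

  g1 <- point_grid(c(100, 60), n_points = 1, offset = "centered")
  expect_equal(g1$y, 50)
  expect_equal(g1$x, 30)

  expect_error(point_grid(c(100, 100), n_points = 80), "perfect square")
  expect_error(point_grid(c(5, 5), n_points = 81), "larger than image")
})

test_that("random-offset grids are reproducible and stay in bounds", {
  a <- point_grid(c(128, 128), offset = "random", seed = 5)
  b <- point_grid(c(128, 128), offset = "random", seed = 5)
  expect_identical(a$y, b$y)
  expect_identical(a$x, b$x)
  for (i in 1:20) {
    g <- point_grid(c(128, 128), offset = "random", seed = i)
    expect_true(all(g$py >= 1 & g$py <= 128))
    expect_true(all(g$px >= 1 & g$px <= 128))
  }
})

test_that("point classification agrees with direct pixel lookup", {
  lab <- matrix(1L, 90, 90)
  lab[, 1:45] <- 2L  # left half gland
  lm <- section_labelmap(lab, pixel_size = 1)
  grid <- point_grid(c(90, 90), offset = "centered")
  counts <- classify_points(grid, lm)
  expect_equal(sum(counts), 81)
  # oracle: enumerate the 81 lookups
  oracle <- table(factor(lab[cbind(grid$py, grid$px)], levels = 0:5))
  expect_equal(unname(counts), as.integer(oracle))
  # grid columns sit at pixels 6,16,...,86: 4 of 9 fall in the gland half
  expect_equal(unname(counts["gland"]), 36L)

  all_gland <- section_labelmap(matrix(2L, 64, 64))
  cg <- classify_points(point_grid(c(64, 64)), all_gland)
  expect_equal(unname(cg["gland"]), 81L)
})

test_that("volume fractions follow the point-count ratios", {
  counts <- c(background = 0L, tissue = 54L, gland = 18L,
              positive_gland = 9L, epithelium = 0L, positive_epithelium = 0L)
  vf <- volume_fractions(counts)
  expect_equal(vf$P_tissue, 81)
  expect_equal(vf$P_gland, 27)
  expect_equal(vf$P_vitronectin, 9)
  expect_equal(vf$G_vf, 1 / 3)
  expect_equal(vf$V_vf, 1 / 3)

  all_pos <- c(background = 0L, tissue = 0L, gland = 0L,
               positive_gland = 81L, epithelium = 0L,
               positive_epithelium = 0L)
  vf2 <- volume_fractions(all_pos)
  expect_equal(vf2$G_vf, 1)
  expect_equal(vf2$V_vf, 1)

  no_gland <- c(background = 40L, tissue = 41L, gland = 0L,
                positive_gland = 0L, epithelium = 0L,
                positive_epithelium = 0L)
  expect_warning(vf3 <- volume_fractions(no_gland), "V_vf is missing")
  expect_true(is.na(vf3$V_vf))
  expect_equal(vf3$G_vf, 0)
})

test_that("area fractions convert pixel counts to mm^2 and percent", {
  lab <- matrix(0L, 200, 200)
  lab[1:100, 1:100] <- 2L  # 10^4 gland pixels
  af <- area_fraction(section_labelmap(lab, pixel_size = 1))
  expect_equal(af$gland_area_mm2, 0.01)
  expect_equal(af$percent_positive, 0)

  lab[1:100, 1:100] <- 3L
  af2 <- area_fraction(section_labelmap(lab, pixel_size = 1))
  expect_equal(af2$percent_positive, 100)

  expect_warning(af3 <- area_fraction(section_labelmap(matrix(1L, 10, 10))),
                 "missing")
  expect_equal(af3$gland_area_mm2, 0)
  expect_true(is.na(af3$percent_positive))
})

test_that("subject summaries are medians, invariant to image order", {
  df <- data.frame(subject_id = "S1", group = "HC",
                   image_id = c("a", "b", "c"), measure = "V_vf",
                   value = c(0.1, 0.3, 0.5))
  expect_equal(subject_summaries(df)$value, 0.3)
  shuffled <- df[c(3, 1, 2), ]
  expect_equal(subject_summaries(shuffled), subject_summaries(df))
  one <- df[1, ]
  expect_equal(subject_summaries(one)$value, 0.1)
})

test_that("random-offset point counting is unbiased for area fractions", {
  sec <- sim_section_labelmap(section_sim_spec(shape = c(256, 256),
                                               gland_fraction = 0.35,
                                               positive_fraction = 0.25,
                                               seed = 61))
  lab <- sec$labelmap$labels
  exact <- sum(lab == 2L | lab == 3L) / sum(lab != 0L)
  set.seed(62)
  est <- replicate(1500, {
    counts <- classify_points(point_grid(c(256, 256), offset = "random"),
                              sec$labelmap)
    vf <- volume_fractions(counts)
    c(vf$P_gland / 81, vf$G_vf)
  })
  # raw hit fraction is unbiased for gland share of the whole image
  exact_whole <- sum(lab == 2L | lab == 3L) / length(lab)
  expect_lt(abs(mean(est[1, ]) - exact_whole), 0.01)
  # the tissue-referenced ratio estimator tracks the pixel-exact fraction
  expect_lt(abs(mean(est[2, ]) - exact), 0.015)
})

test_that("estimator variance shrinks as grid density grows", {
  sec <- sim_section_labelmap(section_sim_spec(shape = c(256, 256),
                                               gland_fraction = 0.4,
                                               positive_fraction = 0.3,
                                               seed = 63))
  set.seed(64)
  vars <- vapply(c(81, 324, 1296), function(np) {
    v <- replicate(400, {
      counts <- classify_points(
        point_grid(c(256, 256), n_points = np, offset = "random"),
        sec$labelmap)
      suppressWarnings(volume_fractions(counts)$V_vf)
    })
    var(v, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})
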