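test_that("diameter profile matches analytic band and disc geometry", {
  # horizontal band 11 px wide: EDT quantization allows mean in [10, 12]
  mask <- matrix(FALSE, 60, 200)
  mask[25:35, ] <- TRUE
  pr <- diameter_profile(as_fiber_mask(mask), cal1)
  expect_gte(mean(pr$diameter_um), 10)
  expect_lte(mean(pr$diameter_um), 12)
  expect_equal(stats::sd(pr$diameter_um), 0)

  # solid disc of radius r: skeleton collapses to the center, diameter ~ 2r
  g <- expand.grid(r = 1:80, c = 1:80)
  disc <- matrix(sqrt((g$r - 40)^2 + (g$c - 40)^2) <= 15, 80, 80)
  prd <- diameter_profile(as_fiber_mask(disc), cal1)
  expect_lte(nrow(prd), 3)
  expect_equal(mean(prd$diameter_um), 30, tolerance = 0.05)

  expect_error(diameter_profile(as_fiber_mask(matrix(FALSE, 5, 5)), cal1),
               "empty")
})

test_that("tapered band yields an increasing profile within quantization", {
  sp <- fiber_spec(width_um = function(x) 8 + 8 * x / 400)
  r <- render_pair(sp, shape = c(120, 400))
  f <- segment_fiber(r$pair$brightfield)
  pr <- diameter_profile(f, cal1)
  per_col <- tapply(pr$diameter_um, pr$col, mean)
  expect_gt(stats::cor(as.numeric(names(per_col)), per_col), 0.95)
  # monotone up to +-1 px quantization steps
  expect_true(all(diff(per_col) >= -1))
})

test_that("morphology summary arithmetic is exact on hand-computable profiles", {
  prof <- structure(data.frame(row = c(1, 1, 1), col = 1:3,
                               diameter_um = c(8, 10, 12)),
                    class = c("diameter_profile", "data.frame"))
  mask <- matrix(FALSE, 100, 100)
  mask[1:50, 1:100] <- TRUE  # 5000 px
  cal05 <- pixel_calibration(0.5)
  m <- summarize_morphology(prof, as_fiber_mask(mask), cal05)
  expect_equal(m$mean_diam_um, 10)
  expect_equal(m$min_diam_um, 8)
  expect_equal(m$sd_diam_um, 2)       # sample SD of {8, 10, 12}
  expect_equal(m$area_um2, 1250)      # 5000 px * 0.25 um^2
  expect_equal(m$n_axis_samples, 3L)

  prof0 <- prof
  prof0$diameter_um <- rep(10, 3)
  m0 <- summarize_morphology(prof0, as_fiber_mask(mask), cal05)
  expect_equal(m0$sd_diam_um, 0)
  expect_equal(m0$mean_diam_um, m0$min_diam_um)
})

test_that("lengths scale linearly and areas quadratically with calibration", {
  sp <- fiber_spec(width_um = 12)
  r <- render_pair(sp, shape = c(80, 200))
  f <- segment_fiber(r$pair$brightfield)
  m1 <- summarize_morphology(diameter_profile(f, cal1), f, cal1)
  cal2 <- pixel_calibration(2)
  m2 <- summarize_morphology(diameter_profile(f, cal2), f, cal2)
  expect_identical(m2$mean_diam_um, 2 * m1$mean_diam_um)
  expect_identical(m2$min_diam_um, 2 * m1$min_diam_um)
  expect_identical(m2$area_um2, 4 * m1$area_um2)
})

test_that("diameter is rotation-robust (not an axis-aligned measure)", {
  n <- 220
  th <- 30 * pi / 180
  g <- expand.grid(r = 1:n, c = 1:n)
  d <- abs(-sin(th) * (g$c - n / 2) + cos(th) * (g$r - n / 2))
  mask <- matrix(d <= 6, n, n)  # width 12 px band at 30 degrees
  pr <- diameter_profile(as_fiber_mask(mask), cal1)
  expect_lt(abs(mean(pr$diameter_um) - 12) / 12, 0.05)
})

test_that("sinusoidal width is recovered and stable to threshold perturbation", {
  sp <- fiber_spec(width_um = function(x) 10 + 3 * sin(2 * pi * x / 100))
  r <- render_pair(sp, shape = c(120, 400))
  f <- segment_fiber(r$pair$brightfield)
  pr <- diameter_profile(f, cal1)
  expect_lt(abs(mean(pr$diameter_um) - r$truth$mean_diameter_um) /
              r$truth$mean_diameter_um, 0.05)
  expect_lte(abs(min(pr$diameter_um) - r$truth$min_diameter_um), 1)

  # noise-free fiber: +-1 threshold change leaves the mean within 1 px
  for (t in c(147L, 149L)) {
    ft <- segment_fiber(r$pair$brightfield, threshold_spec("fixed", t))
    prt <- diameter_profile(ft, cal1)
    expect_lte(abs(mean(prt$diameter_um) - mean(pr$diameter_um)), 1)
  }
})
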