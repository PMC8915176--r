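frame_rows <- function(fiber_id, diam, int, n_axis, n_px, strength = NA_real_) {
  data.frame(fiber_id = fiber_id, mean_diam_um = diam, mean_int_full = int,
             n_axis_samples = n_axis, n_fiber_px = n_px,
             measured_strength = strength, stringsAsFactors = FALSE)
}

test_that("fiber summaries pool frames by their pixel populations", {
  # single frame: NI is a plain ratio
  s1 <- summarize_fiber(frame_rows("a", 4, 120, 100, 1000))
  expect_equal(s1$normalized_intensity, 30)

  # equal weights: pooled means are frame means
  s2 <- summarize_fiber(frame_rows("a", c(4, 6), c(100, 140),
                                   c(50, 50), c(500, 500)))
  expect_equal(s2$mean_diameter, 5)
  expect_equal(s2$mean_intensity, 120)
  expect_equal(s2$normalized_intensity, 24)

  # weighting oracle: pooled mean equals the concatenated-population mean
  pop1 <- rep(90, 2000)   # frame with 10x the pixels
  pop2 <- rep(190, 200)
  fr <- frame_rows("a", c(5, 5), c(mean(pop1), mean(pop2)),
                   c(100, 100), c(length(pop1), length(pop2)))
  s3 <- summarize_fiber(fr)
  expect_equal(s3$mean_intensity, mean(c(pop1, pop2)))
  s3e <- summarize_fiber(fr, weighting = "equal")
  expect_equal(s3e$mean_intensity, 140)

  expect_error(summarize_fiber(frame_rows(c("a", "b"), c(4, 5), c(1, 2),
                                          c(1, 1), c(1, 1))),
               "single fiber")
})

test_that("a noise-free linear relation is fitted exactly", {
  co <- generate_cohort(10, intercept = 5, slope = 2, noise_sd = 0, seed = 2)
  m <- fit_strength_model(co$summaries)
  expect_equal(m$intercept, 5, tolerance = 1e-9)
  expect_equal(m$slope, 2, tolerance = 1e-9)
  expect_equal(m$pearson_r_abs, 1, tolerance = 1e-12)
  expect_equal(m$residual_sd, 0, tolerance = 1e-9)
  expect_identical(m$model_form, "linear")

  rep <- predict_strength(m, co$summaries)
  expect_equal(rep$mean_percent_difference, 0, tolerance = 1e-8)
  expect_equal(rep$pearson_r_abs_pred_vs_meas, 1, tolerance = 1e-12)
})

test_that("prediction arithmetic and degenerate inputs behave as specified", {
  m <- structure(list(intercept = 5, slope = 2, quad = NULL, n_fit = 10,
                      pearson_r_abs = 1, residual_sd = 0,
                      model_form = "linear", lr_test_p = NA_real_,
                      predictor = "normalized_intensity",
                      setup = NA_character_),
                 class = "strength_model")
  s <- data.frame(fiber_id = c("a", "b"),
                  normalized_intensity = c(10, NA),
                  measured_strength = c(NA, NA))
  expect_equal(predict_strength(m, s)$fibers$predicted_strength[1], 25)

  s2 <- data.frame(fiber_id = c("a", "b"),
                   normalized_intensity = c(2.5, 7.5),
                   measured_strength = c(10, 25))
  r2 <- predict_strength(m, s2)  # predicted {10, 20}
  expect_equal(r2$fibers$percent_difference, c(0, 20))
  expect_equal(r2$mean_percent_difference, 10)

  expect_error(predict_strength(list(), s2), "fitted strength_model")
  const <- data.frame(fiber_id = letters[1:4], mean_diameter = rep(5, 4),
                      normalized_intensity = 1:4,
                      measured_strength = c(10, 20, 30, 40))
  expect_error(diameter_only_baseline(const), "zero variance")
  expect_error(fit_strength_model(const[1:2, ]), "at least 3")
})

test_that("|r| is affine-invariant and OLS residuals are orthogonal", {
  co <- generate_cohort(40, seed = 8)
  s <- co$summaries
  r0 <- fit_strength_model(s)$pearson_r_abs
  set.seed(9)
  for (i in 1:5) {
    a <- runif(1, -50, 50); b <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    s2 <- s
    s2$normalized_intensity <- a + b * s$normalized_intensity
    expect_equal(fit_strength_model(s2)$pearson_r_abs, r0, tolerance = 1e-12)
  }
  m <- fit_strength_model(s)
  resid <- s$measured_strength - (m$intercept + m$slope * s$normalized_intensity)
  scale <- sqrt(sum(s$normalized_intensity^2)) * sqrt(sum(resid^2))
  expect_lt(abs(sum(resid * s$normalized_intensity)) / scale, 1e-8)
})

test_that("diameter-only reference is beaten by the NI model on NI-driven cohorts", {
  wins <- 0L
  for (i in 1:25) {
    co <- generate_cohort(30, seed = 1000 + i)
    ni <- fit_strength_model(co$summaries)$pearson_r_abs
    d <- diameter_only_baseline(co$summaries)$model$pearson_r_abs
    wins <- wins + (ni > d)
  }
  expect_gte(wins, 24L)  # the full 200-rep property lives in the acceptance suite
})

test_that("models are setup-tagged and refuse silent cross-setup prediction", {
  co <- generate_cohort(20, seed = 4)
  m <- fit_strength_model(co$summaries, setup = "setup1")
  s2 <- co$summaries
  attr(s2, "setup") <- "setup2"
  expect_error(predict_strength(m, s2), "exposure-specific")
  expect_silent(predict_strength(m, s2, allow_cross_setup = TRUE))

  # JSON round trip preserves the model
  dir <- withr_local_tempdir()
  p <- file.path(dir, "model.json")
  write_strength_model(m, p)
  m2 <- read_strength_model(p)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(m2$slope, m$slope, tolerance = 1e-12)
  expect_identical(m2$setup, m$setup)
  r1 <- predict_strength(m, co$summaries)
  r2 <- predict_strength(m2, co$summaries)
  expect_equal(r2$fibers$predicted_strength, r1$fibers$predicted_strength,
               tolerance = 1e-12)
})
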