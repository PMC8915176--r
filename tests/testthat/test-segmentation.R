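test_that("Yen threshold splits isolated modes and matches the brute-force oracle", {
  h <- numeric(256)
  h[50 + 1] <- 400
  h[200 + 1] <- 600
  t <- yen_threshold(h)
  expect_gt(t, 50)
  expect_lt(t, 200)

  # exhaustive-criterion oracle over 100 random histograms
  set.seed(101)
  for (i in 1:100) {
    h <- random_histogram()
    expect_identical(yen_threshold(h), yen_oracle(h))
  }

  expect_error(yen_threshold({h1 <- numeric(256); h1[10] <- 5; h1}),
               "no threshold separates")
})

test_that("Yen threshold separates a noisy dark-fiber/bright-background image", {
  # comparable class masses: Yen's criterion is entropy-driven, so a heavily
  # unbalanced histogram pulls the split toward the dominant mode (the reason
  # practice locks in a fixed threshold after auto-thresholding a new setup)
  sp <- fiber_spec(width_um = 60, bf_fiber_level = 60,
                   bf_background_level = 220, noise_sd = 5, seed = 3)
  r <- render_pair(sp, shape = c(120, 400))
  t <- yen_threshold(r$pair$brightfield)
  fiber_px <- r$pair$brightfield[r$truth$mask]
  bg_px <- r$pair$brightfield[!r$truth$mask]
  expect_gt(mean(fiber_px < t), 0.99)  # generating dark class recovered
  expect_gt(mean(bg_px >= t), 0.99)    # generating bright class recovered
})

test_that("fiber segmentation recovers a dark band and filters specks", {
  sp <- fiber_spec(width_um = 12, bf_fiber_level = 60,
                   bf_background_level = 220)
  r <- render_pair(sp, shape = c(100, 300))
  f <- segment_fiber(r$pair$brightfield, threshold_spec("fixed", 148L))
  expect_s3_class(f, "fiber_mask")
  expect_equal(f$threshold_used, 148L)
  truth_area <- sum(r$truth$mask)
  expect_lt(abs(sum(f$mask) - truth_area) / truth_area, 0.02)

  # a 5-px dark speck below min_area_px is excluded, the band retained
  bf <- r$pair$brightfield
  bf[5:9, 10] <- 20L
  f2 <- segment_fiber(bf, threshold_spec("fixed", 148L), min_area_px = 50L)
  expect_identical(f2$mask, f$mask)

  expect_error(
    segment_fiber(matrix(220L, 50, 50), threshold_spec("fixed", 148L)),
    "no fiber detected")
})

test_that("auto mode records the Yen threshold it used", {
  sp <- fiber_spec(width_um = 15, noise_sd = 4, seed = 9)
  r <- render_pair(sp, shape = c(100, 300))
  f <- segment_fiber(r$pair$brightfield, threshold_spec("auto_yen"))
  expect_identical(f$threshold_used, yen_threshold(r$pair$brightfield))
  expect_lt(abs(sum(f$mask) - sum(r$truth$mask)) / sum(r$truth$mask), 0.02)
})

test_that("fixed-threshold segmentation is pure and monotone in the threshold", {
  sp <- fiber_spec(width_um = 10, noise_sd = 5, seed = 7)
  r <- render_pair(sp, shape = c(80, 200))
  f1 <- segment_fiber(r$pair$brightfield, threshold_spec("fixed", 148L))
  f2 <- segment_fiber(r$pair$brightfield, threshold_spec("fixed", 148L))
  expect_identical(f1, f2)  # bit-exact purity

  # raising the threshold never shrinks the foreground before selection
  bf <- r$pair$brightfield
  fgs <- lapply(c(60L, 100L, 148L, 200L, 240L), function(t) bf < t)
  for (i in seq_len(length(fgs) - 1L)) {
    expect_true(all(fgs[[i + 1L]][fgs[[i]]]))  # nested foreground sets
  }
})

test_that("bright-area segmentation is a strict masked comparison", {
  sp <- fiber_spec(width_um = 14, pom_base_level = 80,
                   patches = data.frame(x0_um = c(30, 120, 200),
                                        length_um = c(20, 30, 25),
                                        level = 210))
  r <- render_pair(sp, shape = c(100, 300))
  f <- segment_fiber(r$pair$brightfield)

  # uniformly dark POM inside the fiber -> empty bright mask
  b0 <- segment_bright_areas(matrix(0L, 100, 300), f, 100L)
  expect_false(any(b0$mask))

  # uniformly saturated POM -> bright mask equals the fiber mask
  b1 <- segment_bright_areas(matrix(255L, 100, 300), f, 100L)
  expect_identical(b1$mask, f$mask)

  # three rectangular patches above threshold -> count matches the inventory
  b <- segment_bright_areas(r$pair$pom, f, 150L)
  expect_true(all(f$mask[b$mask]))  # subset invariant
  expect_equal(sum(b$mask), sum(r$truth$patch_inventory$area_px))

  expect_error(segment_bright_areas(matrix(0L, 10, 10), f, 150L),
               "dimensions differ")
})
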