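make_scene <- function() {
  sp <- fiber_spec(width_um = 14, pom_base_level = 90,
                   patches = data.frame(x0_um = c(40, 130, 220),
                                        length_um = c(25, 30, 20),
                                        level = 220),
                   seed = 5)
  r <- render_pair(sp, shape = c(100, 300))
  f <- segment_fiber(r$pair$brightfield)
  list(r = r, f = f)
}

test_that("intensity statistics are masked, exact, and background-invariant", {
  s <- make_scene()
  # constant field inside the mask
  pom <- matrix(0L, 100, 300)
  pom[s$f$mask] <- 100L
  st <- intensity_stats(pom, s$f)
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)

  # hand arithmetic on a 4-pixel mask: {0, 0, 200, 200}
  m4 <- matrix(FALSE, 4, 4)
  m4[1, 1:4] <- TRUE
  p4 <- matrix(0L, 4, 4)
  p4[1, ] <- c(0L, 0L, 200L, 200L)
  st4 <- intensity_stats(p4, as_fiber_mask(m4))
  expect_equal(st4$mean, 100)
  expect_equal(st4$sd, sqrt(4 * 100^2 / 3), tolerance = 1e-12)  # 115.47

  # generator ground truth within 1 intensity unit (noise-free render)
  st_true <- intensity_stats(s$r$pair$pom, as_fiber_mask(s$r$truth$mask))
  expect_lt(abs(st_true$mean - s$r$truth$mean_pom_intensity), 1)

  # changing background pixels changes nothing
  pom2 <- s$r$pair$pom
  pom2[!s$f$mask] <- 255L
  expect_identical(intensity_stats(pom2, s$f),
                   intensity_stats(s$r$pair$pom, s$f))
})

test_that("bright segments are counted, sized, and bounded correctly", {
  # two disjoint rectangles of 20 and 50 px inside a square fiber
  mask <- matrix(FALSE, 40, 60)
  mask[5:35, 5:55] <- TRUE
  pom <- matrix(0L, 40, 60)
  pom[10:13, 10:14] <- 200L   # 20 px
  pom[20:24, 30:39] <- 230L   # 50 px
  f <- as_fiber_mask(mask)
  b <- segment_bright_areas(pom, f, 150L)
  out <- analyze_bright_segments(b, pom, cal1)
  expect_equal(out$summary$n_segments, 2L)
  expect_equal(out$summary$seg_area_min_um2, 20)
  expect_equal(out$summary$seg_area_max_um2, 50)
  expect_equal(out$summary$seg_area_mean_um2, 35)
  expect_equal(sort(out$segments$mean_intensity), c(200, 230))

  # segment areas partition the bright mask: sum = bright_fraction * fiber area
  expect_identical(sum(out$segments$area_px), sum(b$mask))
  expect_equal(sum(out$segments$area_um2),
               out$summary$bright_fraction * sum(mask) * 1^2)

  # every bright pixel strictly exceeds the cut-off
  expect_gt(out$summary$mean_int_bright, b$bright_threshold)
  expect_true(all(pom[b$mask] > b$bright_threshold))
})

test_that("empty bright mask yields zero count and explicit undefined stats", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:15, 5:15] <- TRUE
  pom <- matrix(10L, 20, 20)
  b <- segment_bright_areas(pom, as_fiber_mask(mask), 150L)
  out <- analyze_bright_segments(b, pom, cal1)
  expect_equal(out$summary$n_segments, 0L)
  expect_equal(out$summary$bright_fraction, 0)
  expect_true(is.na(out$summary$mean_int_bright))
  expect_true(is.na(out$summary$seg_area_mean_um2))
  expect_equal(nrow(out$segments), 0L)
})

test_that("generator patch inventory is reproduced segment for segment", {
  s <- make_scene()
  b <- segment_bright_areas(s$r$pair$pom, s$f, 150L)
  out <- analyze_bright_segments(b, s$r$pair$pom, cal1)
  inv <- s$r$truth$patch_inventory
  expect_equal(out$summary$n_segments, nrow(inv))
  expect_equal(sort(out$segments$area_px), sort(inv$area_px))
  expect_equal(out$summary$seg_area_min_um2, min(inv$area_um2))
  expect_equal(out$summary$seg_area_max_um2, max(inv$area_um2))

  full <- birefringence_result(s$r$pair$pom, s$f, b, cal1)
  expect_equal(full$n_segments, nrow(inv))
  expect_equal(full$bright_fraction, sum(b$mask) / sum(s$f$mask))
  # 8-connectivity: a diagonal-only join still forms one segment
  dm <- matrix(FALSE, 10, 10)
  dm[3, 3] <- dm[4, 4] <- TRUE
  dp <- matrix(0L, 10, 10); dp[dm] <- 200L
  fb <- as_fiber_mask(matrix(TRUE, 10, 10))
  o2 <- analyze_bright_segments(segment_bright_areas(dp, fb, 150L), dp, cal1)
  expect_equal(o2$summary$n_segments, 1L)
})
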