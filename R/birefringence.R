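#' Full-fiber POM intensity statistics
#'
#' Mean and sample standard deviation of the polarized-light intensity over
#' the fiber-mask pixels only; background pixels never enter the statistics.
#' At fixed exposure and crossed polarizers this intensity is the working
#' proxy for birefringence, i.e. for the degree of molecular alignment in the
#' fiber.
#'
#' @param pom Integer matrix, same dimensions as the fiber mask.
#' @param fiber A `fiber_mask`.
#' @return List with `mean` and `sd` (sample SD; 0 for a single-pixel mask).
#' @export
intensity_stats <- function(pom, fiber) {
  stopifnot(inherits(fiber, "fiber_mask"))
  if (!is.matrix(pom) || !identical(dim(pom), dim(fiber$mask))) {
    stop("POM frame and fiber mask dimensions differ", call. = FALSE)
  }
  v <- pom[fiber$mask]
  if (length(v) == 0L) stop("empty fiber mask", call. = FALSE)
  list(mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Bright-segment decomposition of the fiber
#'
#' Enumerates the 8-connected components of the bright-area mask (the fiber
#' pixels whose POM intensity exceeds the cut-off) and reports per-segment
#' area, mean intensity and centroid, plus the summary statistics: segment
#' count, mean/min/max segment area, the bright fraction of the fiber, and the
#' mean intensity over all bright pixels. When no pixel is bright the segment
#' statistics are `NA` (explicit nulls in CSV output) — never 0, which would
#' bias any aggregation.
#'
#' @param bright A [segment_bright_areas()] result.
#' @param pom Integer matrix, same dimensions as the masks.
#' @param calibration A [pixel_calibration()].
#' @return List with `segments` (data frame: `segment_id`, `area_px`,
#'   `area_um2`, `mean_intensity`, `centroid_row`, `centroid_col`) and
#'   `summary` (one-row data frame: `mean_int_bright`, `n_segments`,
#'   `seg_area_mean_um2`, `seg_area_min_um2`, `seg_area_max_um2`,
#'   `bright_fraction`).
#' @export
analyze_bright_segments <- function(bright, pom, calibration) {
  stopifnot(inherits(bright, "bright_area_mask"),
            inherits(calibration, "pixel_calibration"))
  if (!is.matrix(pom) || !identical(dim(pom), dim(bright$mask))) {
    stop("POM frame and bright mask dimensions differ", call. = FALSE)
  }
  px2 <- calibration$microns_per_pixel^2
  fiber_px <- sum(bright$parent$mask)
  n_bright <- sum(bright$mask)
  if (n_bright == 0L) {
    return(list(
      segments = data.frame(segment_id = integer(), area_px = integer(),
                            area_um2 = numeric(), mean_intensity = numeric(),
                            centroid_row = numeric(), centroid_col = numeric()),
      summary = data.frame(mean_int_bright = NA_real_, n_segments = 0L,
                           seg_area_mean_um2 = NA_real_,
                           seg_area_min_um2 = NA_real_,
                           seg_area_max_um2 = NA_real_,
                           bright_fraction = 0)
    ))
  }
  lab <- label_components8(bright$mask)
  ids <- seq_len(max(lab))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  vals <- pom[lab > 0]
  area_px <- tabulate(l, nbins = max(lab))
  segments <- data.frame(
    segment_id = ids,
    area_px = area_px,
    area_um2 = area_px * px2,
    mean_intensity = as.numeric(tapply(vals, l, mean)),
    centroid_row = as.numeric(tapply(idx[, 1], l, mean)),
    centroid_col = as.numeric(tapply(idx[, 2], l, mean))
  )
  summary <- data.frame(
    mean_int_bright = mean(vals),
    n_segments = length(ids),
    seg_area_mean_um2 = mean(segments$area_um2),
    seg_area_min_um2 = min(segments$area_um2),
    seg_area_max_um2 = max(segments$area_um2),
    bright_fraction = n_bright / fiber_px
  )
  # bookkeeping identity: segment areas partition the bright mask
  stopifnot(sum(segments$area_px) == n_bright,
            isTRUE(all.equal(summary$bright_fraction * fiber_px, n_bright)))
  list(segments = segments, summary = summary)
}

#' Per-frame birefringence summary
#'
#' Convenience wrapper combining [intensity_stats()] and
#' [analyze_bright_segments()] into the per-frame POM output row, including
#' the generic combination parameters derived from the bright-area
#' decomposition (these are a documented non-canonical set, see Details).
#'
#' @details The combination parameters emitted are `bright_fraction`,
#' `bright_intensity_product` (bright fraction x mean bright intensity) and
#' `intensity_area_product` (full-fiber mean intensity x fiber area, µm²
#' intensity units). They summarize how much of the fiber is strongly
#' birefringent and how intense those regions are; the headline predictor
#' (mean intensity / mean diameter) is computed at the fiber level by
#' [summarize_fiber()].
#'
#' @param pom Integer matrix.
#' @param fiber A `fiber_mask`.
#' @param bright A `bright_area_mask` derived from `fiber`.
#' @param calibration A [pixel_calibration()].
#' @param fiber_area_um2 Fiber area, if already computed (else from the mask).
#' @return One-row data frame of class `birefringence_result`.
#' @export
birefringence_result <- function(pom, fiber, bright, calibration,
                                 fiber_area_um2 = NULL) {
  st <- intensity_stats(pom, fiber)
  seg <- analyze_bright_segments(bright, pom, calibration)
  if (is.null(fiber_area_um2)) {
    fiber_area_um2 <- sum(fiber$mask) * calibration$microns_per_pixel^2
  }
  s <- seg$summary
  res <- data.frame(
    mean_int_full = st$mean,
    sd_int_full = st$sd,
    mean_int_bright = s$mean_int_bright,
    n_segments = s$n_segments,
    seg_area_mean_um2 = s$seg_area_mean_um2,
    seg_area_min_um2 = s$seg_area_min_um2,
    seg_area_max_um2 = s$seg_area_max_um2,
    bright_fraction = s$bright_fraction,
    bright_threshold = bright$bright_threshold,
    bright_intensity_product = s$bright_fraction *
      ifelse(is.na(s$mean_int_bright), NA_real_, s$mean_int_bright),
    intensity_area_product = st$mean * fiber_area_um2
  )
  class(res) <- c("birefringence_result", "data.frame")
  attr(res, "segments") <- seg$segments
  res
}
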