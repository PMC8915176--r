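#' Fiber-level summary from per-frame results
#'
#' Pools the per-frame morphology and POM metrics of one fiber into the
#' fiber-level quantities the strength model consumes, in particular the
#' normalized intensity NI = pooled mean POM intensity / pooled mean diameter
#' (intensity units per µm), the diameter-normalized birefringence predictor.
#'
#' Pooling is weighted by default: the mean diameter weights each frame by its
#' number of medial-axis samples and the mean intensity by its number of fiber
#' pixels, so that the pooled values equal the statistics that would be
#' obtained from the concatenated per-pixel populations. Unweighted frame
#' averaging is available via `weighting = "equal"`.
#'
#' @param frames Data frame of per-frame rows for one fiber with columns
#'   `fiber_id`, `mean_diam_um`, `n_axis_samples`, `mean_int_full`,
#'   `n_fiber_px`, and optionally `measured_strength`.
#' @param weighting `"samples"` (default) or `"equal"`.
#' @return One-row data frame of class `fiber_summary` with columns
#'   `fiber_id`, `mean_diameter`, `mean_intensity`, `normalized_intensity`,
#'   `n_frames`, `measured_strength` (NA when absent).
#' @export
summarize_fiber <- function(frames, weighting = c("samples", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(frames))
  if (nrow(frames) == 0L) stop("no frames to summarize", call. = FALSE)
  if (length(unique(frames$fiber_id)) != 1L) {
    stop("summarize_fiber expects frames of a single fiber", call. = FALSE)
  }
  wd <- if (weighting == "samples") frames$n_axis_samples else rep(1, nrow(frames))
  wi <- if (weighting == "samples") frames$n_fiber_px else rep(1, nrow(frames))
  mean_diameter <- stats::weighted.mean(frames$mean_diam_um, wd)
  mean_intensity <- stats::weighted.mean(frames$mean_int_full, wi)
  strength <- if ("measured_strength" %in% names(frames)) {
    frames$measured_strength[1]
  } else NA_real_
  res <- data.frame(
    fiber_id = frames$fiber_id[1],
    mean_diameter = mean_diameter,
    mean_intensity = mean_intensity,
    normalized_intensity = mean_intensity / mean_diameter,
    n_frames = nrow(frames),
    measured_strength = strength,
    stringsAsFactors = FALSE
  )
  class(res) <- c("fiber_summary", "data.frame")
  res
}

#' Calibrate the linear strength model
#'
#' Ordinary least squares of measured engineering strength (MPa) on the
#' normalized intensity (or another single predictor). A quadratic nested
#' model is also fitted and compared by a likelihood-ratio test with statistic
#' `n * ln(RSS_linear / RSS_quadratic)` referred to chi-square with one degree
#' of freedom; the simpler linear model is retained unless the test rejects at
#' the 0.05 level. The Pearson correlation between predictor and strength is
#' reported as an absolute value — the magnitude, regardless of sign, is what
#' informs on the degree of correlation.
#'
#' @param summaries Data frame of fiber summaries with `measured_strength`.
#' @param predictor Column used as the predictor, default
#'   `"normalized_intensity"`.
#' @param allow_quadratic_check Run the quadratic comparison (needs >= 5
#'   fibers so the quadratic fit has residual degrees of freedom).
#' @param setup Optional acquisition-setup tag stored in the model. NI values
#'   are exposure-specific, so a model calibrated on one setup must not be
#'   applied to images from another.
#' @return Object of class `strength_model`: intercept, slope (and `quad` if
#'   the quadratic form is retained), `n_fit`, `pearson_r_abs`, `residual_sd`,
#'   `model_form`, `lr_test_p`, `predictor`, `setup`.
#' @export
fit_strength_model <- function(summaries,
                               predictor = "normalized_intensity",
                               allow_quadratic_check = TRUE,
                               setup = NA_character_) {
  stopifnot(is.data.frame(summaries), predictor %in% names(summaries))
  ok <- is.finite(summaries[[predictor]]) &
    is.finite(summaries$measured_strength)
  x <- summaries[[predictor]][ok]
  y <- summaries$measured_strength[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 fibers with measured strength",
                   call. = FALSE)
  if (stats::var(x) == 0) {
    stop(sprintf("degenerate predictor: %s has zero variance", predictor),
         call. = FALSE)
  }
  lin <- stats::lm(y ~ x)
  lr_p <- NA_real_
  model_form <- "linear"
  quad_coef <- NULL
  if (allow_quadratic_check && n >= 5L) {
    quad <- stats::lm(y ~ x + I(x^2))
    rss_lin <- sum(stats::residuals(lin)^2)
    rss_quad <- sum(stats::residuals(quad)^2)
    if (rss_quad > 0) {
      lr_stat <- n * log(rss_lin / rss_quad)
      lr_p <- stats::pchisq(lr_stat, df = 1, lower.tail = FALSE)
      if (!is.na(lr_p) && lr_p < 0.05) {
        model_form <- "quadratic"
        quad_coef <- unname(stats::coef(quad))
      }
    }
  }
  structure(
    list(intercept = unname(stats::coef(lin)[1]),
         slope = unname(stats::coef(lin)[2]),
         quad = quad_coef,
         n_fit = n,
         pearson_r_abs = abs(stats::cor(x, y)),
         residual_sd = sqrt(sum(stats::residuals(lin)^2) / (n - 2L)),
         model_form = model_form,
         lr_test_p = lr_p,
         predictor = predictor,
         setup = setup),
    class = "strength_model"
  )
}

#' @export
print.strength_model <- function(x, ...) {
  cat(sprintf(
    "strength_model (%s, predictor = %s): strength = %.4g %+.4g * %s\n",
    x$model_form, x$predictor, x$intercept, x$slope, x$predictor))
  cat(sprintf("  n = %d, |r| = %.3f, residual SD = %.3g MPa, LR p = %s\n",
              x$n_fit, x$pearson_r_abs, x$residual_sd,
              ifelse(is.na(x$lr_test_p), "NA", sprintf("%.3f", x$lr_test_p))))
  invisible(x)
}

#' Predict fiber strength from a calibrated model
#'
#' Evaluates the calibrated model on new fiber summaries (blind prediction).
#' When measured strengths are present, per-fiber percent differences
#' `|predicted - measured| / measured * 100` and their mean (the mean absolute
#' percent error) plus the absolute Pearson correlation between predicted and
#' measured strength are reported.
#'
#' @param model A [fit_strength_model()] result.
#' @param summaries Data frame of fiber summaries.
#' @param allow_cross_setup Override the guard that refuses to apply a model
#'   calibrated on one acquisition setup to summaries tagged with another.
#' @return Object of class `prediction_report`: data frame `fibers`
#'   (`fiber_id`, `predicted_strength`, `measured_strength`,
#'   `percent_difference`), plus `mean_percent_difference` and
#'   `pearson_r_abs_pred_vs_meas` (NA when no measured values).
#' @export
predict_strength <- function(model, summaries, allow_cross_setup = FALSE) {
  if (!inherits(model, "strength_model")) {
    stop("model must be a fitted strength_model", call. = FALSE)
  }
  stopifnot(is.data.frame(summaries), model$predictor %in% names(summaries))
  setup_new <- attr(summaries, "setup")
  if (!allow_cross_setup && !is.na(model$setup) && !is.null(setup_new) &&
      !is.na(setup_new) && !identical(setup_new, model$setup)) {
    stop(sprintf(
      "model was calibrated on setup '%s' but summaries are from setup '%s'; NI is exposure-specific (use allow_cross_setup = TRUE to override)",
      model$setup, setup_new), call. = FALSE)
  }
  x <- summaries[[model$predictor]]
  pred <- model$intercept + model$slope * x
  if (identical(model$model_form, "quadratic")) {
    pred <- model$quad[1] + model$quad[2] * x + model$quad[3] * x^2
  }
  meas <- if ("measured_strength" %in% names(summaries)) {
    summaries$measured_strength
  } else rep(NA_real_, length(pred))
  pdiff <- ifelse(is.finite(meas) & meas != 0,
                  abs(pred - meas) / abs(meas) * 100, NA_real_)
  fibers <- data.frame(fiber_id = summaries$fiber_id,
                       predicted_strength = pred,
                       measured_strength = meas,
                       percent_difference = pdiff,
                       stringsAsFactors = FALSE)
  have <- is.finite(meas)
  structure(
    list(fibers = fibers,
         mean_percent_difference = if (any(have)) mean(pdiff[have]) else NA_real_,
         pearson_r_abs_pred_vs_meas = if (sum(have) >= 3L) {
           abs(stats::cor(pred[have], meas[have]))
         } else NA_real_),
    class = "prediction_report"
  )
}

#' Diameter-only reference model
#'
#' Fits and self-evaluates a strength model that uses the mean diameter as the
#' sole predictor. This is the reference the normalized-intensity predictor is
#' judged against: for thin fibers the diameter–strength correlation is weak,
#' and the NI model should beat this baseline in |r|.
#'
#' @param summaries Fiber summaries with `measured_strength`.
#' @param setup Optional setup tag.
#' @return List with `model` (a `strength_model` on `mean_diameter`) and
#'   `report` (self-prediction `prediction_report`).
#' @export
diameter_only_baseline <- function(summaries, setup = NA_character_) {
  model <- fit_strength_model(summaries, predictor = "mean_diameter",
                              setup = setup)
  list(model = model,
       report = predict_strength(model, summaries))
}

#' Serialize / restore a strength model
#'
#' @param model A `strength_model`.
#' @param path JSON path.
#' @return `write_strength_model` invisibly returns `path`;
#'   `read_strength_model` returns the restored `strength_model`.
#' @export
write_strength_model <- function(model, path) {
  stopifnot(inherits(model, "strength_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_strength_model
#' @export
read_strength_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: %s", path), call. = FALSE)
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("intercept", "slope", "n_fit", "model_form", "predictor")
  if (!all(need %in% names(m))) {
    stop("not a strength model JSON (missing fields)", call. = FALSE)
  }
  for (nm in c("lr_test_p", "setup")) if (is.null(m[[nm]])) m[nm] <- list(NA)
  structure(m, class = "strength_model")
}
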