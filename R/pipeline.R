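#' Run configuration for the batch pipeline
#'
#' Bundles every setting of an analysis run: input/output paths, pixel
#' calibration, the brightfield threshold specification, the POM bright-area
#' cut-off, the component area filter, the frame-pooling mode and an
#' acquisition-setup tag. All thresholds are recorded in the outputs and the
#' run manifest, so a table can always be traced back to its settings.
#'
#' @param input_dir Directory of paired micrographs (see [discover_series()]).
#' @param output_dir Directory for the CSV/JSON outputs (created if missing).
#' @param calibration A [pixel_calibration()].
#' @param bf_threshold A [threshold_spec()] for the brightfield segmentation.
#' @param bright_threshold POM bright-area cut-off (0..255).
#' @param min_area_px Minimum fiber-component area in pixels.
#' @param prune_px Skeleton spur-pruning iterations.
#' @param weighting Frame-pooling mode for [summarize_fiber()].
#' @param setup Acquisition setup tag stored in models and summaries.
#' @param seed Integer seed recorded in the manifest.
#' @param pattern,modality_tokens Filename pairing rule for [discover_series()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       calibration = pixel_calibration(1),
                       bf_threshold = threshold_spec("fixed", 148L),
                       bright_threshold = 150L,
                       min_area_px = 50L, prune_px = 10L,
                       weighting = "samples",
                       setup = "setup1", seed = 1L,
                       pattern = "^(.+)_f(\\d+)_(bf|pom)\\.(?:tif|tiff|png)$",
                       modality_tokens = c(bf = "bf", pom = "pom")) {
  stopifnot(inherits(calibration, "pixel_calibration"),
            inherits(bf_threshold, "threshold_spec"))
  if (bright_threshold < 0 || bright_threshold > 255) {
    stop("bright_threshold must be in [0, 255]", call. = FALSE)
  }
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         calibration = calibration, bf_threshold = bf_threshold,
         bright_threshold = as.integer(bright_threshold),
         min_area_px = as.integer(min_area_px),
         prune_px = as.integer(prune_px),
         weighting = weighting, setup = setup, seed = as.integer(seed),
         pattern = pattern, modality_tokens = modality_tokens),
    class = "run_config"
  )
}

#' Analyze one image pair
#'
#' The per-frame unit of the pipeline: segment the fiber in the brightfield
#' frame, measure its diameter profile and morphology, segment the bright
#' birefringent areas of the POM frame within the fiber, and summarize the
#' intensities. Returns one frame-level result row.
#'
#' @param pair An [image_pair()].
#' @param config A [run_config()] (paths unused here).
#' @return One-row data frame with the frame-level schema (morphology +
#'   birefringence columns); per-segment table attached as attribute
#'   `"segments"`.
#' @export
analyze_pair <- function(pair, config = run_config(".", ".")) {
  stopifnot(inherits(pair, "image_pair"))
  fiber <- segment_fiber(pair$brightfield, config$bf_threshold,
                         min_area_px = config$min_area_px,
                         fiber_id = pair$fiber_id,
                         frame_index = pair$frame_index)
  profile <- diameter_profile(fiber, pair$calibration,
                              prune_px = config$prune_px)
  morph <- summarize_morphology(profile, fiber, pair$calibration)
  bright <- segment_bright_areas(pair$pom, fiber, config$bright_threshold)
  biref <- birefringence_result(pair$pom, fiber, bright, pair$calibration,
                                fiber_area_um2 = morph$area_um2)
  row <- cbind(
    data.frame(fiber_id = pair$fiber_id, frame_index = pair$frame_index,
               stringsAsFactors = FALSE),
    morph, biref)
  attr(row, "segments") <- attr(biref, "segments")
  row
}

#' Batch analysis of a micrograph directory
#'
#' Discovers all fiber series in `config$input_dir`, analyzes every frame, and
#' writes `frames.csv` (one row per frame), `fiber_summary.csv` (one row per
#' fiber, including the normalized intensity) and `manifest.json` (settings
#' and per-fiber frame counts) to `config$output_dir`. A failure in one fiber
#' is logged and skipped; the remaining fibers complete and the exit status
#' reports the partial failure.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `frames`, `summaries`, `failed` (named
#'   character vector of error messages) and `status` (0 = clean, 2 = some
#'   fibers skipped).
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  series <- discover_series(config$input_dir, config$calibration,
                            pattern = config$pattern,
                            modality_tokens = config$modality_tokens,
                            load = FALSE)
  frames <- list(); summaries <- list(); failed <- character()
  for (s in series) {
    rows <- tryCatch({
      do.call(rbind, lapply(s$pairs, function(p) {
        pair <- load_image_pair(p$brightfield_path, p$pom_path,
                                config$calibration, fiber_id = p$fiber_id,
                                frame_index = p$frame_index)
        analyze_pair(pair, config = config)
      }))
    }, error = function(e) {
      message(sprintf("fiber %s skipped: %s", s$fiber_id, conditionMessage(e)))
      failed[[s$fiber_id]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(rows)) next
    frames[[s$fiber_id]] <- rows
    summaries[[s$fiber_id]] <- summarize_fiber(rows, weighting = config$weighting)
  }
  frames <- if (length(frames)) do.call(rbind, frames) else data.frame()
  summaries <- if (length(summaries)) do.call(rbind, summaries) else data.frame()
  rownames(frames) <- rownames(summaries) <- NULL
  if (nrow(summaries)) attr(summaries, "setup") <- config$setup
  write_results_table(frames, file.path(config$output_dir, "frames.csv"))
  write_results_table(summaries,
                      file.path(config$output_dir, "fiber_summary.csv"))
  write_manifest(list(
    tool = "fiberpom", version = as.character(utils::packageVersion("fiberpom")),
    microns_per_pixel = config$calibration$microns_per_pixel,
    bf_threshold_mode = config$bf_threshold$mode,
    bf_threshold_fixed = config$bf_threshold$fixed_value,
    bright_threshold = config$bright_threshold,
    min_area_px = config$min_area_px, prune_px = config$prune_px,
    weighting = config$weighting, setup = config$setup, seed = config$seed,
    n_fibers = nrow(summaries),
    frames_per_fiber = if (nrow(frames)) {
      as.list(table(frames$fiber_id))
    } else list(),
    failed_fibers = as.list(failed)
  ), file.path(config$output_dir, "manifest.json"))
  invisible(list(frames = frames, summaries = summaries, failed = failed,
                 status = if (length(failed)) 2L else 0L))
}

#' Simulate a micrograph directory with known ground truth
#'
#' Samples a synthetic cohort, renders each fiber as a series of paired
#' brightfield/POM frames (same fiber, frame-specific noise), and writes the
#' TIFF pairs plus `cohort.csv` (true diameters, NI and strengths) and
#' `ground_truth.json` into a directory laid out exactly as [run_analyze()]
#' expects.
#'
#' @param out_dir Output directory (created).
#' @param n_fibers,frames_per_fiber Cohort and series sizes.
#' @param shape Frame dimensions `c(rows, cols)` in pixels.
#' @param calibration A [pixel_calibration()].
#' @param seed Integer seed for cohort and noise.
#' @param ... Passed to [generate_cohort()].
#' @return Invisibly, the cohort (with the file layout recorded).
#' @export
run_simulate <- function(out_dir, n_fibers = 3L, frames_per_fiber = 6L,
                         shape = c(120L, 400L),
                         calibration = pixel_calibration(1), seed = 1L,
                         ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_fibers = n_fibers, seed = seed,
                            ni_range = c(4, 10), ...)
  frame_len <- shape[2] * calibration$microns_per_pixel
  specs <- cohort_fiber_specs(cohort, frame_length_um = frame_len)
  truth <- list()
  for (i in seq_len(n_fibers)) {
    fid <- cohort$summaries$fiber_id[i]
    for (k in seq_len(frames_per_fiber) - 1L) {
      sp <- specs[[i]]
      sp$seed <- seed * 10000L + i * 100L + k  # frame-specific noise
      r <- render_pair(sp, shape = shape, calibration = calibration,
                       fiber_id = fid, frame_index = k)
      tiff::writeTIFF(r$pair$brightfield / 255,
                      file.path(out_dir, sprintf("%s_f%d_bf.tif", fid, k)),
                      bits.per.sample = 8L)
      tiff::writeTIFF(r$pair$pom / 255,
                      file.path(out_dir, sprintf("%s_f%d_pom.tif", fid, k)),
                      bits.per.sample = 8L)
      if (k == 0L) {
        truth[[fid]] <- list(
          mean_diameter_um = r$truth$mean_diameter_um,
          min_diameter_um = r$truth$min_diameter_um,
          area_um2 = r$truth$area_um2,
          mean_pom_intensity = r$truth$mean_pom_intensity,
          n_patches = nrow(r$truth$patch_inventory))
      }
    }
  }
  write_results_table(cohort$summaries, file.path(out_dir, "cohort.csv"))
  write_manifest(list(generator = cohort$truth, per_fiber = truth),
                 file.path(out_dir, "ground_truth.json"))
  invisible(cohort)
}

#' Calibrate a strength model from summary and strength tables
#'
#' @param summary_csv Fiber-summary CSV (from [run_analyze()] or external),
#'   containing `fiber_id` and the predictor column. If it lacks
#'   `measured_strength`, strengths are joined from `strengths_csv`.
#' @param model_json Output path for the model JSON.
#' @param strengths_csv Optional CSV with `fiber_id`, `measured_strength`.
#' @param setup Setup tag stored in the model.
#' @param ... Passed to [fit_strength_model()].
#' @return Invisibly, the fitted `strength_model`.
#' @export
run_calibrate <- function(summary_csv, model_json, strengths_csv = NULL,
                          setup = NA_character_, ...) {
  s <- utils::read.csv(summary_csv, stringsAsFactors = FALSE)
  if (!is.null(strengths_csv)) {
    st <- utils::read.csv(strengths_csv, stringsAsFactors = FALSE)
    s$measured_strength <- st$measured_strength[match(s$fiber_id, st$fiber_id)]
  }
  model <- fit_strength_model(s, setup = setup, ...)
  write_strength_model(model, model_json)
  invisible(model)
}

#' Predict strengths for a summary table with a stored model
#'
#' @param model_json Path of a model written by [run_calibrate()].
#' @param summary_csv Fiber-summary CSV to predict on.
#' @param out_csv Output CSV (per-fiber predictions; the summary lines
#'   `mean_percent_difference` and `pearson_r_abs` are reported in the return
#'   value and printed).
#' @param allow_cross_setup Passed to [predict_strength()].
#' @return Invisibly, the `prediction_report`.
#' @export
run_predict <- function(model_json, summary_csv, out_csv,
                        allow_cross_setup = FALSE) {
  model <- read_strength_model(model_json)
  s <- utils::read.csv(summary_csv, stringsAsFactors = FALSE)
  rep <- predict_strength(model, s, allow_cross_setup = allow_cross_setup)
  write_results_table(rep$fibers, out_csv)
  message(sprintf(
    "predicted %d fibers; mean percent difference %s, |r| pred vs meas %s",
    nrow(rep$fibers),
    ifelse(is.na(rep$mean_percent_difference), "NA",
           sprintf("%.1f%%", rep$mean_percent_difference)),
    ifelse(is.na(rep$pearson_r_abs_pred_vs_meas), "NA",
           sprintf("%.2f", rep$pearson_r_abs_pred_vs_meas))))
  invisible(rep)
}

#' Batch tensile analysis
#'
#' @param tensile_csv Force–displacement CSV (see [read_tensile_csv()]).
#' @param diameters Named numeric vector or data frame (`fiber_id`,
#'   `mean_diameter`) of image-derived mean diameters in µm.
#' @param out_csv Output CSV with per-fiber `ultimate_strength_MPa`,
#'   `strain_at_break`, `diameter_used_um`.
#' @param force_unit,gauge_length_mm,drop_fraction See
#'   [read_tensile_csv()] and [engineering_stress_strain()].
#' @return Invisibly, the per-fiber results data frame.
#' @export
run_tensile <- function(tensile_csv, diameters, out_csv, force_unit = "N",
                        gauge_length_mm = 10, drop_fraction = 0.5) {
  recs <- read_tensile_csv(tensile_csv, force_unit = force_unit,
                           gauge_length_mm = gauge_length_mm)
  if (is.data.frame(diameters)) {
    dmap <- stats::setNames(diameters$mean_diameter, diameters$fiber_id)
  } else {
    dmap <- diameters
  }
  rows <- lapply(recs, function(r) {
    d <- unname(dmap[r$fiber_id])
    if (length(d) != 1L || is.na(d)) {
      stop(sprintf("no diameter supplied for fiber %s", r$fiber_id),
           call. = FALSE)
    }
    cv <- engineering_stress_strain(r, d, drop_fraction = drop_fraction)
    data.frame(fiber_id = r$fiber_id,
               ultimate_strength_MPa = cv$ultimate_strength_MPa,
               strain_at_break = cv$strain_at_break,
               diameter_used_um = cv$diameter_used_um,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_results_table(out, out_csv)
  invisible(out)
}
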