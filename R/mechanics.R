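#' Tensile test record
#'
#' Force–displacement record of a single-fiber tensile test on a 10 mm gauge
#' (fibers mounted across a paper frame with a 10 mm gap).
#'
#' @param fiber_id Fiber identifier.
#' @param displacement_mm Non-decreasing grip displacement series (mm).
#' @param force_N Measured force series (N), same length.
#' @param gauge_length_mm Initial gauge length (mm), default 10.
#' @return Object of class `tensile_record`.
#' @export
tensile_record <- function(fiber_id, displacement_mm, force_N,
                           gauge_length_mm = 10) {
  if (length(displacement_mm) != length(force_N) ||
      length(force_N) < 2L) {
    stop("displacement and force must have equal length >= 2", call. = FALSE)
  }
  if (is.unsorted(displacement_mm)) {
    stop("displacement must be non-decreasing", call. = FALSE)
  }
  if (gauge_length_mm <= 0) stop("gauge_length_mm must be > 0", call. = FALSE)
  structure(
    list(fiber_id = as.character(fiber_id),
         displacement_mm = as.numeric(displacement_mm),
         force_N = as.numeric(force_N),
         gauge_length_mm = as.numeric(gauge_length_mm)),
    class = "tensile_record"
  )
}

#' Engineering stress–strain curve and ultimate strength
#'
#' Converts a force–displacement record to engineering stress and strain using
#' the image-derived mean fiber diameter for the cross-section. The
#' cross-section is taken as circular, `A = pi (d/2)^2`; for fibers with a
#' longitudinal groove this overestimates the true area, so the reported
#' stress is a conservative underestimate. Strain is displacement divided by
#' the initial gauge length. Fracture is detected as the first sample where
#' the force falls below `drop_fraction` of the running maximum; the ultimate
#' strength is the stress at the last point before that drop. If no drop
#' occurs the final sample is used, with a warning.
#'
#' @param record A [tensile_record()].
#' @param mean_diameter_um Image-derived mean fiber diameter (µm, > 0).
#' @param drop_fraction Force fraction of the running maximum below which the
#'   fiber is considered fractured (default 0.5).
#' @return Object of class `stress_strain_curve`: list with `strain`,
#'   `stress_MPa`, `ultimate_strength_MPa`, `strain_at_break`,
#'   `diameter_used_um`, `fracture_index`, `gauge_length_mm`, `fiber_id`.
#' @examples
#' rec <- tensile_record("f1", seq(0, 1, length.out = 11),
#'                       c(seq(0, 1e-3, length.out = 10), 0))
#' curve <- engineering_stress_strain(rec, mean_diameter_um = 5)
#' curve$ultimate_strength_MPa  # ~50.93 MPa
#' @export
engineering_stress_strain <- function(record, mean_diameter_um,
                                      drop_fraction = 0.5) {
  stopifnot(inherits(record, "tensile_record"))
  if (!is.finite(mean_diameter_um) || mean_diameter_um <= 0) {
    stop("mean_diameter_um must be positive", call. = FALSE)
  }
  if (all(record$force_N == 0)) {
    stop("all-zero force record", call. = FALSE)
  }
  area_m2 <- pi * (mean_diameter_um * 1e-6 / 2)^2
  stress_MPa <- record$force_N / area_m2 / 1e6
  strain <- record$displacement_mm / record$gauge_length_mm
  runmax <- cummax(record$force_N)
  n <- length(strain)
  drop <- which(seq_len(n) > 1L & record$force_N < drop_fraction *
                  c(0, runmax[-n]))
  if (length(drop) == 0L) {
    warning("no fracture drop detected; using the final sample as break point",
            call. = FALSE)
    fracture_index <- n + 1L
    break_at <- n
  } else {
    fracture_index <- drop[1L]
    break_at <- fracture_index - 1L
  }
  structure(
    list(strain = strain, stress_MPa = stress_MPa,
         ultimate_strength_MPa = stress_MPa[break_at],
         strain_at_break = strain[break_at],
         diameter_used_um = as.numeric(mean_diameter_um),
         fracture_index = fracture_index,
         gauge_length_mm = record$gauge_length_mm,
         fiber_id = record$fiber_id,
         drop_fraction = drop_fraction),
    class = "stress_strain_curve"
  )
}

#' Read tensile records from CSV
#'
#' Expects columns `displacement_mm` and `force_N` (or `force_mN` with
#' `force_unit = "mN"`), optionally `fiber_id` for long-format files holding
#' several fibers.
#'
#' @param path CSV path.
#' @param force_unit `"N"` or `"mN"`.
#' @param gauge_length_mm Gauge length applied to every record.
#' @return List of [tensile_record()]s, one per fiber.
#' @export
read_tensile_csv <- function(path, force_unit = c("N", "mN"),
                             gauge_length_mm = 10) {
  force_unit <- match.arg(force_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcol <- if (force_unit == "mN") "force_mN" else "force_N"
  if (!all(c("displacement_mm", fcol) %in% names(df))) {
    stop(sprintf("CSV must contain displacement_mm and %s columns", fcol),
         call. = FALSE)
  }
  force <- df[[fcol]] * if (force_unit == "mN") 1e-3 else 1
  if (is.null(df$fiber_id)) {
    df$fiber_id <- tools::file_path_sans_ext(basename(path))
  }
  lapply(split(seq_len(nrow(df)), df$fiber_id), function(i) {
    tensile_record(df$fiber_id[i[1]], df$displacement_mm[i], force[i],
                   gauge_length_mm = gauge_length_mm)
  })
}
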