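#' Specification of a synthetic fiber field of view
#'
#' Describes one analytically defined fiber as imaged by the two modalities:
#' dark band on bright background in brightfield, bright band (with optional
#' brighter birefringent patches) on dark background under crossed polarizers.
#' The rendered images follow this specification exactly (hard band edges, no
#' anti-aliasing), so the ground truth attached to a render is analytic and
#' never derived from the rendered pixels.
#'
#' @param width_um Fiber width in µm: a scalar (constant width) or a function
#'   of the longitudinal position in µm.
#' @param centerline Vertical offset of the fiber center from the image
#'   mid-line, in µm: `NULL` (straight), a scalar, or a function of position.
#' @param bf_fiber_level,bf_background_level Brightfield intensities of fiber
#'   and background (fiber must be darker).
#' @param pom_base_level,pom_background_level POM intensities of the fiber
#'   body and the background (fiber brighter).
#' @param patches Optional data frame with columns `x0_um`, `length_um`,
#'   `level`: longitudinal intervals where the whole fiber cross-section takes
#'   the given POM level (the patchy bright birefringence seen along real
#'   recombinant fibers).
#' @param noise_sd Additive Gaussian read-noise SD (intensity units); noise is
#'   clipped to [0, 255] after addition.
#' @param seed Integer seed making the render deterministic.
#' @return Object of class `fiber_spec`.
#' @export
fiber_spec <- function(width_um = 10, centerline = NULL,
                       bf_fiber_level = 60, bf_background_level = 220,
                       pom_base_level = 120, pom_background_level = 10,
                       patches = NULL, noise_sd = 0, seed = 1L) {
  if (bf_fiber_level >= bf_background_level) {
    stop("brightfield fiber level must be below the background level",
         call. = FALSE)
  }
  for (v in c(bf_fiber_level, bf_background_level, pom_base_level,
              pom_background_level)) {
    if (v < 0 || v > 255) stop("levels must lie in [0, 255]", call. = FALSE)
  }
  if (!is.null(patches)) {
    stopifnot(is.data.frame(patches),
              all(c("x0_um", "length_um", "level") %in% names(patches)))
  }
  structure(
    list(width_um = width_um, centerline = centerline,
         bf_fiber_level = bf_fiber_level,
         bf_background_level = bf_background_level,
         pom_base_level = pom_base_level,
         pom_background_level = pom_background_level,
         patches = patches, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "fiber_spec"
  )
}

#' Render a synthetic brightfield/POM pair with analytic ground truth
#'
#' Rasterizes a [fiber_spec()] into one co-registered image pair plus the
#' ground truth computed from the specification itself: the exact fiber mask,
#' per-column width, mean/min diameter, fiber area, the noise-free mean POM
#' intensity over the mask, and the inventory of bright patches clipped to the
#' mask. Identical seeds give bit-identical images; the ground truth does not
#' depend on the seed because noise is zero-mean and applied after the truth
#' is recorded.
#'
#' @param spec A [fiber_spec()].
#' @param shape Image dimensions `c(rows, cols)`.
#' @param calibration A [pixel_calibration()].
#' @param fiber_id,frame_index Identifiers for the emitted [image_pair()].
#' @return List with `pair` (an `image_pair`) and `truth` (class
#'   `ground_truth`): `mask`, `col_width_px`, `mean_diameter_um`,
#'   `min_diameter_um`, `area_um2`, `mean_pom_intensity`, `patch_inventory`
#'   (data frame `patch_id`, `area_px`, `area_um2`, `level`).
#' @export
render_pair <- function(spec, shape = c(200L, 400L),
                        calibration = pixel_calibration(1),
                        fiber_id = "synthetic", frame_index = 0L) {
  stopifnot(inherits(spec, "fiber_spec"),
            inherits(calibration, "pixel_calibration"))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  mpp <- calibration$microns_per_pixel
  x_um <- (seq_len(nc) - 0.5) * mpp
  wfun <- if (is.function(spec$width_um)) spec$width_um else {
    w0 <- spec$width_um; function(x) rep(w0, length(x))
  }
  cfun <- if (is.null(spec$centerline)) {
    function(x) rep(0, length(x))
  } else if (is.function(spec$centerline)) {
    spec$centerline
  } else {
    c0 <- spec$centerline; function(x) rep(c0, length(x))
  }
  w_px <- round(wfun(x_um) / mpp)
  if (any(w_px < 1)) stop("fiber width below one pixel", call. = FALSE)
  cy <- nr / 2 + cfun(x_um) / mpp
  top <- round(cy - w_px / 2) + 1L
  bot <- top + w_px - 1L
  if (any(top < 1L) || any(bot > nr)) {
    stop("fiber does not fit inside the frame vertically", call. = FALSE)
  }
  mask <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) mask[top[j]:bot[j], j] <- TRUE

  bf <- matrix(spec$bf_background_level, nr, nc)
  bf[mask] <- spec$bf_fiber_level
  pom <- matrix(spec$pom_background_level, nr, nc)
  pom[mask] <- spec$pom_base_level

  patch_inventory <- data.frame(patch_id = integer(), area_px = integer(),
                                area_um2 = numeric(), level = numeric())
  if (!is.null(spec$patches) && nrow(spec$patches)) {
    inv <- vector("list", nrow(spec$patches))
    for (i in seq_len(nrow(spec$patches))) {
      p <- spec$patches[i, ]
      cols <- which(x_um >= p$x0_um & x_um < p$x0_um + p$length_um)
      sel <- matrix(FALSE, nr, nc)
      for (j in cols) sel[top[j]:bot[j], j] <- TRUE
      pom[sel] <- p$level
      inv[[i]] <- data.frame(patch_id = i, area_px = sum(sel),
                             area_um2 = sum(sel) * mpp^2, level = p$level)
    }
    patch_inventory <- do.call(rbind, inv)
  }
  mean_pom <- mean(pom[mask])  # truth recorded before noise

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    bf <- bf + stats::rnorm(length(bf), 0, spec$noise_sd)
    pom <- pom + stats::rnorm(length(pom), 0, spec$noise_sd)
  }
  bf <- matrix(as.integer(pmin(255, pmax(0, round(bf)))), nr, nc)
  pom <- matrix(as.integer(pmin(255, pmax(0, round(pom)))), nr, nc)

  truth <- structure(
    list(mask = mask, col_width_px = w_px,
         mean_diameter_um = mean(w_px) * mpp,
         min_diameter_um = min(w_px) * mpp,
         area_um2 = sum(mask) * mpp^2,
         mean_pom_intensity = mean_pom,
         patch_inventory = patch_inventory),
    class = "ground_truth"
  )
  list(pair = image_pair(fiber_id, frame_index, bf, pom, calibration),
       truth = truth)
}

#' Generate a synthetic calibration cohort
#'
#' Samples a cohort of fibers whose engineering strength is a noisy linear
#' function of the normalized intensity (NI) and only weakly related to the
#' diameter, emulating the regime in which the NI predictor is useful: thin
#' recombinant fibers whose strength tracks molecular alignment rather than
#' size. NI and diameter are drawn from uniform marginals coupled through a
#' Gaussian copula with correlation `ni_diameter_cor`.
#'
#' Defaults (chosen once as the package's study conditions): diameters span
#' 3.1–24.0 µm, the span observed for wet-spun NT2RepCT fibers; NI spans 2–10
#' intensity units/µm so that mean POM intensity (NI x diameter) stays within
#' the 8-bit range when cohorts are rendered to images; strength
#' `30 + 20 NI + N(0, 35)` MPa gives realistic strengths (~90–270 MPa) and a
#' population |r| of about 0.8 between NI and strength; `ni_diameter_cor`
#' -0.25 yields the weak diameter–strength correlation seen for thin fibers.
#'
#' @param n_fibers Number of fibers (>= 3).
#' @param intercept,slope,noise_sd Strength model: MPa, MPa per (intensity/µm),
#'   and residual SD in MPa.
#' @param diameter_range,ni_range Uniform marginal ranges.
#' @param ni_diameter_cor Gaussian-copula correlation between NI and diameter.
#' @param seed Integer seed.
#' @return List with `summaries` (a fiber-summary data frame with
#'   `measured_strength`) and `truth` (the generating parameters).
#' @export
generate_cohort <- function(n_fibers = 30L, intercept = 30, slope = 20,
                            noise_sd = 35, diameter_range = c(3.1, 24.0),
                            ni_range = c(2, 10), ni_diameter_cor = -0.25,
                            seed = 1L) {
  if (n_fibers < 3L) stop("n_fibers must be >= 3", call. = FALSE)
  if (diff(diameter_range) < 0 || diff(ni_range) < 0 ||
      any(diameter_range <= 0) || any(ni_range <= 0)) {
    stop("invalid diameter_range or ni_range", call. = FALSE)
  }
  if (abs(ni_diameter_cor) >= 1) {
    stop("ni_diameter_cor must lie in (-1, 1)", call. = FALSE)
  }
  set.seed(seed)
  z1 <- stats::rnorm(n_fibers)
  z2 <- ni_diameter_cor * z1 +
    sqrt(1 - ni_diameter_cor^2) * stats::rnorm(n_fibers)
  ni <- ni_range[1] + diff(ni_range) * stats::pnorm(z1)
  d <- diameter_range[1] + diff(diameter_range) * stats::pnorm(z2)
  strength <- intercept + slope * ni + stats::rnorm(n_fibers, 0, noise_sd)
  summaries <- data.frame(
    fiber_id = sprintf("fiber%03d", seq_len(n_fibers)),
    mean_diameter = d,
    mean_intensity = ni * d,
    normalized_intensity = ni,
    n_frames = 1L,
    measured_strength = strength,
    stringsAsFactors = FALSE
  )
  class(summaries) <- c("fiber_summary", "data.frame")
  list(summaries = summaries,
       truth = list(intercept = intercept, slope = slope,
                    noise_sd = noise_sd, ni_diameter_cor = ni_diameter_cor,
                    diameter_range = diameter_range, ni_range = ni_range,
                    seed = as.integer(seed)))
}

#' Fiber specs for rendering a cohort to images
#'
#' Turns each cohort fiber into a constant-width [fiber_spec()] whose POM base
#' level equals NI x diameter, so that analyzing the rendered images recovers
#' the cohort's normalized intensities. Optional bright patches raise part of
#' the fiber by `patch_delta`; the base level is lowered to compensate so the
#' fiber's mean POM intensity (and hence its NI) is preserved up to the patch
#' area quantization.
#'
#' @param cohort A [generate_cohort()] result.
#' @param frame_length_um Longitudinal extent of one frame (µm).
#' @param n_patches Bright patches per frame (0 for none).
#' @param patch_delta Intensity increment of patches over the base level.
#' @return List of `fiber_spec`s, one per cohort fiber.
#' @export
cohort_fiber_specs <- function(cohort, frame_length_um = 400,
                               n_patches = 2L, patch_delta = 60) {
  s <- cohort$summaries
  lapply(seq_len(nrow(s)), function(i) {
    target <- s$mean_intensity[i]
    patches <- NULL
    base <- target
    if (n_patches > 0L) {
      len <- frame_length_um / (3 * n_patches)
      x0 <- frame_length_um * (seq_len(n_patches) - 0.6) / n_patches
      frac <- n_patches * len / frame_length_um
      base <- target - patch_delta * frac
      if (base < 0 || base + patch_delta > 255) {
        base <- target
        patches <- NULL
      } else {
        patches <- data.frame(x0_um = x0, length_um = len,
                              level = base + patch_delta)
      }
    }
    fiber_spec(width_um = s$mean_diameter[i],
               pom_base_level = base,
               patches = patches,
               noise_sd = 3,
               seed = cohort$truth$seed + i)
  })
}
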