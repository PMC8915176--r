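#' Medial axis (topological skeleton) of a binary mask
#'
#' Zhang–Suen thinning: the mask is iteratively peeled from alternating sides
#' until a one-pixel-wide, 8-connected centerline remains. The medial axis is
#' where the Euclidean distance transform attains its local ridge, so sampling
#' the EDT along it yields the local half-width of the object at every
#' position along its length.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @return Logical matrix of the same dimensions containing the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  ctr <- 2:(nr - 1L); ccc <- 2:(nc - 1L)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # 8-neighbourhood, clockwise from north (P2..P9)
      P <- m[ctr, ccc]
      P2 <- m[ctr - 1L, ccc];      P3 <- m[ctr - 1L, ccc + 1L]
      P4 <- m[ctr, ccc + 1L];      P5 <- m[ctr + 1L, ccc + 1L]
      P6 <- m[ctr + 1L, ccc];      P7 <- m[ctr + 1L, ccc - 1L]
      P8 <- m[ctr, ccc - 1L];      P9 <- m[ctr - 1L, ccc - 1L]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      del <- P & B >= 2 & B <= 6 & A == 1
      if (pass == 1L) {
        del <- del & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        del <- del & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(del)) {
        sub <- m[ctr, ccc]
        sub[del] <- FALSE
        m[ctr, ccc] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[ctr, ccc]
}

# Remove skeleton spurs: iteratively delete endpoints (pixels with exactly one
# 8-neighbour) n_iter times. Isolated pixels (zero neighbours) are preserved,
# so a disc's single-point skeleton survives. Thresholding noise creates short
# spurs whose EDT values are boundary artifacts; 10 iterations removes spurs
# up to 10 px long at the cost of trimming 10 px off the true axis ends, which
# the frame-border exclusion discards anyway.
prune_spurs <- function(skel, n_iter = 10L) {
  if (n_iter <= 0L) return(skel)
  m <- skel
  for (i in seq_len(n_iter)) {
    nb <- neighbor_count8(m)
    ep <- m & nb == 1L
    if (!any(ep)) break
    m[ep] <- FALSE
  }
  m
}

neighbor_count8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  s <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  s
}

#' Local diameter profile along the fiber
#'
#' Computes the Euclidean distance transform of the fiber mask (distance of
#' each fiber pixel to the nearest background pixel), extracts the medial axis
#' by thinning, prunes short spurs, and reports the local diameter
#' `2 x EDT x microns_per_pixel` at every remaining axis pixel — i.e. the
#' diameter is measured for every pixel along the captured fiber length rather
#' than at a few hand-picked points. Axis pixels closer to the left/right
#' image border than their own local diameter are excluded, because the EDT
#' there reflects the frame truncation, not the fiber surface. The estimator
#' is quantized at the pixel scale: for a band an odd number of pixels wide
#' the nearest background pixel *center* is half a pixel beyond the surface,
#' so local diameters carry a +-1 px discretization.
#'
#' @param fiber A [segment_fiber()] result (or any `fiber_mask`).
#' @param calibration A [pixel_calibration()].
#' @param prune_px Spur-pruning iterations (default 10).
#' @return A data frame of class `diameter_profile` with columns `row`, `col`
#'   (axis pixel coordinates) and `diameter_um`.
#' @export
diameter_profile <- function(fiber, calibration, prune_px = 10L) {
  stopifnot(inherits(fiber, "fiber_mask"),
            inherits(calibration, "pixel_calibration"))
  mask <- fiber$mask
  if (!any(mask)) stop("empty fiber mask", call. = FALSE)
  edt <- EBImage::distmap(mask * 1L)
  skel <- prune_spurs(skeletonize(mask), n_iter = prune_px)
  if (!any(skel)) {
    stop("skeleton empty after pruning; fiber too small or fragmented",
         call. = FALSE)
  }
  idx <- which(skel, arr.ind = TRUE)
  d_px <- 2 * edt[idx]
  # exclude axis pixels within one local diameter of the left/right borders
  margin <- pmin(idx[, 2] - 1L, ncol(mask) - idx[, 2])
  keep <- margin >= d_px
  if (!any(keep)) {
    stop("no axis pixel survives the frame-border exclusion", call. = FALSE)
  }
  out <- data.frame(row = idx[keep, 1], col = idx[keep, 2],
                    diameter_um = d_px[keep] * calibration$microns_per_pixel)
  out <- out[order(out$col, out$row), ]
  rownames(out) <- NULL
  class(out) <- c("diameter_profile", "data.frame")
  out
}

#' Per-frame morphology summary
#'
#' The standard per-frame morphology outputs: fiber area and the mean, sample
#' standard deviation and minimum of the local diameter profile, together with
#' the threshold that produced the mask and the number of axis samples that
#' entered the statistics.
#'
#' @param profile A [diameter_profile()] result.
#' @param fiber The `fiber_mask` the profile was measured on.
#' @param calibration A [pixel_calibration()].
#' @return A one-row data frame of class `morphometry_result` with columns
#'   `area_um2`, `mean_diam_um`, `sd_diam_um`, `min_diam_um`,
#'   `threshold_used`, `n_axis_samples`, `n_fiber_px`.
#' @export
summarize_morphology <- function(profile, fiber, calibration) {
  stopifnot(inherits(profile, "diameter_profile"),
            inherits(fiber, "fiber_mask"),
            inherits(calibration, "pixel_calibration"))
  d <- profile$diameter_um
  if (length(d) == 0L) stop("empty diameter profile", call. = FALSE)
  n_px <- sum(fiber$mask)
  res <- data.frame(
    area_um2 = n_px * calibration$microns_per_pixel^2,
    mean_diam_um = mean(d),
    sd_diam_um = if (length(d) > 1L) stats::sd(d) else 0,
    min_diam_um = min(d),
    threshold_used = fiber$threshold_used,
    n_axis_samples = length(d),
    n_fiber_px = n_px
  )
  stopifnot(res$min_diam_um <= res$mean_diam_um, res$area_um2 > 0)
  class(res) <- c("morphometry_result", "data.frame")
  res
}
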