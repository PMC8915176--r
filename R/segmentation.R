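#' Threshold specification
#'
#' Chooses between Yen's automatic entropic threshold and a fixed user value
#' for the brightfield fiber segmentation. The fixed mode mirrors routine
#' practice: the automatic method finds a sensible level on a new setup, a
#' fixed value is then locked in for all comparable acquisitions so local
#' shadows are never misidentified as fiber. `148` is a typical locked-in value
#' for a 10x brightfield configuration at fixed 2 ms exposure.
#'
#' @param mode `"auto_yen"` or `"fixed"`.
#' @param fixed_value Intensity in 0..255; required iff `mode = "fixed"`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("auto_yen", "fixed"), fixed_value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(fixed_value) || length(fixed_value) != 1L ||
        !is.finite(fixed_value) || fixed_value < 0 || fixed_value > 255) {
      stop("fixed mode requires fixed_value in [0, 255]", call. = FALSE)
    }
    fixed_value <- as.integer(fixed_value)
  } else if (!is.null(fixed_value)) {
    stop("fixed_value must be absent when mode = 'auto_yen'", call. = FALSE)
  }
  structure(list(mode = mode, fixed_value = fixed_value),
            class = "threshold_spec")
}

#' Yen's entropic-correlation threshold
#'
#' Computes the automatic threshold of Yen, Chang and Chang (1995) from a
#' 256-bin intensity histogram. For each candidate split of the gray levels
#' into a lower class `0..t-1` and an upper class `t..255` the
#' entropic-correlation criterion
#' \deqn{TC(t) = -\ln(G_1 G_2) + 2 \ln(P_1 P_2)}
#' is evaluated, where \eqn{P_1, P_2} are the class probabilities and
#' \eqn{G_1, G_2} the within-class sums of squared normalized histogram
#' entries. The returned level `t` (the first level of the upper class)
#' maximizes TC; ties are broken toward the lowest level, and splits with an
#' empty or zero-mass class are not candidates. Pixels with intensity below
#' `t` form the dark class (the fiber, in brightfield), pixels at or above `t`
#' the bright class.
#'
#' @param x Either a numeric vector of length 256 (counts of levels 0..255) or
#'   an integer image matrix from which the histogram is taken over the full
#'   frame.
#' @return Integer threshold level in 1..255.
#' @export
yen_threshold <- function(x) {
  h <- as_histogram256(x)
  if (sum(h > 0) < 2L) {
    stop("no threshold separates foreground from background: ",
         "image has a single gray level", call. = FALSE)
  }
  p <- h / sum(h)
  P1 <- cumsum(p)          # P1[i] = mass of levels 0..i-1 at split t = i
  G <- cumsum(p^2)
  Gtot <- G[256]
  t_cand <- 1:255
  P1t <- P1[t_cand]
  G1 <- G[t_cand]
  G2 <- Gtot - G1
  tc <- rep(-Inf, 255)
  ok <- P1t > 0 & P1t < 1 & G1 > 0 & G2 > 0
  tc[ok] <- -log(G1[ok] * G2[ok]) + 2 * log(P1t[ok] * (1 - P1t[ok]))
  which.max(tc)  # first (lowest) maximizer; level t = index
}

as_histogram256 <- function(x) {
  if (is.matrix(x)) {
    if (min(x) < 0 || max(x) > 255) {
      stop("image intensities must lie in [0, 255]", call. = FALSE)
    }
    tabulate(as.integer(x) + 1L, nbins = 256L)
  } else if (is.numeric(x) && length(x) == 256L) {
    if (any(x < 0) || !all(is.finite(x))) {
      stop("histogram must be non-negative and finite", call. = FALSE)
    }
    x
  } else {
    stop("x must be a 256-bin histogram or an intensity matrix", call. = FALSE)
  }
}

#' Segment the fiber in a brightfield frame
#'
#' The fiber is a dark object on a bright background: foreground pixels are
#' those with intensity strictly below the threshold (Yen-automatic or fixed).
#' Holes are filled, connected components smaller than `min_area_px` are
#' discarded (these are the local shadows and debris a fixed threshold guards
#' against), and of the survivors the component with the largest horizontal
#' extent is selected — fibers span the frame horizontally in the acquisition
#' geometry — with ties broken toward larger area.
#'
#' @param brightfield Integer matrix, values 0..255.
#' @param spec A [threshold_spec()].
#' @param min_area_px Minimum component area in pixels (default 50).
#' @param fiber_id,frame_index Provenance identifiers stored in the mask.
#' @return An object of class `fiber_mask`: list with logical `mask`,
#'   `threshold_used`, and `source_frame`.
#' @export
segment_fiber <- function(brightfield, spec = threshold_spec("fixed", 148L),
                          min_area_px = 50L, fiber_id = "fiber",
                          frame_index = 0L) {
  stopifnot(is.matrix(brightfield), inherits(spec, "threshold_spec"),
            min_area_px >= 1L)
  thr <- if (spec$mode == "fixed") spec$fixed_value
         else yen_threshold(brightfield)
  fg <- brightfield < thr
  if (!any(fg)) {
    stop(sprintf("no fiber detected (threshold %d): no pixel below threshold",
                 thr), call. = FALSE)
  }
  fg <- EBImage::fillHull(fg * 1L) > 0
  lab <- EBImage::bwlabel(fg * 1L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) {
    stop(sprintf(
      "no fiber detected (threshold %d): all %d component(s) below min_area_px = %d",
      thr, length(sizes), min_area_px), call. = FALSE)
  }
  cols <- col(lab)
  extent <- vapply(keep, function(k) {
    cc <- cols[lab == k]
    diff(range(cc)) + 1L
  }, integer(1))
  best <- keep[order(-extent, -sizes[keep])][1L]
  structure(
    list(mask = lab == best, threshold_used = as.integer(thr),
         source_frame = list(fiber_id = as.character(fiber_id),
                             frame_index = as.integer(frame_index))),
    class = "fiber_mask"
  )
}

#' Segment bright birefringent areas within the fiber
#'
#' Second-stage segmentation: within the fiber region found in the brightfield
#' frame, POM pixels with intensity strictly above `bright_threshold` are
#' classified as bright. No morphological cleanup is applied — a bright
#' segment may be a single pixel — so the decomposition is a pure function of
#' the threshold.
#'
#' @param pom Integer matrix, same dimensions as the fiber mask.
#' @param fiber A [segment_fiber()] result.
#' @param bright_threshold Intensity cut-off in 0..255.
#' @return An object of class `bright_area_mask`: logical `mask` (always a
#'   subset of the fiber mask), `bright_threshold`, and `parent`.
#' @export
segment_bright_areas <- function(pom, fiber, bright_threshold) {
  stopifnot(inherits(fiber, "fiber_mask"))
  if (!is.matrix(pom) || !identical(dim(pom), dim(fiber$mask))) {
    stop("POM frame and fiber mask dimensions differ", call. = FALSE)
  }
  if (length(bright_threshold) != 1L || bright_threshold < 0 ||
      bright_threshold > 255) {
    stop("bright_threshold must be in [0, 255]", call. = FALSE)
  }
  mask <- fiber$mask & (pom > bright_threshold)
  stopifnot(all(fiber$mask[mask]))  # bright area is a subset of the fiber
  structure(
    list(mask = mask, bright_threshold = as.integer(bright_threshold),
         parent = fiber),
    class = "bright_area_mask"
  )
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so labels
# touching only diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # NW-SE diagonal neighbours
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]    # NE-SW diagonal neighbours
  prs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
               cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d]))
  if (nrow(prs)) {
    for (i in seq_len(nrow(prs))) {
      ra <- find(prs[i, 1]); rb <- find(prs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
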