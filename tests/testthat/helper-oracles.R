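# Brute-force evaluation of Yen's entropic-correlation criterion, written
# directly from its definition (plain sums, no cumulative recurrences) as an
# independent oracle for yen_threshold(). Split at level t: lower class is
# levels 0..t-1 (indices 1..t), upper class t..255.
yen_oracle <- function(h) {
  p <- h / sum(h)
  tc <- rep(-Inf, 255)
  for (t in 1:255) {
    lo <- p[1:t]
    hi <- p[(t + 1):256]
    P1 <- sum(lo); P2 <- sum(hi)
    G1 <- sum(lo^2); G2 <- sum(hi^2)
    if (P1 > 0 && P2 > 0 && G1 > 0 && G2 > 0) {
      tc[t] <- -log(G1 * G2) + 2 * log(P1 * P2)
    }
  }
  which.max(tc)
}

# Random 256-bin histogram with at least two nonempty bins.
random_histogram <- function() {
  k <- sample(2:40, 1)
  bins <- sample(0:255, k)
  h <- numeric(256)
  h[bins + 1] <- stats::rpois(k, lambda = sample(5:500, 1)) + 1
  h
}

# Wrap a bare logical matrix as a fiber_mask for direct morphometry tests.
as_fiber_mask <- function(mask, threshold = 148L) {
  structure(list(mask = mask, threshold_used = as.integer(threshold),
                 source_frame = list(fiber_id = "test", frame_index = 0L)),
            class = "fiber_mask")
}

cal1 <- pixel_calibration(1)

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
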