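---
title: "Predicting protein-fiber tensile strength from brightfield and POM micrographs"
author: "fiberpom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-fiber tensile strength from brightfield and POM micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberpom)
```

## The measurement model

A protein fiber — here the motivating case is a wet-spun recombinant
spider-silk fiber — is mounted across a 10 mm paper frame and photographed in
two modalities at each of several fields of view along its length (typically
6 frames, each covering roughly 1400 µm of fiber):

* **brightfield**: the fiber is a dark, roughly horizontal band on a bright
  background; it carries the morphology signal.
* **polarized optical microscopy (POM)**: between crossed polarizers only
  optically anisotropic (molecularly aligned) material transmits, so the
  fiber appears bright on a dark background. At fixed exposure, pixel
  intensity is a monotone proxy for the degree of alignment. No retardance or
  Michel–Lévy analysis is attempted: the raw 8-bit intensity at constant
  acquisition settings is the observable, which is why calibrated models are
  tagged with a setup identifier and refuse cross-setup prediction unless
  explicitly overridden.

The two frames of a pair are acquired back to back on a static mount and are
treated as co-registered; no image registration is performed.

The pipeline condenses each fiber into two numbers: the pooled mean diameter
$\bar d$ (µm) and the pooled mean POM intensity $\bar I$, giving the
**normalized intensity** $\mathrm{NI} = \bar I / \bar d$ (intensity units per
µm). Normalization matters because a thick, weakly aligned fiber can collect
as much polarized light as a thin, highly aligned one; dividing by diameter
converts total brightness into an alignment density, which is what tracks
strength. Engineering strength is then modeled as

$$S = \beta_0 + \beta_1\,\mathrm{NI} + \varepsilon,$$

calibrated by ordinary least squares on fibers that were subsequently tensile
tested, and applied blind to new fibers.

## Segmentation

Brightfield segmentation classifies pixels with intensity strictly below a
threshold as fiber. Two threshold modes exist:

* **Yen's entropic-correlation threshold** (`threshold_spec("auto_yen")`),
  computed on the 256-bin histogram of the full frame. For each candidate
  split into classes $[0, t-1]$ and $[t, 255]$ the criterion
  $-\ln(G_1 G_2) + 2\ln(P_1 P_2)$ is maximized, where $P_k$ are class
  probabilities and $G_k$ within-class sums of squared bin masses. The
  returned level is the first level of the upper class, with ties broken
  toward the lowest level, so the strict `< t` fiber comparison keeps the
  whole dark mode. The implementation is validated against exhaustive
  evaluation of the criterion at all 255 splits.
* **a fixed threshold** (`threshold_spec("fixed", 148L)`), the recommended
  routine mode. Yen's method is entropy-driven: when the fiber occupies a
  small fraction of the frame the split migrates toward the dominant
  background mode and local shadows can be picked up as fiber. Standard
  practice is therefore to run the auto method once on a new setup, inspect,
  and lock the value (148 is a typical locked-in value for a 10×
  configuration; 103 for a second, older setup) for all comparable
  acquisitions.

After thresholding, holes are filled, components smaller than `min_area_px`
(default 50 px) are discarded, and the component with the largest horizontal
extent wins (ties to larger area) — fibers span the frame horizontally in the
acquisition geometry. The POM bright-area segmentation is a second, strict
`> bright_threshold` comparison applied only inside the fiber mask, with no
morphological cleanup, so single-pixel segments are possible by design. The
cut-off is a configuration value recorded in every output row; there is no
universal default that suits all exposures.

## Diameter via the Euclidean distance transform

The local width estimator is the standard ridge construction: compute the EDT
of the fiber mask (distance of each fiber pixel to the nearest background
pixel, `EBImage::distmap`), thin the mask to its medial axis (Zhang–Suen),
and report $2\times$EDT at every axis pixel as the local diameter. This
realizes "measured at every pixel along the captured length": a 400 px frame
yields ~370 diameter samples rather than the 3–10 manual point measurements
it replaces.

Numerical choices:

* **Quantization.** The EDT measures to the nearest background pixel
  *center*, so bands an odd number of pixels wide are overestimated by
  exactly 1 px and even widths are exact; the estimator is used uncorrected
  and its error is bounded by 1 px, which at typical calibrations
  (0.3–1 µm/px) is small against the 3.1–24 µm fibers of interest.
* **Spur pruning** (default 10 iterations): thresholding noise grows short
  skeleton branches whose EDT values reflect boundary accidents; endpoints
  (axis pixels with exactly one 8-neighbour) are deleted iteratively.
  Isolated single pixels are kept, so a disc's point skeleton survives.
* **Border exclusion**: axis pixels closer to the left/right frame edge than
  their own local diameter are dropped — the fiber is truncated by the frame
  there, and the EDT would measure the cut.
* **SD convention**: the per-frame diameter SD is the sample ($n-1$) standard
  deviation of the axis samples.

Rotation robustness (a 30° band keeps the mean diameter within 5% of truth)
and exact scale equivariance in the calibration factor are enforced by tests.

## Pooling, calibration and blind prediction

Frame values are pooled per fiber by their underlying sample populations:
frame mean diameters are weighted by axis-sample counts, frame mean
intensities by fiber-pixel counts, so pooled means equal the statistics of
the concatenated populations (unweighted pooling is available via
`weighting = "equal"`). NI is the ratio of the two pooled means.

`fit_strength_model()` fits the linear model and, alongside, the nested
quadratic; the likelihood-ratio statistic $n\ln(\mathrm{RSS}_1 /
\mathrm{RSS}_2)$ is referred to $\chi^2_1$ and the simpler linear form is
retained unless $p < 0.05$. The LR form is the classical Gaussian one and is
asymptotic: at cohort size 30 its analytic type-I rate is ≈6.5%, reaching the
nominal 5% regime around $n = 100$, which is the cohort size the package's
calibration-of-the-test simulation uses. Correlations are reported as $|r|$
throughout — the sign carries no information about predictive quality here.

Prediction applies the calibrated line to new summaries. When measured
strengths are available, accuracy is summarized by the mean absolute percent
difference with the *measured* value as denominator (MAPE), and by $|r|$
between predicted and measured. The `diameter_only_baseline()` fits the same
machinery with $\bar d$ as the predictor; on cohorts where strength is driven
by alignment, NI beats it essentially always.

## Mechanics

`engineering_stress_strain()` uses the image-derived mean diameter for a
circular cross-section $A = \pi d^2/4$. Real spun fibers can carry a
longitudinal groove; a circular section then overestimates $A$ and the
reported stress is a conservative underestimate — deliberately left
uncorrected, as cross-sectional shape is not observable in these images.
Strain is displacement over the 10 mm gauge, with no toe-region correction
(these fibers show none). Fracture is the first sample whose force falls
below half (configurable) of the running maximum; the ultimate strength is
the stress at the sample immediately before. This "last point before
fracture" rule is robust to the noisy post-break tail of a load cell, which a
global maximum is not.

## The synthetic generator, and what passing tests mean

`fiber_spec()`/`render_pair()` rasterize an analytic fiber: a band of
specified width profile (constant, tapered, sinusoidal, or any function) and
centerline, with hard edges, dark-on-bright in brightfield and
bright-on-dark with optional brighter longitudinal patches in POM, plus
additive Gaussian noise clipped to [0, 255]. Ground truth (mask, per-column
width, mean/min diameter, area, noise-free mean POM intensity, patch
inventory) is computed from the specification, never from the rendered
pixels, so recovery tests are non-circular. Hard edges are the default so
mask recovery has exact truth; they also mean the generator does **not**
emulate out-of-focus blur, uneven illumination, debris, or partial-volume
edge pixels of real micrographs. Passing the recovery suite demonstrates the
estimators are correct on their own terms, not that any particular microscope
needs no threshold tuning.

`generate_cohort()` samples fiber-level cohorts directly: NI and diameter
from uniform marginals on [2, 10] intensity/µm and [3.1, 24.0] µm (the span
observed for wet-spun NT2RepCT fibers) coupled by a Gaussian copula
(correlation −0.25, reproducing the weak diameter–strength association of
thin fibers), and strength $30 + 20\,\mathrm{NI} + N(0, 35)$ MPa — mean
strength ≈150 MPa and a population $|r| \approx 0.80$ between NI and
strength, the regime in which the method is useful. The NI range is capped at
10 so that $\mathrm{NI}\times d \le 240$ stays renderable in 8 bits when
cohorts are turned into images by `cohort_fiber_specs()`.

Problem sizes used by the validation suite: 120×400 px frames; widths 4–24 µm
at 1 µm/px; cohorts of 28–30 fibers (500 replicates for confidence-interval
coverage, 1000 at $n=100$ for LR-test size, 200 for the NI-vs-diameter
comparison). These sizes give Monte-Carlo standard errors comfortably inside
the asserted bands.

## Known limitations

* One fiber per frame, spanning it roughly horizontally; no multi-fiber
  scenes, no registration, no machine-learned segmentation.
* Intensity is setup-specific; there is no exposure normalization across
  microscopes, only the setup-tag guard.
* The diameter estimator is 2×EDT on the medial axis and inherits its ±1 px
  quantization; no subpixel boundary refinement.
* Strength prediction is a single-predictor linear model by design; it is a
  quality-control tool, not a structural model of fiber failure.
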