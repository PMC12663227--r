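---
title: "sporetrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sporetrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporetrack)
```

# The problem

Fungal sporangiospores that carry intracellular bacteria (for example
*Rhizopus microsporus* spores hosting injected *Ralstonia pickettii*) are
imaged by multi-position time-lapse microscopy as they germinate: a widefield
channel shows the spore body and the emerging germ tube, and an mCherry
fluorescence channel reports the bacterial load inside each spore.
`sporetrack` turns such time-lapse data — or synthetic stand-ins with known
ground truth — into per-spore quantities:

* **area** of the segmented object (pixels²), the 2-D projection used as a
  proxy for spore volume;
* **length**, the cumulative length of the skeletonized object;
* **roundness**, $4\pi \cdot \mathrm{area} / \mathrm{perimeter}^2$;
* **bacterial load**, the summed fluorescence of the z sum-projection within
  the object mask (arbitrary units);

and from these: germination calls, whole-series doubling times $T_D$,
maximum-growth-window doubling times $T_{D\max}$, and the serial-passaging
fitness analytics (germination success, positive fraction, fitness index,
median-split load gating, retention summaries, and nonparametric group
comparisons).

# Segmentation model

The package does not run a neural network. It consumes three per-frame
probability maps from any backend (the `ProbabilityMaps` contract): a
**whole-cell** map, a **contour** map, and a **spore-body** map in which germ
tubes are absent. `integrate_maps()` then

1. binarizes the cell map (default threshold 0.5);
2. subtracts binarized contour pixels, so touching spores fall apart along
   the shared contour ridge;
3. labels connected components (default 8-connectivity);
4. reassigns each subtracted cell pixel to the adjacent component with the
   largest shared border (ties to the lower label id), so the ridge width
   does not bias object areas;
5. discards components with zero overlap with the binarized body map
   (objects must be connected to a cell body);
6. discards components below `min_area` (default 30 px²).

`filter_objects()` removes objects with roundness below 0.6. As a spore
germinates, the elongating germ tube drives roundness down; the filter
therefore restricts tracking and growth quantification to the early
germination phase, before germlings entangle across the field of view.

Design points that the data model leaves open, fixed here:

* **Map thresholds** default to 0.5 and are exposed in
  `segmentation_params()`. Cell and body maps binarize at `>= threshold`;
  contour pixels are those *strictly above* the threshold, so
  `contour_threshold = 1` disables splitting (and merges touching spores) —
  useful for sensitivity checks.
* **Connectivity** defaults to 8 because diagonal adjacency is the usual
  notion of "touching" for blob labeling; it is a parameter because it
  changes split behavior.
* **Contour-pixel reassignment** (step 4) is iterative majority voting over
  the neighboring labels. Whether the original pipeline restored contour
  pixels at all is unknowable from the outside; we restore them because
  otherwise every object loses a one-to-two-pixel ring, a bias of order
  `perimeter/area` that would distort early growth rates.
* **Perimeter estimator.** Roundness is sensitive to the perimeter
  estimator. `mask_perimeter()` uses the Crofton boundary-configuration
  estimator with four test directions: the histogram of 2×2 boundary
  configurations weighted by integral-geometry coefficients. On a digital
  disc of radius 50 px it is accurate to under 1%, where a naive
  boundary-pixel count errs by tens of percent. Calibration tests pin the
  circle limit (roundness $1 \pm 0.05$ for radius ≥ 50) and the analytic
  square closed form ($4\pi s^2/(4s)^2 = \pi/4$). Digital-grid roundness can
  slightly exceed 1 on coarse discs; values are reported as computed, with no
  clipping, because the filter only applies a lower bound.
* **Roundness is computed on the 2-D footprint** (the z-projection), matching
  2-D segmentation of projected stacks.

# Tracking model

`match_frames()` assigns each object at frame $t{+}1$ to the modal
non-background label of frame $t$ under its pixels (spatial overlap of the
maximal modal value). Conventions:

* the mode is taken over frame-$t$ labels within the $t{+}1$ object — an
  object mostly over background but partly over one old object still joins
  that object;
* modal ties break toward the larger pixel overlap, then the lower label id;
* when two new objects claim the same ancestor, the larger overlap continues
  the track and the other starts a new one (deterministic and
  order-independent);
* no gap closing: an object that disappears is never re-linked. A spore
  removed by the roundness filter therefore *ends* its track, which is the
  intended censoring behavior.

# Growth and load quantification

**Germination call.** A track is germinating if its projected area reaches
1.5× its initial area within the first 10 h (`germination_params()`). The
area fold is used directly as the volume-proxy criterion; traces that end
before 10 h without crossing are right-censored (`NA`), not guessed.
Uniform rescaling of areas does not change the call.

**Doubling time.** `fit_doubling_time()` regresses $\ln(\mathrm{area})$ on
time and returns $T_D = \ln 2 / \mathrm{slope}$. The fit starts at the first
point reaching 1.5× the initial size: before germination the area series is
flat and would dilute the slope. Multiplicative (log-normal) measurement
noise leaves the estimator unbiased, which the tests check over 30 simulated
series.

**Maximum-growth window.** `max_growth_doubling_time()` fits every sliding
window (default 5 points) and keeps the steepest. Because the argmax of
noisy slopes is biased upward, the window should span a substantial fraction
of the exponential phase; the synthetic single-cell volume series
(`simulate_voxel_series()`) therefore defaults to 60-min sampling over 15 h,
for which the selection bias is a few percent at 5% multiplicative noise.
Shorter windows or denser sampling make $T_{D\max}$ an increasingly
optimistic (small) estimate — a property of this class of estimator, not of
the implementation.

**Load.** `load_at_start()` returns the summed z sum-projected fluorescence
within the mask at the first frame of the track. No background subtraction
is applied by default (none is part of the measurement definition); a
constant-offset correction can be applied upstream if needed.

# Fitness analytics

* `germination_success()` reports germinated/total with a Wilson 95%
  interval; Wilson because 0/n and n/n plates occur routinely in passaging
  experiments and the Wald interval degenerates there.
* `fitness_index()` is the product of germination success and the positive
  fraction — the fraction of viable offspring that carry bacteria.
* `gate_by_load()` median-splits the positive population into B+ (lower
  50%) and B++ (upper 50%); with an odd count the median element goes to
  B+, a fixed tie rule documented because instrument gates are drawn by hand
  in practice. An all-equal input is flagged degenerate.
* `group_compare()` offers the Kruskal–Wallis omnibus with Dunn's rank-based
  post-hoc z tests (tie-corrected, Bonferroni over all pairs, two-sided) and
  pairwise two-sided Mann–Whitney U tests with Benjamini–Hochberg
  adjustment, plus a compact letter display at α = 0.05. Kruskal–Wallis and
  Mann–Whitney come from base R; Dunn's test and the letter display are
  implemented here (insert-and-absorb algorithm) because no installed
  package provides them. The exact small-sample Mann–Whitney p equals full
  enumeration of rank assignments, verified by a brute-force oracle in the
  tests.
* `enrichment_fraction()` reports percentages to one decimal with an
  optional hypergeometric tail against a genome background — optional
  because the fraction itself, not a test, is the primary readout.

# The synthetic-data generator

`simulation_config()` + `generate_population()` + `render_timelapse()`
emulate the statistical structure the analysis assumes, with full ground
truth, so that every stage is testable without microscope data or trained
models.

**What is emulated.** Spores are discs (initial radius ~6 px at the default
magnification-free pixel scale) placed on a jittered grid; imaging runs 64
frames at 15-min intervals (16 h). A spore germinates with probability
`germination_probability` (default 0.52, the non-injected baseline),
optionally modulated by a logistic *decrease* with log bacterial load — only
the direction of that coupling is established, so the logistic form is a
modeling choice with the midpoint at the median load. After a normal lag
(default 240 ± 60 min) the true projected area grows exponentially with a
per-spore doubling time (default 98 ± 13.5 min), and a rectangular germ tube
(2 px/frame, width 4 px) elongates, pulling roundness down through the 0.6
cutoff a few hours after germination — the same censoring the real filter
produces. Bacterial load per spore starts log-normal and grows exponentially
(doubling 102 min ≈ 1.7 h) after a 6-h bacterial lag. Fluorescence is drawn
in one z-slice but written as a z-stack whose sum projection integrates to
the true load exactly when noise is off (the conservation oracle). Imaging
noise is additive Gaussian per channel with optional Poisson resampling;
the *measured* area series additionally carries multiplicative log-normal
jitter (default 5%), emulating focus and segmentation variability.

**What is not emulated.** No point-spread function, no photorealism, no
stage drift, no spore-spore occlusion dynamics, no z-resolved bacterial
geometry, and no µm calibration (all areas are pixels²). Fluorescence
background level and camera noise of real instruments are nominal, not
calibrated. Passing tests therefore demonstrate correctness of the
*computational* pipeline under the stated generative assumptions, not
robustness to every real-microscope artifact.

**Rendering cap.** Rendered morphology saturates at 12× the initial area
(`max_render_fold`), with the germ tube capped at 40 px and at 30% of the
area increase. The analysis never uses frames beyond the roundness cutoff
(tracks end there), and the cap keeps rendered footprints inside a
provably collision-free grid cell, which the auto-sizing of `image_shape`
relies on. True areas in the truth tables keep growing un-capped; tests that
compare measured to true series restrict to pre-saturation frames by
construction because the roundness filter ends tracks first.

**Determinism.** One global RNG stream; `run_pipeline()` seeds from
`config$seed` and reruns are bit-identical, including all per-frame
rendering draws (area jitter and tube directions are pre-drawn into the
population object, so rendering is a pure function of it).

# Numerical choices and degenerate inputs

* Empty masks raise errors in `mask_roundness()`; single-pixel objects have
  an estimated perimeter of 0 and undefined (`NA`) roundness, and are
  removed by the area floor before the roundness filter matters.
* `fit_doubling_time()` requires ≥ 3 positive points after the growth-phase
  gate and returns `NA` for non-positive slopes rather than extrapolating.
* Labeling of 8-connected components merges 4-connected labels that touch
  diagonally via union-find, on top of `EBImage::bwlabel()`.
* CSV outputs carry provenance headers (version, seed, config hash) as `#`
  comments; coordinates are pixel-based, origin top-left, y before x,
  1-based; frames 0-based; times in minutes. The 15-min interval is a
  configuration default, never hard-coded.

# Problem sizes used in the shipped checks

The parameter-recovery runs use cohorts of 50 spores × 64 frames for the
doubling-time medians (the auto-sized field is ~1100 × 1250 px), 288
single-spore traces for the germination-success baseline, paired cohorts of
50 spores for the load-ratio recovery, and a 16-point single-cell volume
series for $T_{D\max}$ — sizes at which the medians and fractions are stable
to well within the tolerances being checked while the whole suite stays
desk-scale.

# Known limitations

* The tracker is strictly consecutive-frame and overlap-based; fast-moving
  or blinking objects fragment into multiple tracks by design.
* Roundness values depend on the perimeter estimator; comparing roundness
  across software requires matching estimators, which is why the estimator
  is documented and calibrated here.
* The germination call uses the literal 1.5-fold reading of the
  area-increase criterion; if a stricter doubling criterion is wanted,
  `germination_params(fold_threshold = 2)` expresses it.
* `T_{D\max}` from short windows on noisy series is biased low; prefer the
  whole-series fit when the growth phase is identifiable.
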