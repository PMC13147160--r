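---
title: "Quantifying cold-acclimation effects on T-cell motility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cold-acclimation effects on T-cell motility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldmotility)
```

## The scientific problem

T cells survey tissue by amoeboid crawling: lamellipodia and filopodia
extend and retract continuously, translating the cell body and remodeling
its contour. Low temperature suppresses this behavior — below ~32 °C cells
progressively round up and stop — while prolonged (~24 h) culture at a
subphysiological temperature induces *cold acclimation*, restoring
motility in the cold together with increased mitochondrial spare
respiratory capacity and broad transcriptional remodeling. Quantifying
such an experiment requires three kinds of analysis, all implemented
here: per-cell motility/morphology statistics from time-lapse binary
masks, group statistics across cohorts and conditions, and summaries of
extracellular-flux and differential-expression data.

## The motility statistics

A recording is a stack of per-frame binary (or labeled) masks with known
frame interval (default 20 s, 60 frames — 20 min of imaging) and pixel
size (default 0.25 µm/px, typical for a 40× objective). Metrics are
evaluated at non-overlapping 3-min boundary pairs — frames 0→9, 9→18, …,
45→54 for 20-s frames — because consecutive, non-overlapping intervals
keep per-pair values independent; the 5 frames after frame 54 are simply
unused, which `validate_acquisition()` reports explicitly.

- **Cell deformation area**: with `C_t` the binarized cell region,
  `A_CD = Area(C_{t+1} \ C_t)` on superimposed masks — a pixel-exact set
  difference, so `A_CD(A, B) = |B| − |A ∩ B|` holds identically and
  integer translation gains exactly what it loses.
- **Centroid displacement**: Euclidean distance between unweighted
  foreground-pixel centroids of the pair. Coordinates follow the raster
  convention (row, col), origin top-left, centroid in µm as
  `x = (col − ½)·s`, `y = (row − ½)·s`.
- **Circularity index**: `perimeter² / (4π · area)`, computed per frame;
  1 for an ideal circle, larger for irregular contours. Note the
  direction of this index as printed: a cell that *rounds up* moves the
  index *down* toward 1, so cold-suppressed rounded cells score lower
  than protrusive amoeboid cells. Reports that describe rounded cold
  cells as having "increased circularity" use the reciprocal convention;
  we implement the formula exactly as printed and leave the naming
  discrepancy to the reader's attention rather than silently inverting it.

Per-cell summaries are arithmetic means over the listed pairs/frames;
cohort figures' per-cell dots are these means. Outputs carry an explicit
units column (µm/µm², falling back to px with a warning when the pixel
size is absent).

### The perimeter estimator

Circularity is exquisitely sensitive to the perimeter estimator. Counting
boundary pixels (weighted or not) biases disks far above 1 — a digitized
circle's 8-connected boundary is up to 59 % "longer" than the true
circumference — while multi-directional Crofton-style intercept counting
is exact on disks but systematically ~10 % short on axis-aligned
rectangles, enough to distort the square's continuous-limit value 4/π.
We therefore extract the 0.5-level isocontour of the zero-padded mask
(vertices at subpixel positions between foreground and background pixel
centers), apply two passes of a 3-point circular moving average to remove
the pixelation staircase, and take the closed polygon length. Measured on
rasterized references this estimator is within ~2 % on disks of radius
20–80 px (always slightly positive, so disk circularity stays at or just
above 1), ~2 % short on large squares and 2:1 rectangles, and scales to
within 5 % under ×2 nearest-neighbour upsampling. The estimator name is
recorded in every record and run manifest; `epsilon_raster`, the
raster-induced tolerance on circularity, is about 2 %.

### Tracking and inclusion

Per-frame components are defined under 8-connectivity (diagonally
touching pixels belong to one cell) and linked frame-to-frame by maximal
intersection-over-union, ties broken by smaller centroid distance then
smaller label; unmatched components start new tracks and a track that
loses its component ends (tracks cover one contiguous frame range).
Following the study's selection criteria, a cell enters the analysis only
if its track (a) spans every frame, (b) never touches the raster border,
and (c) never comes within 2 px (Chebyshev) of another cell —
"sufficiently separated to allow accurate segmentation" operationalized
as a configurable ≥ 2 px gap. Excluded tracks keep per-criterion flags so
the inclusion report can say *why* each cell was dropped. For synthetic
grayscale frames a minimal segmenter (Otsu threshold, hole filling,
removal of objects under 20 px) stands in for interactive contour
selection; real mask stacks are ingested directly from multi-page TIFF
with a JSON sidecar carrying the frame interval and pixel size.

## The synthetic amoeboid-cell generator

The generator provides ground-truthed input for every downstream stage.
Each cell combines:

- **A persistent random walk** for the centroid: fixed step length
  `speed × Δt` per frame and wrapped-normal turning with
  `E[cos Δθ] = persistence`, so `persistence = 1` is exactly ballistic
  (displacement = speed × time) and `persistence = 0` has independent
  headings. The programmed frame-to-frame speed is exact by construction.
- **A radial Fourier contour** `r(θ, t) = R(1 + Σ_k a_k(t) cos(kθ + φ_k))`
  over modes k = 2 … 7, each amplitude an Ornstein–Uhlenbeck process with
  stationary SD `protrusion_amplitude / k` and relaxation rate
  `protrusion_rate_per_min`. The k = 1 mode is excluded deliberately: to
  first order it translates the contour rather than deforming it, and
  including it couples shape noise into the centroid — with it, the
  deformation and translation channels are no longer independently
  tunable. Radii are clamped at `0.2 R` (with a warning) if the noise
  would drive them non-positive.

Cells are placed uniformly at random, rejecting placements that would
bring any frame's raster footprint within 3 px of another cell or the
border, so generated movies satisfy the inclusion criteria by
construction (the inclusion filter itself is tested on deliberately
pathological fixtures). Ground truth records each cell's programmed
centroid path and, at 3-min intervals, the programmed newly-gained area
computed at 3× subpixel resolution.

Randomness uses one root seed with per-cell child seeds
(`(root + 1000003·cell + 97·stream) mod 2³¹−1`, separate streams for
shape, track and placement), so identical configs are bit-identical and
adding a cell never perturbs earlier cells.

**What the generator does and does not emulate.** It reproduces the
*geometry* of amoeboid crawling — independently tunable translation and
contour remodeling, realistic mask rasters, non-overlapping cells at
20-s/60-frame acquisition — so it can validate the measurement chain:
that programmed speed ratios reappear as displacement fold changes, that
protrusion amplitude drives deformation area monotonically, that
centroids and areas are recovered to pixel accuracy. It does not emulate
photorealistic microscopy (no point-spread function, noise, or focus
drift), cell–cell contact, division, or the biophysics linking
temperature to speed; passing tests therefore certify the measurement
pipeline, not any biological model of temperature response. Absolute
µm-scale values are defined by the configured pixel size, as no
magnification calibration exists to reproduce.

Default study conditions mirror the imaging design: 60 frames at 20 s,
0.25 µm/px, base radius 5 µm. The focal acclimation contrast at 26 °C is
programmed as an 8-fold speed ratio (0.2 vs 1.6 µm/min, persistence 0.5)
with protrusion amplitude 0.1 vs 0.4 — speeds chosen so the programmed
displacement ratio matches the order of the reported motility rescue.

## Cohort statistics

Comparisons between two groups use Welch's t-test (two-sided,
Welch–Satterthwaite df) with stars `*` p < 0.05, `**` p < 0.01, `***`
p < 0.001, `****` p < 0.0001 (strict inequalities). Cohort summaries are
mean ± SD; SEM appears only in flux time-course output, matching the
reporting convention for those panels. Fold changes are ratios of group
means, with a non-positive reference mean treated as undefined (error)
rather than infinity. Per-temperature panels are tested independently
with no correction across panels — matching per-panel testing practice,
and a documented caveat of that practice. Paired designs are out of
scope: each condition measures different cells.

Degenerate inputs are handled explicitly: two identical constant groups
give t = 0, p = 1 with a warning; two *different* constant groups are an
error from `welch_t_test()` itself but degrade to NA comparison fields
inside `group_flux()`, where noiseless synthetic wells legitimately
produce zero-variance parameters.

## Extracellular-flux parameters

A trace is one well's OCR/ECAR sequence over the canonical mito-stress
phases basal → oligomycin → FCCP → rotenone/antimycin A (defaults: 3
cycles per phase, 6-min cycles; cycle counts are configuration, not
assertions about any instrument run). Per-phase levels follow the
vendor-style report conventions — last basal cycle, minimum
post-oligomycin, maximum post-FCCP, mean rotenone/antimycin A — with a
`phase_mean` alternative; the rule used is logged in the output. From
levels: non-mito = rotAA; basal respiration = basal − non-mito;
ATP-linked = basal − oligomycin; proton leak = oligomycin − non-mito;
maximal = FCCP − non-mito; spare capacity = maximal − basal (absolute and
percent; fold statements are over the absolute value). The decomposition
`ATP-linked + proton leak = basal respiration` holds exactly on every
trace. Negative spare capacity is reported with a warning, never clamped,
so QC can flag bad wells. Protein normalization divides all parameters by
the well's protein content (µg), making parameters exactly equivariant in
protein.

The synthetic flux conditions program a 1.69× maximal-respiration and
3.49× spare-capacity increase at comparable basal respiration and proton
leak (5 wells per condition, cycle noise 0.8 OCR units ≈ 2 % of signal).
Note the protocol level rules (min/max over cycles) make small spare
capacities slightly noise-inflated, so recovered spare-capacity folds
scatter a few percent around the programmed value.

## Differential-expression summaries

Genes are classified from `log2fc` and BH-adjusted p-values with the
standard thresholds exactly as conventionally printed: |log2FC| ≥ 1
*inclusive*, FDR < 0.05 *strict*. "Detected genes" are the rows of the
input table; no independent expression filter is applied (any such filter
belongs to the upstream model fit, which is out of scope — this module
consumes the fitted table's schema). Summaries report counts and
one-decimal percentages of detected genes; at the study scale of 15,234
genes with 1,243 up and 1,008 down spiked, the classifier recovers
8.2 % / 6.6 %. Volcano coordinates are `(log2fc, −log10 padj)` with zero
adjusted p-values floored at one tenth of the smallest nonzero value
(flagged). Heatmap matrices are row-Z-scored with the sample SD
(denominator n − 1; a documented choice, as either convention is seen in
the wild), constant rows zeroed with a warning, and values clamped to
[−2, +2].

The spiked generator draws null log2FC from N(0, 0.2) and null p-values
uniformly, spiked genes with |log2FC| ≥ the effect size and p ≤ 10⁻¹⁰;
under the null configuration the fraction passing FDR < 0.05 stays
controlled, and with a strong effect the spiked counts are recovered
exactly with overwhelming probability.

## Numerical choices and degenerate inputs

- Connectivity is fixed at 8 for components and touching tests.
- Contours are sampled at 120 uniform angles; `contour_area()` integrates
  `r²/2 dθ` on that grid and is exact for circles.
- The inclusion gap (2 px), minimum object size (20 px), classification
  thresholds and flux level rules are all configurable arguments with the
  defaults above; every configurable decision lands in the run manifest.
- Blank frames segment to empty masks with a warning (not an error);
  empty masks are errors for centroid/perimeter, which require cells.
- `validate_acquisition()` prints the total imaging time under both
  counting conventions (`n × Δt` and `(n−1) × Δt`) to avoid ambiguity,
  and warns when the metric interval is not commensurate with the frame
  interval (pairs then use the floor).

## Problem sizes used in the tests and scripts

The test suite and acceptance script run entirely on generated data:
motility cohorts of 20 cells per condition (4 fields × 5 cells,
512 × 512 px, 60 frames) for the fold-change recoveries, 6-cell cohorts
for the temperature sweep in `analysis/`, 5 wells per flux condition, and
the full 15,234-gene scale for DE summaries. These sizes were chosen to
hold Monte-Carlo error on recovered fold changes to a few percent while
keeping any single run in the tens of seconds on one core.

## Known limitations

- The tracker is overlap-based and assumes the field is stationary (as in
  fixed-dish imaging); it has no motion model, so a cell jumping farther
  than its own diameter between frames breaks its track.
- Circularity from rasters is only meaningful for cells above ~20 px
  radius; below that, `epsilon_raster` grows quickly.
- At very low programmed speeds the measured 3-min displacement has a
  small positive noise floor from raster centroid jitter, which deflates
  large programmed fold ratios by a few percent — visible in the
  recovered ~7–7.6× values for the programmed 8× contrast.
- The DE module summarizes a fitted statistics table; it does not fit the
  expression model, and percentages depend on the caller's definition of
  the detected-gene universe.
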