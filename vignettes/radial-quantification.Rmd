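---
title: "Segmenting, classifying and quantifying radially organized plant sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting, classifying and quantifying radially organized plant sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radialcells` turns two-channel confocal images of transverse sections of
radially organized plant organs — hypocotyls, stems, roots in secondary
growth — into per-cell, per-sub-region, per-quadrant quantitative tables.
Channel 1 is a cell-wall counterstain (e.g. calcofluor white) that drives
segmentation; channel 2 is the signal of interest (e.g. indirect
immunofluorescence against a cell-wall epitope). This vignette explains the
models and procedures the package implements, the parameters that matter,
and the design choices made where the method is genuinely open.

```{r setup, message = FALSE}
library(radialcells)
library(dplyr)
```

## Segmentation model

The counterstain restricts fluorescence to cell walls, so in channel 1
cells appear as dark lumens surrounded by bright walls. The segmentation
treats the smoothed image as a topographic surface and floods it from its
regional minima (Meyer's watershed, 4-connectivity): basins grow from the
lumens, and dams — labelled 0 — form on the wall ridges. Three aligned
label maps are produced:

* **ROIC**, the whole cell: one watershed basin per cell;
* **ROIL**, the lumen: within each cell, pixels below that cell's own Otsu
  threshold;
* **ROIW**, the wall: the set difference ROIC minus ROIL.

### Smoothing

`smooth_reference()` applies a separable Gaussian low-pass with variance
`smoothing_variance_px` (pixels squared; sigma is its square root),
reflective boundaries, kernel truncated at four sigma and renormalised so
total intensity is conserved. The default variance of 1 px² suits
well-stained, low-noise sections. For noisy material the variance should be
raised until spurious intensity minima stop splitting lumens: on synthetic
tissue with signal-to-noise ratio 5 (wall mean / noise sd), recovery
degrades when the variance is much below about 7 px² because residual
noise minima inside large lumens survive the merge step, while walls of
2–4 px thickness still segment reliably at considerably stronger smoothing.
The package's recommendation for such data is variance 8 px², and the
noisy-condition tests and the acceptance script use exactly that setting.
The merge threshold (below) is kept at its default throughout.

### Region merging

Watershed over-segments wherever a lumen contains more than one intensity
minimum. `merge_shallow_regions()` corrects this with a dam-saliency rule:
for two adjacent regions \(a, b\) with intensity minima \(m_a, m_b\) and
shared dam pixels \(D_{ab}\),

\[ S(a,b) \;=\; \min_{p \in D_{ab}} I(p) \;-\; \max(m_a, m_b), \]

and regions with \(S < \texttt{merge\_depth\_threshold}\) (default 10
intensity units, on the 8-bit-like scale of typical confocal exports) are
merged. Merging is iterative, lowest saliency first, with minima and
adjacency recomputed after every merge, so chains of shallow basins
collapse into one region; dam pixels left between merged regions are
absorbed into the merged label. Two readings of "the first dam pixel
touching the two regions" are possible (dam minimum, or first in flooding
order); the dam-minimum reading — the classic waterfall saliency — is
implemented because it is order-free and deterministic. Likewise the rule
could be applied in one pass or iteratively; iterative application is
chosen because a single pass leaves chains of shallow basins split, which
is exactly the artifact the rule exists to remove.

### Per-cell lumen threshold

Otsu's criterion is applied *within each cell's own footprint*, not
globally: each cell's pixel histogram (256 equal-width bins over the
cell's own range) is scanned exhaustively for the split maximising the
between-class variance, and the lumen is the set of pixels strictly below
the resulting threshold. The smallest threshold attaining the maximum is
taken, making ties deterministic. Per-cell thresholding matters because
wall brightness varies strongly across tissues (thick secondary walls vs
thin cambial walls); a global threshold misplaces lumen boundaries in
low-contrast cells. Degenerate (constant-intensity) cells get an empty
lumen: the whole cell is treated as wall, and downstream wall statistics
remain defined.

### Cropping

`crop_restrict()` keeps cells whose *centroid* falls inside a pixel
rectangle. Centroid inclusion (rather than clipping footprints) avoids
partial cells with distorted shape features; surviving cells keep their
full footprints and are relabelled consecutively.

## Radial geometry and quadrants

All position features and the quadrant split are anchored on a
user-supplied tissue center (the organ's anatomical origin), stored with
the image record so reruns are reproducible. For a cell with centroid
\(c\) and outward radial unit vector \(u\) (tissue center to centroid),
every ROIC pixel \(p\) is classified by the angle \(\varphi\) between
\(p - c\) and \(u\):

* \(|\varphi| \le 45^\circ\): quadrant 3, the **outer periclinal** sector;
* \(|\varphi| \ge 135^\circ\): quadrant 4, the **inner periclinal** sector;
* the two remaining lateral sectors are the **anticlinal** quadrants 1 and
  2, with 1 on the counter-clockwise side of \(u\) (in the x-right,
  y-down pixel frame).

Equal 90° sectors are the only symmetric reading of the quadrant split;
pixels at exactly 45° resolve to the periclinal sector, a deterministic
tie-break. Quadrant numbering orientation is a pure convention — only the
periclinal-vs-anticlinal contrast is biology-facing — and is fixed for
determinism. ROIL and ROIW inherit the ROIC assignment, so a pixel carries
the same quadrant in every ROI kind. A cell whose centroid coincides with
the tissue center has no radial direction; it is flagged and excluded from
quadrant-based measures rather than assigned arbitrarily.

## Morphometric features

`compute_feature_table()` computes 22 features per cell, covering position
(`m.cx`, `m.cy`, `Xnew`, `Ynew`, `radialV`, `angleV`), shape
(`m.majoraxes`, `m.eccentricity`, `m.theta`, `s.area`, `perimeter`,
`s.radius.mean/min/max`, `extv`, `inclV`, `P2A`, `m.theta.real`) and
counterstain intensity (`MedianROIC`, `MeanROIC`, `MedianROIW`,
`MeanROIW`). Estimator choices:

* Axis lengths come from principal-component analysis of the cell's pixel
  coordinates, scaled by \(4\sqrt{\lambda}\) so a filled ellipse recovers
  its true axis lengths; eccentricity is
  \(\sqrt{1 - \mathrm{minor}^2/\mathrm{major}^2}\).
* The perimeter is a Moore boundary walk with \(\sqrt 2\)-weighted
  diagonal steps — a standard low-bias estimator; `P2A` is the plain
  perimeter/area ratio as its description states, despite the
  "circularity" name.
* `inclV` and `m.theta.real` both measure the angle between the outward
  radial vector and the major axis and are folded to \([0, \pi/2]\) (an
  acute angle between undirected lines); they therefore coincide and are
  kept as two columns only to preserve the 22-feature contract.
  `m.theta` is the major-axis angle to the horizontal in
  \((-\pi/2, \pi/2]\).
* The wall-intensity features are computed over ROIW (their names are
  authoritative; their conventional descriptions elsewhere as "ROIC
  intensity" are treated as a recording slip).
* The historical misspelling `m.eccenticity` is accepted as an input alias
  anywhere feature names are resolved.

Single-pixel cells are degenerate: axis and radius features are 0 and a
warning is raised, rather than failing the whole table.

## Cell-type classification

A Breiman Random Forest (`randomForest`) is trained on *untransformed*
feature values — no scaling or normalisation, which for this classifier
family gives the best fit and keeps the model interpretable in feature
units. The default feature set excludes the four Cartesian coordinates
(`m.cx`, `m.cy`, `Xnew`, `Ynew`), which are arbitrary in a radially
symmetric organ; `radialV` and the intensity medians carry the
discriminative burden. Defaults: 500 trees; a seed is mandatory and stored
with the model, making training and prediction bit-reproducible.

Per-feature importance is the out-of-bag permutation importance (impurity
importance is also recorded). Reduced feature subsets are supported but
deliberately not hard-coded: which 12 or 5 features survive pruning is a
data-dependent user decision; `reduced_subset_seed()` lists the four
consistently top-ranked features (`radialV`, `MedianROIW`, `MedianROIC`,
`s.area`) as the seed of a compact set.

Every cell is classified; the **confidence score** of a cell is the
fraction of trees voting for its winning class (ties resolve to the
earlier class in the model's class list, deterministically).
`filter_by_confidence()` retains cells at or above a threshold — 0.5, 0.7
and 0.9 are the conventional working points — and the retained sets are
nested by construction, so misclassification can be traded against
coverage monotonically.

## Fluorescence quantification

The signal channel is background-corrected once per image before any
masking: the background estimate is the *median* intensity over non-tissue
pixels (ROIC = 0), subtracted everywhere with clamping at zero. The median
is robust to the bright tissue-adjacent haze that contaminates a mean.

`quantify_roi_quadrants()` then reports, for every (cell, ROI kind,
quadrant), the mean, the population (n-denominator) standard deviation and
the area of the masked pixels. Population rather than sample variance is
used because the pixels are the complete region, not a sample; the choice
is documented here because either is defensible. Empty quadrants get size
0 and missing statistics — missing, not zero, so class summaries use
per-measure n and a signal-free quadrant is never conflated with an
unmeasurable one.

Derived per-cell measures (`derive_measures()`): with per-quadrant means
\(\mu_q\) and areas \(s_q\),

* `*RPA` (per ROI kind) is the ratio of *summed* periclinal to anticlinal
  signal, \((\mu_3 s_3 + \mu_4 s_4) / (\mu_1 s_1 + \mu_2 s_2)\);
* `*RPAmean` is the ratio of mean intensities,
  \((\mu_3 + \mu_4)/(\mu_1 + \mu_2)\). The two names otherwise carry
  identical descriptions in the measure list; summed-vs-mean is the only
  reading that makes them distinct measures, and both are useful (the
  summed form weights by wall area, the mean form does not);
* `*signal` is the total summed signal \(\sum_q \mu_q s_q\), so
  `Cellsignal = Lumensignal + Wallsignal` holds exactly;
* `*signalmean` is total / area;
* `PvD` (punctateness vs diffuseness of the lumen signal) has no received
  formula; it is implemented as the coefficient of variation (pooled
  population sd / mean) of the ROIL pixel intensities — 0 for uniform
  signal, \(\sqrt{n-1}\) for a single bright pixel among \(n\) — and the
  definition is isolated in one function so alternatives (e.g. top-decile
  mass fraction) can be swapped without touching callers.

Ratios with a zero denominator are flagged missing and the cell is kept.
`summarize_by_class()` filters predictions at a confidence threshold,
groups by class, and reports mean ± sd per measure (sample sd across
cells, the error-bar convention), optionally rescaled to the maximum class
mean for relative-intensity plots.

## The synthetic tissue generator

Real sections for this assay are not redistributable, so every stage is
validated on `generate_radial_tissue()`: concentric rings of cells around
a center, one cell type per ring, emulating the ringed anatomy of a
21-day hypocotyl (xylem vessels and parenchyma, cambium, phloem fibers and
parenchyma, cortex). Cell seeds are placed by dart throwing with spacing
drawn from each ring's cell-size distribution (blue-noise spacing, so cell
sizes are realistic rather than Poisson-clustered); cells are nearest-seed
regions clipped to their ring; walls are painted on region boundaries at
ring-specific thickness — with the organ surface and pith boundary given
the same wall cross-section as interior walls — and channel intensities
are ring-specific means plus additive Gaussian noise clipped at zero.
SNR is defined as wall mean / noise sd. The default study conditions are a
512 × 512 image at 0.7 µm/px with about 150 cells in six rings, walls
150–240 and lumens 30 on an 8-bit-like scale, noiseless; channel-2 signal
(amplitude 150) confined to the xylem-vessel ring's walls, emulating a
secondary-cell-wall epitope. A denser 896 × 896 variant
(`classification_tissue_spec()`, 320 cells, ≥ 40 per class) serves
classifier training; its `radius_scale` argument shifts ring boundaries to
emulate genotypes with altered tissue proportions.

What the generator does **not** emulate: point-spread-function blur,
wall texture, uneven illumination, bleed-through between channels,
out-of-plane structure, and irregular (non-annular) tissue architecture.
Passing tests therefore demonstrate the correctness and robustness of the
algorithms under controlled geometry and noise, not segmentation accuracy
on any particular microscope's output; on real data the smoothing variance
and merge depth remain the user's responsibility, tuned on training images
exactly as the pipeline's training workflow prescribes.

## Numerical choices and degenerate inputs

* Intensities are processed as floating point regardless of input dtype;
  TIFF storage is 16-bit with rounding, so integer-valued images
  round-trip exactly.
* Watershed flooding is ordered by (intensity, insertion order), making
  dam placement deterministic; merge ties resolve to the lowest label
  pair. Watershed output is exactly invariant to adding a constant on
  integer-valued rasters; after smoothing, floating-point ties can
  legitimately reorder plateau flooding, so exact shift invariance is
  only guaranteed pre-smoothing.
* Otsu scans 256 equal-width bins of each cell's own range; the smallest
  maximising threshold is returned.
* A flat image (single regional minimum) segments to one region with a
  warning; constant cells get empty lumens; cells whose lumen is the whole
  cell get an empty wall with a warning; quadrant-undefined cells (centroid
  on the tissue center) are excluded from quadrant measures.
* Pooled lumen statistics for `PvD` are weighted by integer pixel counts,
  so a uniform lumen gives `PvD` exactly 0.

## Problem sizes used by the test suite

Unit tests run on a compact 3-ring, 256 px, ~32-cell tissue; segmentation
recovery is assessed on the default 512 px, ~150-cell conditions
(noiseless and SNR 5, two to three replicate sections); classification
recovery trains on one 320-cell tissue and predicts a second, independent
one. These sizes were chosen as the smallest at which ring geometry,
per-class cell counts and noise behaviour are all representative.

## Known limitations

* Dams are excluded from all ROIs (cells are disjoint), which biases wall
  thickness slightly low where walls are thin; merged-away dams are the
  exception.
* 2-D only: no z-stacks, no volumetric quadrants.
* The classifier transfers across genotypes only as far as ring geometry
  does; with shifted ring radii, errors concentrate at ring boundaries —
  the dominant radial feature is a strength within a genotype and a
  liability across them. Scaling or dropping `radialV` is the documented
  escape hatch.
* `LumenRPA`-style ratios are undefined for cells whose anticlinal sectors
  carry no signal; downstream summaries must respect the per-measure n.
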