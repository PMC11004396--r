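---
title: "Methods: emergence-rate mapping by vegetation-index fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emergence-rate mapping by vegetation-index fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`otsufuse` estimates the emergence rate of row-sown cotton — the
percentage of sown seeds that produced a visible seedling — from a pair of
co-registered rasters: a visible RGB image in 8-bit digital numbers (DN)
and a five-band reflectance stack (Blue, Green, Red, RedEdge, NIR, each in
[0, 1]). The method is pixel-spectral, not morphological: at a ground
sampling distance (GSD) of ~1.6 cm/px a seedling canopy spans only a few
pixels, too few for shape features, but its spectrum differs sharply from
the background in the red and NIR regions. The pipeline assumes:

* the two rasters are co-registered, radiometrically calibrated, and free
  of stitching artifacts (orthomosaic preparation is upstream of this
  package);
* seedling canopies do not overlap (true at the 2–4 leaf stage with 10 cm
  plant spacing), so one connected component is one plant;
* a set of manually labeled pixels of the four surface classes
  (seedling, bare soil, mulch film, drip tape) is available for mask
  orientation, index scoring, and classifier training.

Two segmentation strategies produce the seedling mask:

1. **Otsu-intersection (OI).** Every layer of a 39-layer index bank is
   binarized with Otsu's method and oriented so that seedlings are
   foreground. Each oriented mask is scored by *balanced separation
   accuracy*: the mean of seedling recall in the foreground and
   non-seedling rejection in the background, computed over the labeled
   pixels. The top six indices are fused by pixelwise logical AND.
   Intersection is the right fusion for this task because the failure
   modes of individual indices are disjoint (soil-texture noise for
   ratio-type indices, tape shadows for NDVI-type indices): a pixel
   survives only if every key index calls it seedling.
2. **Pixel classification.** A 4-class SVM (RBF), random forest, or KNN
   model is trained on per-pixel feature vectors over a feature group
   (visible 20 layers, multispectral 19, or all 39), using a stratified
   calibration/validation split of the labeled pixels, then applied to
   every pixel; the three non-seedling classes collapse to background.

Either mask is then cleaned morphologically and converted to counts:
connected components are labeled (8-connectivity by default), each
component is assigned to the square grid cell containing its centroid, and
the per-cell rate is `NE / NS × 100`, with `NS` either supplied per cell or
derived from the areal seeding rate as
`NS = round(rate_per_m2 × (grid_px × gsd_cm / 100)^2)`.

Accuracy of the inversion is summarized by RMSE, MAE, and two R²
variants. `r2_standard` is the coefficient of determination
`1 − SSres/SStot`; `r2_printed` is the explained-sum-of-squares ratio
`Σ(ŷᵢ − ȳ)² / Σ(yᵢ − ȳ)²`, a form some field studies print for
validation scatter. The two coincide exactly when the estimates are OLS
fitted values of the measurements and diverge otherwise, so both are
reported rather than silently substituting one for the other;
`r2_standard` is the headline metric.

## The index bank

The bank contains 20 visible layers (R, G, B digital numbers plus 17
visible indices) and 19 multispectral layers (5 reflectance bands plus 14
indices). Conventions:

* Lower-case `r, g, b` are chromatic coordinates `r = R/(R+G+B)` etc.;
  indices written with lower-case symbols in the literature (NGRDI, GLI,
  VARI, ExR/ExG/ExB/ExGR) are evaluated on them. CIVE, VEG, MExG, IKAW
  and TGI are evaluated on raw digital numbers, following the symbol
  convention of their original definitions. VARI uses its standard form
  `(g − r)/(g + r − b)`.
* RDVI is `(ρNIR − ρRed)/√(ρNIR + ρRed)` and MCARI is implemented as the
  standard MCARI2 expression
  `1.5(2.5(ρNIR − ρRed) − 1.3(ρNIR − ρGreen)) / √((2ρNIR+1)² − (6ρNIR − 5√ρRed) − 0.5)`;
  both are the canonical radical forms of these indices.
* All arithmetic is double precision; DN channels are converted to float
  before any formula.
* **Invalid-pixel policy.** Wherever a formula is undefined (zero
  denominator, zero chromatic sum, negative radicand), the pixel is set to
  `NA` and flagged, never silently zeroed. Invalid pixels are excluded
  from Otsu histograms and forced to background after binarization;
  labeled pixels with invalid features are dropped (with a count) from
  classifier training; whole-scene classification sends them to
  background. Exclusion avoids biasing thresholds toward an arbitrary
  fill value.

## Otsu thresholding: numerical conventions

* Histogram: 256 bins spanning `[min, max]` of the *valid* pixels. 256
  matches the classic formulation and the 8-bit depth of the visible
  data; since binning is min–max based, the resulting mask is invariant
  under positive affine transforms of a layer, so whether an index was
  pre-scaled is immaterial (this invariance is asserted in the tests).
* The split maximizing between-class variance is chosen; among exact ties
  the lowest bin wins (deterministic).
* Classification convention: strictly-greater-than goes to class 1. This
  is stated explicitly because it decides single-bin edge cases.
* A layer whose valid pixels are all equal is rejected as degenerate.
* Mask orientation: if the majority of seedling-labeled pixels land on
  the 0 side, the mask is inverted; an exact 50/50 tie keeps the current
  orientation with a warning. Orientation is idempotent.

## Key-index selection

The original workflow selected key indices by accuracy validation *and
visual inspection*. Visual inspection is not implementable, so selection
is fully formalized as the balanced separation score with `top_k = 6`
(matching the six key indices of the reference workflow); ties are broken
by registry order, which prefers the canonical indices listed first. The
canonical set {NDVI, RVI, SAVI, EVI2, OSAVI, MCARI} remains available as
`preset = "paper"`. On generated scenes the auto-selection is typically
filled by NIR/Red-family multispectral indices whose labeled-pixel score
saturates at 1; NDVI itself can fall just below the saturated group
because drip-tape pixels with near-zero red reflectance produce spuriously
high NDVI values — the same tape-noise sensitivity observed in real
fields.

## Pixel classifiers

Hyperparameters are deliberately plain, since the workflow being
reproduced reports none: SVM with RBF kernel and cost 1 (one-vs-one
multi-class, the standard `e1071` behavior), random forest with 100
trees, KNN with k = 5. Features are standardized to calibration-set mean
and SD for SVM and KNN (distance-based methods) and left raw for random
forest (scale-invariant); both choices are overridable. The
calibration/validation split is stratified per class with
`round(2n/3)` calibration pixels by default; explicit per-class counts are
a first-class option because published sample tables are not always a
consistent rounding of 2/3. All stochastic steps (split, forest, KNN tie
breaks) are driven by one user-supplied seed.

## Morphological cleaning and counting

Cleaning applies, in order, three single-pass 3×3 neighborhood operators
and an area filter:

1. **fill** — a 0-pixel whose four 4-neighbors are all 1 becomes 1
   (closes isolated interior holes);
2. **hbreak** — a 1-pixel whose 3×3 neighborhood matches the H pattern
   (two full parallel bars bridged by the center, in either orientation)
   is removed;
3. **diag** — a 0-pixel flanked by two orthogonally adjacent foreground
   4-neighbors whose shared diagonal is background becomes 1, eliminating
   8-connectivity of the background across foreground diagonals;
4. objects smaller than 2 pixels are deleted — a literal reading of
   "objects with pixels below 2": exactly the 1-pixel specks.

Borders are zero-padded. The operator truth tables are frozen in the test
fixtures. Connected components are labeled by iterative minimum-label
propagation (exact, convergence bounded by component diameter — a few
iterations for few-pixel canopies) under 8-connectivity by default,
configurable to 4; the 4-connectivity labeling is cross-checked against an
independent implementation (`EBImage::bwlabel`) in the tests.

Components are assigned to grid cells by centroid. This guarantees each
seedling is counted exactly once even when its canopy straddles a grid
line; the per-cell counts therefore partition the total count. The grid
default of 144 px corresponds to one mulch-film width at 1.607 cm/px.
With a scalar `NS`, only full cells are scored and components outside
them are dropped with a log message; a per-cell `NS` table scores exactly
the listed cells.

## The synthetic scene generator

The generator is the package's test bed and defines its study
conditions. It emulates:

* **Geometry** — vertical mulch-film strips of 144 px (~2.31 m) separated
  by 30 px bare-soil gaps; per film, three 1-px drip tapes with plant-row
  pairs 3 px either side (the 66 + 10 cm row configuration); seeds every
  6 px (~10 cm) along each row. Defaults: 1008×1008 px, GSD 1.607 cm/px,
  49 full 144-px grid cells, ~5900 sown seeds.
* **Emergence** — i.i.d. Bernoulli per seed, default probability 0.7
  (field-realistic after erosion damage); emerged seeds are painted as
  filled disks with radius uniform in [1, 2] px (3–6 cm canopies).
  Configurations whose disks could overlap across seeds are rejected.
* **Spectra** — class mean plus additive Gaussian noise, clipped to the
  valid range; film gets twice the noise SD (glare). The means encode the
  orderings observed in such fields: film brightest and tape darkest in
  every band, seedling ≈ soil in blue/green, seedling < soil in red,
  seedling > soil in red-edge/NIR, and R > G > B in digital numbers. No
  published per-class means exist for this system, so the defaults are
  plausible magnitudes chosen once (soil red reflectance 0.22 vs seedling
  0.08; seedling NIR 0.50 vs soil 0.30; DN noise SD 5, reflectance noise
  SD 0.01) and validated structurally by `validate_spectra()`. All
  spectra are user-configurable.
* **Determinism** — one RNG stream seeded from `rng_seed`, consumed in
  documented order (emergence flags, radii, DN noise R/G/B, reflectance
  noise Blue→NIR); identical configurations give bit-identical scenes.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real imagery: orthomosaic stitching artifacts and
band misregistration, radiometric miscalibration, within-class spectral
texture (soil moisture mottling, film wrinkles beyond inflated noise),
cast shadows (only an optional 1-px tape fringe), weeds, and emergence
that is spatially correlated rather than i.i.d. Real-field accuracy must
be established on real imagery; the synthetic results validate the
machinery (formulas, thresholds, fusion logic, counting, inversion
algebra), not field performance.

## Problem sizes and tolerances in the test suite

The suite exercises the full default scene (1008×1008 px, 49 grids) once
for the end-to-end recovery check — per-grid MAE within 5 percentage
points and absolute grid-mean bias within 3 points for the OI pipeline;
validation pixel accuracy at least 95% and MAE within 5 points for the
all-VIs KNN pipeline; multispectral feature groups at least as accurate
as visible ones for every classifier. Unit tests run on 288–600 px
scenes and a cached 432×432 "bundled" scene. Formula equivalence is
checked against naive per-pixel oracles at 1e-9 relative tolerance on
1000 random pixels; Otsu is checked against an exhaustive 256-candidate
search for exact agreement on 100 random 64×64 layers.

## Known limitations

* The balanced-accuracy selection score depends on the labeled-pixel
  sample; with few labels it can saturate and leave the top-6 choice to
  registry-order tie-breaking.
* Seedlings closer than one canopy diameter merge into one component;
  the package deliberately does not attempt overlap splitting (out of
  scope at the 2–4 leaf stage).
* `NS` from the areal seeding-rate formula assumes spatially uniform
  sowing; on scenes where film layout makes per-cell seed counts uneven,
  supply the per-cell table instead.
* The `r2_printed` variant is unbounded above and should be read as a
  fidelity report of the printed formula, not as a goodness-of-fit
  measure.
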