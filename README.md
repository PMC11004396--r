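# otsufuse

Seedling emergence mapping from drone imagery by Otsu-intersection fusion
of vegetation indices.

## The problem

Estimating how many sown seeds actually emerged is a routine but
labor-intensive task in row-crop management — particularly in mulched
cotton fields, where wind erosion after dust storms can wipe out whole
seed holes and growers must decide quickly whether to re-sow. Low-altitude
drone imagery can replace manual counting, but at seedling stage (2–4
leaves, 3–6 cm canopies, ~1.6 cm/px ground sampling distance) a cotton
seedling is a blob of a few pixels sitting on a visually hostile
background: highly reflective plastic mulch film, black polyethylene drip
tape, and bare soil whose visible color is nearly identical to the
seedlings'.

`otsufuse` implements a pixel-level pipeline for this setting:

1. **Index bank** — from a co-registered 3-channel visible image (digital
   numbers) and a 5-band reflectance stack (Blue, Green, Red, RedEdge,
   NIR), compute 39 spectral layers: the raw channels plus 17 visible and
   14 multispectral vegetation indices (NDVI, RVI, SAVI, EVI2, OSAVI,
   MCARI, ExG, CIVE, …).
2. **Otsu screening** — binarize every layer with Otsu's method (256-bin
   min–max histogram, maximum between-class variance), orient each mask so
   seedlings are foreground, and score each index by balanced separation
   accuracy over labeled pixels.
3. **Otsu-intersection (OI) fusion** — take the pixelwise AND of the
   oriented masks of the best six ("key") indices. Different indices are
   fooled by different background structures, so the intersection retains
   only pixels all six agree on.
4. **Pixel classification** (alternative strategy) — 4-class SVM / random
   forest / KNN on the per-pixel feature vectors, with a stratified
   calibration/validation split.
5. **Counting and inversion** — morphological cleaning (fill, hbreak,
   diagonal fill, removal of sub-2-pixel objects), connected-component
   counting, assignment of components to square grid cells (144 px = one
   film width) by centroid, and per-cell emergence rate
   `NE / NS × 100%`, where `NS` is the number of seeds sown in the cell.
6. **Evaluation** — RMSE, MAE, and two R² variants between estimated and
   reference rates.

Because no field imagery ships with the package, a ground-truthed
synthetic scene generator (`generate_scene()`) reproduces the planting
geometry (vertical mulch-film strips, six plant rows paired around three
drip tapes per film, 10 cm seed spacing) and the spectral ordering of the
four surface classes, with Bernoulli emergence at a known rate. Every
stage of the pipeline is tested end to end against this generator.

## Worked example

```r
library(otsufuse)

sim    <- generate_scene(scene_config(width_px = 432, height_px = 432,
                                      rng_seed = 1))   # 70% emergence
labels <- sample_label_pixels(sim$truth, seed = 2)

res <- run_oi_pipeline(sim$scene, labels,
                       seeds_sown = sim$truth$per_grid[c("grid_row",
                                                         "grid_col", "ns")])
res$selection
#> <key_vi_selection> 6 of 39 indices: DVI, RDVI, SAVI, NLI, MNLI, TVI

head(res$emergence, 3)
#>   grid_row grid_col  ne  ns rate_pct
#> 1        1        1 106 144 73.61111
#> 2        1        2  66  96 68.75000
#> 3        1        3  97 144 67.36111

compare_maps(truth_emergence_map(sim$truth), res$emergence)$report
#> <metric_report> n = 9
#>   R2 (standard) = 1
#>   R2 (printed)  = 1
#>   RMSE = 0%
#>   MAE  = 0%
#>   bias = 0%
```

The six auto-selected key indices are all multispectral NIR/Red-family
indices — visible indices cannot separate seedlings from film-brightened
soil — and on this scene the fused mask recovers the true per-grid counts
exactly: 106 of 144 seeds emerged in cell (1,1), a 73.6% rate, and the
per-cell estimates match the generator's ground truth (RMSE = 0).
`run_ml_pipeline()` runs the SVM/RF/KNN alternative the same way.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "otsufuse", package = "otsufuse"))')
Rscript $CLI simulate --out scene --seed 5 --width 300 --height 300
Rscript $CLI fuse     --scene scene --labels scene/labels.csv --out fused.tif
Rscript $CLI count    --mask fused.tif --grid-px 144 --gsd-cm 1.607 \
                      --seed-rate 26 --out emergence.csv
```

## Documentation

The methods vignette (`vignettes/emergence-mapping.Rmd`) describes the
model assumptions, the synthetic-scene design, parameter defaults and
numerical conventions (histogram binning, tie-breaks, invalid-pixel
policy, connectivity), and known limitations.
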