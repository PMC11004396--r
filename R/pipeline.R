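#' Run the Otsu-intersection (OI) emergence pipeline
#'
#' End-to-end convenience wrapper: computes the index stack, Otsu-screens
#' every layer against the labeled pixels, selects the key indices
#' (default: top 6 by balanced separation score, or the `"paper"` preset),
#' fuses their oriented masks by intersection, cleans the fused mask
#' morphologically, and inverts per-grid emergence rates.
#'
#' @param scene a [multiband_scene].
#' @param labels label table (all labeled pixels).
#' @param seeds_sown scalar NS per cell or per-cell table; see
#'   [grid_emergence()].
#' @param grid_px grid-cell side in pixels (default 144).
#' @param group index group to screen (default `"all"`).
#' @param top_k number of key indices (default 6).
#' @param preset `NULL` or `"paper"`.
#' @param min_px morphological area threshold (default 2).
#' @return A list: `emergence` (an `emergence_map`), `mask` (cleaned fused
#'   mask), `fused` (pre-cleaning fusion), `selection`
#'   (a `key_vi_selection`), `screen` (masks/props/scores of every layer).
#' @export
run_oi_pipeline <- function(scene, labels, seeds_sown, grid_px = 144L,
                            group = "all", top_k = 6L, preset = NULL,
                            min_px = 2L) {
  stack <- compute_stack(scene, group = group)
  screen <- screen_indices(stack, labels)
  selection <- select_key_vis(screen$scores, top_k = top_k, preset = preset)
  fused <- oi_fuse(screen$masks[selection$chosen])
  mask <- morph_filter(fused, min_px = min_px)
  emergence <- grid_emergence(mask, grid_px = grid_px,
                              seeds_sown = seeds_sown)
  list(emergence = emergence, mask = mask, fused = fused,
       selection = selection, screen = screen)
}

#' Run a machine-learning emergence pipeline
#'
#' End-to-end convenience wrapper for the pixel-classification strategy:
#' computes the index stack of the requested feature group, splits the
#' labeled pixels (unless a `split` column is already present), trains the
#' classifier on the calibration split, classifies every pixel of the
#' scene, cleans the seedling mask morphologically, and inverts per-grid
#' emergence rates.
#'
#' @inheritParams run_oi_pipeline
#' @param method `"svm"`, `"rf"` or `"knn"`.
#' @param group feature group: `"visible"`, `"multispectral"` or `"all"`.
#' @param seed RNG seed for split and training.
#' @param split_fraction calibration fraction (default 2/3).
#' @param split_counts optional explicit per-class calibration counts.
#' @return A list: `emergence`, `mask`, `label_map`, `model`, `validation`
#'   (CS/TS accuracy on the validation split), `labels` (with split tags).
#' @export
run_ml_pipeline <- function(scene, labels, seeds_sown, method = "knn",
                            group = "all", grid_px = 144L, seed = 1L,
                            split_fraction = 2 / 3, split_counts = NULL,
                            min_px = 2L) {
  stack <- compute_stack(scene, group = group)
  if (!"split" %in% names(labels)) {
    labels <- split_samples(labels, fraction = split_fraction, seed = seed,
                            counts = split_counts)
  }
  model <- train_classifier(labels, stack, method = method, seed = seed)
  validation <- validate_classifier(model, stack, labels)
  cls <- classify_scene(model, stack)
  mask <- morph_filter(cls$mask, min_px = min_px)
  emergence <- grid_emergence(mask, grid_px = grid_px,
                              seeds_sown = seeds_sown)
  list(emergence = emergence, mask = mask, label_map = cls$label_map,
       model = model, validation = validation, labels = labels)
}
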