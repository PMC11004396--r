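# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The bundled mid-size scene: 432x432 px (3x3 full grids of 144 px),
# default study conditions (70% emergence), fixed seeds.
bundled_scene <- function() {
  cached("bundled", {
    cfg <- scene_config(width_px = 432L, height_px = 432L, rng_seed = 101L)
    out <- generate_scene(cfg)
    out$labels <- sample_label_pixels(out$truth, seed = 102L)
    out
  })
}

bundled_stack <- function() {
  cached("bundled_stack", compute_stack(bundled_scene()$scene, "all"))
}

bundled_screen <- function() {
  cached("bundled_screen",
         screen_indices(bundled_stack(), bundled_scene()$labels))
}

# Paint k disjoint square blobs of side `side` on an oriented mask.
blob_mask <- function(k, h = 60L, w = 60L, side = 2L, gap = 6L) {
  m <- matrix(0L, h, w)
  per_row <- max(1L, (w - gap) %/% (side + gap))
  for (i in seq_len(k)) {
    br <- (i - 1L) %/% per_row
    bc <- (i - 1L) %% per_row
    r0 <- 2L + br * (side + gap)
    c0 <- 2L + bc * (side + gap)
    stopifnot(r0 + side - 1L <= h, c0 + side - 1L <= w)
    m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 1L
  }
  as_oriented_mask(m)
}

as_oriented_mask <- function(values, source = "test") {
  structure(list(values = values, threshold = NA_real_, source = source,
                 seedling_is_one = TRUE,
                 invalid = matrix(FALSE, nrow(values), ncol(values))),
            class = "binary_mask")
}

as_unoriented_mask <- function(values, source = "test") {
  m <- as_oriented_mask(values, source)
  m$seedling_is_one <- NA
  m
}

# Build an emergence_map directly from a per-cell table (for evaluation
# tests).
manual_emergence_map <- function(df, grid_px = 144L) {
  df$rate_pct <- df$ne / df$ns * 100
  structure(df, grid_px = as.integer(grid_px), n_dropped = 0L,
            n_objects = sum(df$ne),
            summary = c(mean = mean(df$rate_pct),
                        median = stats::median(df$rate_pct)),
            class = c("emergence_map", "data.frame"))
}
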