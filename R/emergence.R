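# Morphological cleaning, connected-component counting, and grid-based
# emergence-rate inversion.

# 3x3 neighbourhood operators in the classical lookup-table style. Borders
# are treated as background (zero padding).

# Fill isolated interior pixels: a 0 whose four 4-neighbours are all 1
# becomes 1.
morph_fill_once <- function(m) {
  n <- shift_mat(m, 1, 0)
  s <- shift_mat(m, -1, 0)
  e <- shift_mat(m, 0, -1)
  w <- shift_mat(m, 0, 1)
  out <- m
  out[m == 0L & n == 1L & s == 1L & e == 1L & w == 1L] <- 1L
  out
}

# Remove H-connected pixels: a 1 whose 3x3 neighbourhood matches exactly
#   1 1 1        1 0 1
#   0 1 0   or   1 1 1
#   1 1 1        1 0 1
# is set to 0.
morph_hbreak_once <- function(m) {
  nw <- shift_mat(m, 1, 1);  n <- shift_mat(m, 1, 0);  ne <- shift_mat(m, 1, -1)
  w  <- shift_mat(m, 0, 1);                            e  <- shift_mat(m, 0, -1)
  sw <- shift_mat(m, -1, 1); s <- shift_mat(m, -1, 0); se <- shift_mat(m, -1, -1)
  h1 <- nw & n & ne & sw & s & se & !w & !e   # horizontal bars
  h2 <- nw & w & sw & ne & e & se & !n & !s   # vertical bars
  out <- m
  out[m == 1L & (h1 | h2)] <- 0L
  out
}

# Diagonal fill: eliminate 8-connectivity of the background. A 0 pixel is
# set to 1 when two orthogonally adjacent 4-neighbours are foreground but
# the diagonal between them is background, i.e. the background would
# otherwise cross a foreground diagonal:
#   0 1 .
#   1 0 .   ->  centre becomes 1 (and the three rotations).
morph_diag_once <- function(m) {
  nw <- shift_mat(m, 1, 1);  n <- shift_mat(m, 1, 0);  ne <- shift_mat(m, 1, -1)
  w  <- shift_mat(m, 0, 1);                            e  <- shift_mat(m, 0, -1)
  sw <- shift_mat(m, -1, 1); s <- shift_mat(m, -1, 0); se <- shift_mat(m, -1, -1)
  hit <- (!nw & n & w) | (!ne & n & e) | (!sw & s & w) | (!se & s & e)
  out <- m
  out[m == 0L & hit] <- 1L
  out
}

#' Morphological cleaning of a seedling mask
#'
#' Applies, in order: fill (set 0-pixels whose four 4-neighbours are all 1),
#' hbreak (remove pixels whose neighbourhood matches the H pattern), diag
#' (add pixels to break 8-connectivity of the background across foreground
#' diagonals), then deletes connected objects smaller than `min_px` pixels
#' (default 2, i.e. exactly the 1-pixel specks). Each operator is a single
#' pass of its 3x3 lookup rule with zero-padded borders.
#'
#' @param mask an oriented `binary_mask`.
#' @param min_px minimum object area kept (objects with fewer pixels are
#'   deleted).
#' @param connectivity connectivity used by the area filter (default 8).
#' @return The cleaned `binary_mask`.
#' @export
morph_filter <- function(mask, min_px = 2L, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!isTRUE(mask$seedling_is_one)) {
    stop("mask is not oriented; run orient_mask() first", call. = FALSE)
  }
  m <- morph_fill_once(mask$values)
  m <- morph_hbreak_once(m)
  m <- morph_diag_once(m)
  if (min_px > 1L) {
    lab <- label_components(m, connectivity = connectivity)
    if (lab$count > 0L) {
      sizes <- tabulate(lab$labels[lab$labels > 0L], lab$count)
      small <- which(sizes < min_px)
      if (length(small)) m[lab$labels %in% small] <- 0L
    }
  }
  mask$values <- m
  mask
}

#' Connected-component labeling
#'
#' Labels the foreground of a binary image under 8- (default) or
#' 4-connectivity by iterative minimum-label propagation until a fixed
#' point; labels are renumbered 1..count in order of each component's
#' first pixel (column-major).
#'
#' @param values integer/logical 0-1 matrix, or a `binary_mask`.
#' @param connectivity 8 (default) or 4.
#' @return A list: `labels` (integer matrix, 0 = background) and `count`.
#' @export
label_components <- function(values, connectivity = 8L) {
  if (inherits(values, "binary_mask")) values <- values$values
  stopifnot(is.matrix(values))
  fg <- values != 0L
  h <- nrow(values)
  w <- ncol(values)
  if (!any(fg)) {
    return(list(labels = matrix(0L, h, w), count = 0L))
  }
  offs <- neighbour_offsets(connectivity)
  lab <- matrix(Inf, h, w)
  lab[fg] <- which(fg)  # seed with linear index
  repeat {
    nxt <- lab
    for (o in offs) {
      nxt <- pmin(nxt, shift_mat(lab, o[1], o[2], fill = Inf))
    }
    nxt[!fg] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- lab[fg]
  f <- factor(ids, levels = sort(unique(ids)))
  out <- matrix(0L, h, w)
  out[fg] <- as.integer(f)
  list(labels = out, count = nlevels(f))
}

#' Count seedling objects in a mask
#'
#' Each connected foreground component is one seedling: seedlings are
#' counted as independent individuals, so canopy size does not influence
#' the count.
#'
#' @inheritParams label_components
#' @return A list: `labels`, `count`, and `centroids` (data.frame `id`,
#'   `row`, `col` — component centroids in pixel coordinates).
#' @export
count_objects <- function(values, connectivity = 8L) {
  lab <- label_components(values, connectivity = connectivity)
  if (lab$count == 0L) {
    return(c(lab, list(centroids = data.frame(id = integer(0),
                                              row = numeric(0),
                                              col = numeric(0)))))
  }
  fg <- which(lab$labels > 0L)
  id <- lab$labels[fg]
  rr <- (fg - 1L) %% nrow(lab$labels) + 1L
  cc <- (fg - 1L) %/% nrow(lab$labels) + 1L
  cent <- data.frame(
    id = seq_len(lab$count),
    row = as.numeric(tapply(rr, id, mean)),
    col = as.numeric(tapply(cc, id, mean))
  )
  c(lab, list(centroids = cent))
}

#' Seeds sown per grid cell from the seeding rate
#'
#' Converts an areal seeding rate to the expected number of seeds in one
#' square grid cell: `NS = round(rate * (grid_px * gsd_cm / 100)^2)`.
#'
#' @param gsd_cm ground sampling distance, cm per pixel.
#' @param grid_px grid-cell side in pixels.
#' @param seeding_rate_per_m2 seeds sown per square metre.
#' @return Integer NS.
#' @export
seeds_per_grid <- function(gsd_cm, grid_px, seeding_rate_per_m2) {
  stopifnot(gsd_cm > 0, grid_px > 0, seeding_rate_per_m2 > 0)
  as.integer(round(seeding_rate_per_m2 * (grid_px * gsd_cm / 100)^2))
}

#' Grid-based emergence-rate inversion
#'
#' Divides the image into square grid cells of `grid_px` pixels, assigns
#' each connected seedling component to the cell containing its centroid
#' (so a seedling straddling a grid line is counted exactly once), and
#' computes the per-cell emergence rate `NE / NS x 100`. With a scalar
#' `seeds_sown`, only full cells are scored and components whose centroid
#' falls outside them are dropped with a message; a per-cell table
#' (`grid_row`, `grid_col`, `ns`) scores exactly the listed cells.
#'
#' @param mask an oriented `binary_mask` (typically after [morph_filter()]).
#' @param grid_px grid-cell side in pixels.
#' @param seeds_sown scalar NS per cell, or a data.frame with columns
#'   `grid_row`, `grid_col`, `ns` (NS > 0).
#' @param connectivity component connectivity (default 8).
#' @return An `emergence_map`: data.frame with `grid_row`, `grid_col`,
#'   `ne`, `ns`, `rate_pct`; attributes `grid_px`, `n_dropped`, and
#'   `summary` (mean/median estimated rate).
#' @export
grid_emergence <- function(mask, grid_px, seeds_sown, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!isTRUE(mask$seedling_is_one)) {
    stop("mask is not oriented; run orient_mask() first", call. = FALSE)
  }
  h <- nrow(mask$values)
  w <- ncol(mask$values)
  grid_px <- as.integer(grid_px)
  if (grid_px <= 0) stop("grid_px must be positive", call. = FALSE)
  if (h < grid_px || w < grid_px) {
    stop("mask (", h, "x", w, ") is smaller than one grid cell (",
         grid_px, " px)", call. = FALSE)
  }
  if (is.data.frame(seeds_sown)) {
    stopifnot(all(c("grid_row", "grid_col", "ns") %in% names(seeds_sown)))
    cells <- seeds_sown[, c("grid_row", "grid_col", "ns")]
  } else {
    stopifnot(is.numeric(seeds_sown), length(seeds_sown) == 1L)
    n_gr <- h %/% grid_px
    n_gc <- w %/% grid_px
    cells <- data.frame(grid_row = rep(seq_len(n_gr), each = n_gc),
                        grid_col = rep(seq_len(n_gc), times = n_gr),
                        ns = as.integer(seeds_sown))
  }
  if (any(cells$ns <= 0)) {
    stop("every scored grid cell needs NS > 0 seeds sown", call. = FALSE)
  }
  obj <- count_objects(mask$values, connectivity = connectivity)
  cent <- obj$centroids
  gr <- ceiling(cent$row / grid_px)
  gc <- ceiling(cent$col / grid_px)
  cell_key <- paste(cells$grid_row, cells$grid_col)
  comp_key <- paste(gr, gc)
  scored <- comp_key %in% cell_key
  n_dropped <- sum(!scored)
  if (n_dropped > 0L) {
    message("grid_emergence: ", n_dropped,
            " component(s) fell outside scored cells and were dropped")
  }
  ne <- as.integer(table(factor(comp_key[scored], levels = cell_key)))
  out <- data.frame(grid_row = cells$grid_row, grid_col = cells$grid_col,
                    ne = ne, ns = as.integer(cells$ns))
  out$rate_pct <- out$ne / out$ns * 100
  structure(out,
            grid_px = grid_px,
            n_dropped = n_dropped,
            n_objects = obj$count,
            summary = c(mean = mean(out$rate_pct),
                        median = stats::median(out$rate_pct)),
            class = c("emergence_map", "data.frame"))
}

#' Ground-truth emergence map of a synthetic scene
#'
#' Wraps the per-grid truth table of [generate_scene()] as an
#' `emergence_map` so it can be compared with pipeline estimates via
#' [compare_maps()].
#'
#' @param truth a `ground_truth`.
#' @return An `emergence_map` of the true per-cell rates.
#' @export
truth_emergence_map <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- truth$per_grid
  structure(out,
            grid_px = truth$grid_px,
            n_dropped = 0L,
            n_objects = sum(out$ne),
            summary = c(mean = mean(out$rate_pct),
                        median = stats::median(out$rate_pct)),
            class = c("emergence_map", "data.frame"))
}

#' Write an emergence map as CSV
#'
#' Columns `grid_row,grid_col,NE,NS,rate_pct`.
#'
#' @param map an `emergence_map`.
#' @param path output CSV path.
#' @export
write_emergence <- function(map, path) {
  df <- data.frame(grid_row = map$grid_row, grid_col = map$grid_col,
                   NE = map$ne, NS = map$ns, rate_pct = map$rate_pct)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
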