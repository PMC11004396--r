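#' Default class spectra for the synthetic field
#'
#' Per-class mean digital numbers (visible R, G, B) and mean reflectances
#' (Blue, Green, Red, RedEdge, NIR) for the four surface classes of a
#' mulched cotton field at seedling stage. The values encode the spectral
#' structure observed in such fields: plastic mulch film is the brightest
#' class in every band (specular glare), black PE drip tape the darkest;
#' seedlings and bare soil are nearly indistinguishable in the blue and
#' green regions, while seedlings reflect less in red (chlorophyll
#' absorption) and markedly more in red-edge and NIR (canopy scattering).
#' All classes follow R > G > B in digital numbers.
#'
#' No published per-class means exist for this system, so the defaults are
#' plausible magnitudes chosen once; they are fully configurable through
#' `class_spectra` in [scene_config()] and validated by
#' [validate_spectra()].
#'
#' @return A list with two matrices, `dn` (4 x 3, columns R,G,B) and
#'   `reflectance` (4 x 5, columns Blue..NIR); rows ordered as
#'   [feature_classes()].
#' @export
default_spectra <- function() {
  cls <- feature_classes()
  dn <- rbind(
    soil     = c(R = 102, G = 88, B = 55),
    seedling = c(R = 100, G = 95, B = 62),
    film     = c(R = 200, G = 190, B = 175),
    tape     = c(R = 35, G = 30, B = 25)
  )[cls, ]
  reflectance <- rbind(
    soil     = c(Blue = 0.100, Green = 0.150, Red = 0.220,
                 RedEdge = 0.260, NIR = 0.300),
    seedling = c(Blue = 0.090, Green = 0.140, Red = 0.080,
                 RedEdge = 0.350, NIR = 0.500),
    film     = c(Blue = 0.450, Green = 0.500, Red = 0.550,
                 RedEdge = 0.580, NIR = 0.600),
    tape     = c(Blue = 0.030, Green = 0.035, Red = 0.040,
                 RedEdge = 0.045, NIR = 0.050)
  )[cls, ]
  list(dn = dn, reflectance = reflectance)
}

#' Validate the spectral ordering of a class-spectra table
#'
#' Checks that a `class_spectra` table (as returned by [default_spectra()])
#' satisfies the orderings a mulched cotton field exhibits:
#' * film has the strictly highest value of every band (DN and reflectance);
#' * tape has the strictly lowest value of every band;
#' * seedling reflectance is below soil in Red but above soil in RedEdge
#'   and NIR;
#' * seedling and soil reflectances differ by at most `similar_tol` in
#'   Blue and Green.
#'
#' @param spectra list with `dn` (4 x 3) and `reflectance` (4 x 5) matrices,
#'   rows named as [feature_classes()].
#' @param similar_tol maximum |seedling - soil| reflectance difference
#'   allowed in the blue and green bands (default 0.03).
#' @return Invisibly `TRUE`; errors describing the first violated ordering
#'   otherwise.
#' @export
validate_spectra <- function(spectra, similar_tol = 0.03) {
  stopifnot(is.list(spectra), !is.null(spectra$dn),
            !is.null(spectra$reflectance))
  cls <- feature_classes()
  dn <- spectra$dn
  rf <- spectra$reflectance
  if (!all(cls %in% rownames(dn)) || !all(cls %in% rownames(rf))) {
    stop("class_spectra rows must be named ", paste(cls, collapse = ", "),
         call. = FALSE)
  }
  dn <- dn[cls, , drop = FALSE]
  rf <- rf[cls, , drop = FALSE]
  stopifnot(ncol(dn) == 3L, ncol(rf) == 5L)
  others <- setdiff(cls, "film")
  for (tab in list(dn = dn, reflectance = rf)) {
    if (!all(tab["film", ] > apply(tab[others, , drop = FALSE], 2, max))) {
      stop("spectral ordering violated: film must be the brightest class ",
           "in every band", call. = FALSE)
    }
    non_tape <- setdiff(cls, "tape")
    if (!all(tab["tape", ] < apply(tab[non_tape, , drop = FALSE], 2, min))) {
      stop("spectral ordering violated: tape must be the darkest class ",
           "in every band", call. = FALSE)
    }
  }
  if (!(rf["seedling", "Red"] < rf["soil", "Red"])) {
    stop("spectral ordering violated: seedling reflectance must be below ",
         "soil in the red band", call. = FALSE)
  }
  if (!all(rf["seedling", c("RedEdge", "NIR")] >
             rf["soil", c("RedEdge", "NIR")])) {
    stop("spectral ordering violated: seedling reflectance must exceed ",
         "soil in red-edge and NIR", call. = FALSE)
  }
  if (any(abs(rf["seedling", c("Blue", "Green")] -
                rf["soil", c("Blue", "Green")]) > similar_tol)) {
    stop("spectral ordering violated: seedling and soil must be similar ",
         "(within ", similar_tol, ") in blue and green", call. = FALSE)
  }
  invisible(TRUE)
}

#' Configuration for the synthetic field-scene generator
#'
#' Encodes the study-site geometry: plastic mulch films of 144 px width
#' (about 2.31 m at 1.607 cm/px) running as vertical strips, each film
#' carrying six plant rows paired around three 1-px drip tapes (the
#' "66 + 10 cm" row configuration: pair members about 10 cm apart, pairs
#' about 66 cm apart), bare-soil gaps between films, seeds every
#' `plant_spacing_px` (10 cm) along each row, and Bernoulli emergence with
#' probability `emergence_prob` per sown seed. Emerged seedlings are filled
#' disks with radius drawn uniformly from `canopy_radius_px_range`
#' (1-2 px, i.e. 3-6 cm canopy diameters at this ground sampling distance).
#'
#' @param width_px,height_px scene size in pixels.
#' @param gsd_cm ground sampling distance, cm per pixel (default 1.607).
#' @param film_width_px,film_gap_px film-strip width and bare-soil gap
#'   between films, in pixels.
#' @param tape_rows_per_film number of drip tapes per film (default 3).
#' @param rows_per_film number of plant rows per film; must equal
#'   `2 * tape_rows_per_film` (rows are paired around tapes).
#' @param plant_spacing_px in-row seed spacing in pixels (default 6,
#'   about 10 cm).
#' @param emergence_prob per-seed emergence probability in \[0, 1\].
#' @param canopy_radius_px_range length-2 numeric, min/max seedling disk
#'   radius in pixels.
#' @param class_spectra per-class mean spectra; see [default_spectra()].
#' @param dn_noise_sd additive Gaussian noise SD on digital numbers.
#' @param refl_noise_sd additive Gaussian noise SD on reflectance.
#' @param film_noise_mult noise multiplier on film pixels (glare).
#' @param shadows if `TRUE`, darken a 1-px fringe beside each drip tape,
#'   emulating tape shadows (a known noise source for NDVI/MCARI masks).
#' @param grid_px grid-cell side used for the ground-truth emergence table
#'   (default 144, one film width).
#' @param rng_seed integer seed; scenes are bit-identical for equal
#'   configurations.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(width_px = 1008L, height_px = 1008L,
                         gsd_cm = 1.607,
                         film_width_px = 144L, film_gap_px = 30L,
                         tape_rows_per_film = 3L, rows_per_film = 6L,
                         plant_spacing_px = 6L,
                         emergence_prob = 0.7,
                         canopy_radius_px_range = c(1, 2),
                         class_spectra = default_spectra(),
                         dn_noise_sd = 5, refl_noise_sd = 0.01,
                         film_noise_mult = 2,
                         shadows = FALSE,
                         grid_px = 144L,
                         rng_seed = 1L) {
  cfg <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    gsd_cm = gsd_cm,
    film_width_px = as.integer(film_width_px),
    film_gap_px = as.integer(film_gap_px),
    tape_rows_per_film = as.integer(tape_rows_per_film),
    rows_per_film = as.integer(rows_per_film),
    plant_spacing_px = as.integer(plant_spacing_px),
    emergence_prob = emergence_prob,
    canopy_radius_px_range = as.numeric(canopy_radius_px_range),
    class_spectra = class_spectra,
    dn_noise_sd = dn_noise_sd, refl_noise_sd = refl_noise_sd,
    film_noise_mult = film_noise_mult,
    shadows = isTRUE(shadows),
    grid_px = as.integer(grid_px),
    rng_seed = as.integer(rng_seed)
  )
  geom <- c("width_px", "height_px", "gsd_cm", "film_width_px",
            "plant_spacing_px", "grid_px", "tape_rows_per_film",
            "rows_per_film")
  for (f in geom) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("scene_config: `", f, "` must be a positive scalar", call. = FALSE)
    }
  }
  if (cfg$film_gap_px < 0) {
    stop("scene_config: `film_gap_px` must be >= 0", call. = FALSE)
  }
  if (cfg$emergence_prob < 0 || cfg$emergence_prob > 1) {
    stop("scene_config: `emergence_prob` must lie in [0, 1]", call. = FALSE)
  }
  rr <- cfg$canopy_radius_px_range
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2]) {
    stop("scene_config: `canopy_radius_px_range` must be (min, max) > 0",
         call. = FALSE)
  }
  if (cfg$rows_per_film != 2L * cfg$tape_rows_per_film) {
    stop("scene_config: rows_per_film must equal 2 * tape_rows_per_film ",
         "(plant rows are paired around drip tapes)", call. = FALSE)
  }
  validate_spectra(cfg$class_spectra)
  structure(cfg, class = "scene_config")
}

# Column offsets (1-based, within one film) of drip tapes and plant rows.
film_layout <- function(cfg) {
  k <- cfg$tape_rows_per_film
  tape_off <- round(cfg$film_width_px * (2 * seq_len(k) - 1) / (2 * k))
  pair_half <- max(1L, round(10 / cfg$gsd_cm / 2))  # half of 10 cm pair gap
  row_off <- sort(c(tape_off - pair_half, tape_off + pair_half))
  row_off <- row_off[row_off >= 1 & row_off <= cfg$film_width_px]
  list(tape = as.integer(tape_off), rows = as.integer(row_off))
}

#' Generate a ground-truthed synthetic field scene
#'
#' Builds a per-pixel class map (soil, seedling, film, tape) from the
#' configured film/tape/row geometry, draws per-seed emergence as Bernoulli
#' trials, paints each emerged seed as a filled disk of the seedling class,
#' and renders every band as class mean + additive Gaussian noise clipped
#' to the valid range (\[0, 255\] DN, \[0, 1\] reflectance). One RNG stream
#' seeded from `rng_seed` is consumed in fixed order: emergence flags,
#' canopy radii, visible noise (R, G, B), reflectance noise (Blue, Green,
#' Red, RedEdge, NIR); two calls with an identical configuration produce
#' bit-identical scenes.
#'
#' Configurations whose canopy disks would overlap across neighbouring
#' seeds by construction (2 x max radius >= the minimum seed spacing) are
#' rejected.
#'
#' @param config a [scene_config()].
#' @return A list with elements `scene` (a [multiband_scene]) and `truth`
#'   (class `ground_truth`: `label_map` — integer matrix of class codes
#'   0 = soil, 1 = seedling, 2 = film, 3 = tape; `seeds` — data.frame of
#'   1-based `col`, `row`, `emerged`; `per_grid` — per-cell truth table
#'   with `grid_row`, `grid_col`, `ns` seeds sown, `ne` emerged, `rate_pct`;
#'   `grid_px`; `classes`).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  h <- cfg$height_px
  w <- cfg$width_px
  layout <- film_layout(cfg)

  # minimum center-to-center seed distance: in-row spacing vs adjacent rows
  row_gaps <- diff(layout$rows)
  min_sep <- min(c(cfg$plant_spacing_px, row_gaps))
  if (2 * cfg$canopy_radius_px_range[2] >= min_sep) {
    stop("canopy disks would overlap by construction: 2*max radius (",
         2 * cfg$canopy_radius_px_range[2], ") >= minimum seed spacing (",
         min_sep, ")", call. = FALSE)
  }

  codes <- c(soil = 0L, seedling = 1L, film = 2L, tape = 3L)
  label <- matrix(codes[["soil"]], h, w)

  period <- cfg$film_width_px + cfg$film_gap_px
  film_starts <- seq(1L, w, by = period)
  tape_cols <- integer(0)
  row_cols <- integer(0)
  for (s in film_starts) {
    fcols <- s:min(s + cfg$film_width_px - 1L, w)
    label[, fcols] <- codes[["film"]]
    tc <- s + layout$tape - 1L
    tape_cols <- c(tape_cols, tc[tc <= w])
    rc <- s + layout$rows - 1L
    row_cols <- c(row_cols, rc[rc <= w])
  }
  label[, tape_cols] <- codes[["tape"]]

  # sown seeds: every plant row column, every plant_spacing_px rows
  seed_rows <- seq(ceiling(cfg$plant_spacing_px / 2), h,
                   by = cfg$plant_spacing_px)
  seeds <- expand.grid(row = seed_rows, col = row_cols,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- seeds[order(seeds$col, seeds$row), c("col", "row")]
  rownames(seeds) <- NULL
  n_seeds <- nrow(seeds)

  spectra <- cfg$class_spectra
  dn_mu <- spectra$dn[feature_classes(), , drop = FALSE]
  rf_mu <- spectra$reflectance[feature_classes(), , drop = FALSE]

  out <- with_seed(cfg$rng_seed, {
    emerged <- rbinom(n_seeds, 1L, cfg$emergence_prob) == 1L
    radii <- runif(n_seeds, cfg$canopy_radius_px_range[1],
                   cfg$canopy_radius_px_range[2])

    # paint emerged seeds as filled disks of the seedling class
    which_em <- which(emerged)
    for (i in which_em) {
      r <- radii[i]
      ri <- ceiling(r)
      dr <- (-ri):ri
      disk <- expand.grid(dy = dr, dx = dr)
      disk <- disk[disk$dy^2 + disk$dx^2 <= r^2, ]
      yy <- seeds$row[i] + disk$dy
      xx <- seeds$col[i] + disk$dx
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      label[cbind(yy[ok], xx[ok])] <- codes[["seedling"]]
    }

    cls_idx <- label + 1L  # class code 0-3 -> row 1-4 of spectra tables
    sd_scale <- matrix(1, h, w)
    sd_scale[label == codes[["film"]]] <- cfg$film_noise_mult

    visible <- array(0, c(h, w, 3L))
    for (b in seq_len(3L)) {
      mu <- matrix(dn_mu[cls_idx, b], h, w)
      visible[, , b] <- pmin(pmax(
        mu + rnorm(h * w, sd = cfg$dn_noise_sd) * sd_scale, 0), 255)
    }
    reflectance <- array(0, c(h, w, 5L))
    for (b in seq_len(5L)) {
      mu <- matrix(rf_mu[cls_idx, b], h, w)
      reflectance[, , b] <- pmin(pmax(
        mu + rnorm(h * w, sd = cfg$refl_noise_sd) * sd_scale, 0), 1)
    }
    list(label = label, emerged = emerged,
         visible = visible, reflectance = reflectance)
  })
  label <- out$label

  if (cfg$shadows) {
    # darken the soil-free fringe one pixel to the right of each tape
    fringe <- tape_cols + 1L
    fringe <- fringe[fringe <= w]
    out$visible[, fringe, ] <- out$visible[, fringe, ] * 0.6
    out$reflectance[, fringe, ] <- out$reflectance[, fringe, ] * 0.6
  }

  seeds$emerged <- out$emerged

  # per-grid truth over full grid cells, seeds assigned by sown position
  g <- cfg$grid_px
  n_gr <- h %/% g
  n_gc <- w %/% g
  per_grid <- data.frame(grid_row = integer(0), grid_col = integer(0),
                         ns = integer(0), ne = integer(0),
                         rate_pct = numeric(0))
  if (n_gr >= 1L && n_gc >= 1L) {
    inside <- seeds$row <= n_gr * g & seeds$col <= n_gc * g
    gr <- (seeds$row[inside] - 1L) %/% g + 1L
    gc <- (seeds$col[inside] - 1L) %/% g + 1L
    key <- factor(paste(gr, gc),
                  levels = paste(rep(seq_len(n_gr), each = n_gc),
                                 rep(seq_len(n_gc), times = n_gr)))
    ns <- as.integer(table(key))
    ne <- as.integer(tapply(seeds$emerged[inside], key, sum, default = 0L))
    per_grid <- data.frame(
      grid_row = rep(seq_len(n_gr), each = n_gc),
      grid_col = rep(seq_len(n_gc), times = n_gr),
      ns = ns, ne = ne
    )
    per_grid <- per_grid[per_grid$ns > 0L, ]
    per_grid$rate_pct <- per_grid$ne / per_grid$ns * 100
    rownames(per_grid) <- NULL
  }

  scene <- multiband_scene(visible = out$visible,
                           reflectance = out$reflectance,
                           gsd_cm = cfg$gsd_cm)
  truth <- structure(
    list(label_map = label, seeds = seeds, per_grid = per_grid,
         grid_px = g, classes = feature_classes(), config = cfg),
    class = "ground_truth"
  )
  list(scene = scene, truth = truth)
}

#' Sample labeled pixels from a synthetic ground truth
#'
#' Draws, without replacement, a fixed number of pixels per surface class
#' from a scene's label map — the synthetic analogue of manually labeling
#' regions of interest by visual interpretation. Default counts (302
#' seedling, 224 soil, 237 film, 200 tape) match the pixel-sample sizes of
#' the study this package reproduces.
#'
#' @param truth a `ground_truth` from [generate_scene()].
#' @param counts named integer vector of pixels per class.
#' @param seed RNG seed for the draw.
#' @return A label table: data.frame with 1-based `col`, `row`, `class`.
#' @export
sample_label_pixels <- function(truth,
                                counts = c(seedling = 302L, soil = 224L,
                                           film = 237L, tape = 200L),
                                seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  codes <- c(soil = 0L, seedling = 1L, film = 2L, tape = 3L)
  stopifnot(all(names(counts) %in% names(codes)))
  lab <- truth$label_map
  with_seed(seed, {
    rows <- lapply(names(counts), function(cl) {
      idx <- which(lab == codes[[cl]])
      if (length(idx) < counts[[cl]]) {
        stop("class `", cl, "` has only ", length(idx),
             " pixels; cannot sample ", counts[[cl]], call. = FALSE)
      }
      pick <- sample(idx, counts[[cl]])
      data.frame(col = (pick - 1L) %/% nrow(lab) + 1L,
                 row = (pick - 1L) %% nrow(lab) + 1L,
                 class = cl, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
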