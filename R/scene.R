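#' Multiband scene container
#'
#' Bundles a co-registered 3-channel visible image (8-bit digital numbers,
#' stored as doubles in \[0, 255\]) and a 5-band reflectance stack (Blue,
#' Green, Red, RedEdge, NIR, each in \[0, 1\]) on a common pixel grid.
#' Either modality may be absent (`NULL`) when only part of the pipeline is
#' needed; index computation errors explicitly if a required band is missing.
#'
#' @param visible `height x width x 3` numeric array of digital numbers
#'   (channel order R, G, B), or `NULL`.
#' @param reflectance `height x width x 5` numeric array of reflectances
#'   (band order Blue, Green, Red, RedEdge, NIR), or `NULL`.
#' @param gsd_cm ground sampling distance, cm per pixel.
#'
#' @return An object of class `multiband_scene`: a list with elements
#'   `visible`, `reflectance`, `gsd_cm`, and `dim` (height, width).
#' @export
multiband_scene <- function(visible = NULL, reflectance = NULL,
                            gsd_cm = 1.607) {
  if (is.null(visible) && is.null(reflectance)) {
    stop("a scene needs at least one of `visible`, `reflectance`",
         call. = FALSE)
  }
  dims <- NULL
  if (!is.null(visible)) {
    stopifnot(is.array(visible), length(dim(visible)) == 3L,
              dim(visible)[3] == 3L)
    if (anyNA(visible) || any(!is.finite(visible))) {
      stop("visible channels contain non-finite values", call. = FALSE)
    }
    if (min(visible) < 0 || max(visible) > 255) {
      stop("visible digital numbers must lie in [0, 255]", call. = FALSE)
    }
    dimnames(visible) <- list(NULL, NULL, c("R", "G", "B"))
    dims <- dim(visible)[1:2]
  }
  if (!is.null(reflectance)) {
    stopifnot(is.array(reflectance), length(dim(reflectance)) == 3L,
              dim(reflectance)[3] == 5L)
    if (anyNA(reflectance) || any(!is.finite(reflectance))) {
      stop("reflectance bands contain non-finite values", call. = FALSE)
    }
    dimnames(reflectance) <- list(NULL, NULL, band_names())
    if (!is.null(dims) && !all(dim(reflectance)[1:2] == dims)) {
      stop("visible and reflectance grids have different dimensions",
           call. = FALSE)
    }
    dims <- dim(reflectance)[1:2]
  }
  stopifnot(is.numeric(gsd_cm), gsd_cm > 0)
  structure(
    list(visible = visible, reflectance = reflectance,
         gsd_cm = gsd_cm, dim = as.integer(dims)),
    class = "multiband_scene"
  )
}

#' Multispectral band names
#'
#' @return Character vector of the five reflectance band names in stack
#'   order: Blue, Green, Red, RedEdge, NIR.
#' @export
band_names <- function() c("Blue", "Green", "Red", "RedEdge", "NIR")

#' @export
print.multiband_scene <- function(x, ...) {
  cat("<multiband_scene> ", x$dim[1], "x", x$dim[2], " px, gsd ",
      x$gsd_cm, " cm/px\n", sep = "")
  cat("  visible:    ", if (is.null(x$visible)) "absent" else "R,G,B (DN)",
      "\n", sep = "")
  cat("  reflectance:",
      if (is.null(x$reflectance)) " absent" else
        paste0(" ", paste(band_names(), collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' Write a scene (and optional ground truth) to disk
#'
#' The visible image is written as an 8-bit RGB TIFF, the reflectance stack
#' as a 5-page 32-bit float TIFF (one band per page, stack order
#' Blue/Green/Red/RedEdge/NIR), and the ground-truth label map — if given —
#' as a single-page 8-bit TIFF of class codes 0-3 (soil, seedling, film,
#' tape). Reflectance values are stored at float32 precision.
#'
#' @param scene a [multiband_scene].
#' @param dir output directory (created if absent).
#' @param truth optional ground truth from [generate_scene()]; writes
#'   `labels.tif`, `seeds.csv` and `grid_truth.csv`.
#' @return Invisibly, the directory path.
#' @export
write_scene <- function(scene, dir, truth = NULL) {
  stopifnot(inherits(scene, "multiband_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(scene$visible)) {
    tiff::writeTIFF(scene$visible / 255, file.path(dir, "visible.tif"),
                    bits.per.sample = 8L)
  }
  if (!is.null(scene$reflectance)) {
    pages <- lapply(seq_len(5L), function(b) scene$reflectance[, , b])
    tiff::writeTIFF(pages, file.path(dir, "reflectance.tif"),
                    bits.per.sample = 32L)
  }
  writeLines(as.character(scene$gsd_cm), file.path(dir, "gsd_cm.txt"))
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "ground_truth"))
    tiff::writeTIFF(truth$label_map / 255, file.path(dir, "labels.tif"),
                    bits.per.sample = 8L)
    seeds <- truth$seeds
    seeds$col <- seeds$col - 1L  # CSV convention: 0-based coordinates
    seeds$row <- seeds$row - 1L
    write.csv(seeds, file.path(dir, "seeds.csv"), row.names = FALSE)
    write.csv(truth$per_grid, file.path(dir, "grid_truth.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir directory containing `visible.tif` / `reflectance.tif`.
#' @return A [multiband_scene].
#' @export
read_scene <- function(dir) {
  vis_path <- file.path(dir, "visible.tif")
  ref_path <- file.path(dir, "reflectance.tif")
  gsd_path <- file.path(dir, "gsd_cm.txt")
  visible <- NULL
  reflectance <- NULL
  if (file.exists(vis_path)) {
    visible <- tiff::readTIFF(vis_path) * 255
  }
  if (file.exists(ref_path)) {
    pages <- tiff::readTIFF(ref_path, all = TRUE)
    reflectance <- array(0, c(dim(pages[[1]]), 5L))
    for (b in seq_len(5L)) reflectance[, , b] <- pages[[b]]
  }
  gsd <- if (file.exists(gsd_path)) as.numeric(readLines(gsd_path)) else 1.607
  multiband_scene(visible = visible, reflectance = reflectance, gsd_cm = gsd)
}

#' Read / write a pixel label table
#'
#' Label CSVs use columns `col,row,class` with 0-based pixel coordinates
#' (class as string, one of soil/seedling/film/tape); in-memory tables are
#' 1-based to match R matrix indexing. An optional `split` column
#' (calibration/validation) survives the round trip.
#'
#' @param path CSV path.
#' @return `read_labels()`: a data.frame with 1-based `col`, `row`,
#'   `class` (and `split` if present).
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("col", "row", "class") %in% names(df)))
  df$col <- df$col + 1L
  df$row <- df$row + 1L
  df
}

#' @rdname read_labels
#' @param labels label table with 1-based coordinates.
#' @export
write_labels <- function(labels, path) {
  labels$col <- labels$col - 1L
  labels$row <- labels$row - 1L
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
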