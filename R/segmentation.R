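#' Otsu threshold of a single layer
#'
#' Classic single-level Otsu thresholding: valid pixel values are min-max
#' scaled into 256 histogram bins and the inter-bin split maximizing the
#' between-class variance is selected; among equal-variance splits the
#' lowest bin wins. The returned threshold is on the original value scale
#' (the upper edge of the last background bin), so that `value > threshold`
#' reproduces the bin-level classification. Because binning is min-max
#' based, the resulting mask is invariant under positive affine transforms
#' of the layer.
#'
#' @param layer a `vi_layer` from [compute_index()], or a numeric matrix /
#'   vector.
#' @param invalid optional logical mask of pixels to exclude (ignored when
#'   `layer` is a `vi_layer`, which carries its own).
#' @param nbins number of histogram bins (default 256).
#' @return The threshold, a single numeric on the original value scale.
#' @export
otsu_threshold <- function(layer, invalid = NULL, nbins = 256L) {
  if (inherits(layer, "vi_layer")) {
    invalid <- layer$invalid
    layer <- layer$values
  }
  v <- as.numeric(layer)
  if (!is.null(invalid)) v <- v[!as.logical(invalid)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("all pixels invalid", call. = FALSE)
  mn <- min(v)
  mx <- max(v)
  if (mx == mn) stop("degenerate layer: all valid pixels equal", call. = FALSE)
  width <- (mx - mn) / nbins
  bin <- pmin(floor((v - mn) / (mx - mn) * nbins), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  p <- counts / length(v)
  omega <- cumsum(p)                      # class-0 weight up to bin k
  mu <- cumsum(p * (seq_len(nbins) - 1))  # class-0 first moment
  mu_t <- mu[nbins]
  k <- seq_len(nbins - 1L)                # split after bin k-1 (0-based)
  num <- (mu_t * omega[k] - mu[k])^2
  den <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  k_star <- which.max(sigma_b)            # ties -> lowest bin
  mn + k_star * width
}

#' Binarize a layer at a threshold
#'
#' Pixels strictly greater than the threshold become 1, all others 0;
#' invalid pixels are always 0. The mask's seedling polarity is
#' undetermined until [orient_mask()] is applied.
#'
#' @param layer a `vi_layer` or numeric matrix.
#' @param threshold finite numeric threshold (typically from
#'   [otsu_threshold()]).
#' @param invalid optional logical matrix (taken from a `vi_layer`
#'   automatically).
#' @param source layer name recorded in the mask (from a `vi_layer`
#'   automatically).
#' @return A `binary_mask`: list with `values` (integer 0/1 matrix),
#'   `threshold`, `source`, `seedling_is_one` (`NA` until oriented),
#'   `invalid`.
#' @export
binarize <- function(layer, threshold, invalid = NULL, source = NA_character_) {
  if (inherits(layer, "vi_layer")) {
    invalid <- layer$invalid
    source <- layer$name
    layer <- layer$values
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  stopifnot(is.matrix(layer))
  if (is.null(invalid)) invalid <- !is.finite(layer)
  values <- matrix(0L, nrow(layer), ncol(layer))
  values[!invalid & !is.na(layer) & layer > threshold] <- 1L
  structure(list(values = values, threshold = threshold, source = source,
                 seedling_is_one = NA, invalid = invalid),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", nrow(x$values), "x", ncol(x$values), " px, source ",
      if (is.na(x$source)) "?" else x$source,
      ", threshold ", format(x$threshold), ", foreground ",
      sum(x$values), " px, oriented: ",
      if (isTRUE(x$seedling_is_one)) "yes" else "no", "\n", sep = "")
  invisible(x)
}

#' Orient a mask so seedlings are foreground
#'
#' Otsu binarization assigns classes arbitrarily; this flips the mask if
#' the majority of seedling-labeled pixels fall on the 0 side, so that
#' 1 always means seedling. An exact 50/50 tie keeps the current
#' orientation with a warning. Invalid source pixels remain 0 after
#' inversion. Orienting an already-oriented mask is a no-op.
#'
#' @param mask a `binary_mask`.
#' @param labels label table with at least one `seedling` row inside the
#'   mask extent.
#' @return The oriented `binary_mask` (`seedling_is_one = TRUE`).
#' @export
orient_mask <- function(mask, labels) {
  stopifnot(inherits(mask, "binary_mask"))
  check_labels(labels, dim(mask$values))
  seed <- labels[labels$class == "seedling", , drop = FALSE]
  if (nrow(seed) == 0L) {
    stop("no seedling-labeled pixels to orient against", call. = FALSE)
  }
  vals <- mask$values[cbind(seed$row, seed$col)]
  n0 <- sum(vals == 0L)
  n1 <- length(vals) - n0
  if (n0 == n1) {
    warning("seedling labels split exactly 50/50 between 0 and 1; ",
            "keeping current orientation")
  } else if (n0 > n1) {
    mask$values <- 1L - mask$values
    mask$values[mask$invalid] <- 0L
  }
  mask$seedling_is_one <- TRUE
  mask
}

#' Per-class foreground/background proportions of a mask
#'
#' For each surface class, the fraction of its labeled pixels assigned 0
#' (background) and 1 (foreground) by the mask — the diagnostic used to
#' judge how well one index's Otsu split isolates seedlings.
#'
#' @param mask a `binary_mask`.
#' @param labels label table.
#' @return A data.frame with columns `index`, `class`, `n`, `frac0`,
#'   `frac1` (`frac0 + frac1 = 1` per row).
#' @export
class_proportions <- function(mask, labels) {
  stopifnot(inherits(mask, "binary_mask"))
  check_labels(labels, dim(mask$values))
  vals <- mask$values[cbind(labels$row, labels$col)]
  cls <- factor(as.character(labels$class), levels = feature_classes())
  n <- as.integer(table(cls))
  n1 <- as.integer(tapply(vals, cls, sum, default = 0L))
  keep <- n > 0L
  data.frame(
    index = if (is.na(mask$source)) NA_character_ else mask$source,
    class = feature_classes()[keep],
    n = n[keep],
    frac0 = (n[keep] - n1[keep]) / n[keep],
    frac1 = n1[keep] / n[keep],
    stringsAsFactors = FALSE
  )
}
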