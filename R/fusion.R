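#' Seedling/background separation score of an oriented mask
#'
#' Balanced accuracy over the labeled pixels of an oriented mask: the mean
#' of seedling recall (fraction of seedling labels in the foreground) and
#' background rejection (fraction of non-seedling labels in the
#' background, pooled over soil, film and tape weighted by their label
#' counts). 1 is a perfect split, 0.5 is chance. This formalizes the
#' "high proportion in one of 0 or 1, very low in the other" visual
#' criterion used to pick key indices.
#'
#' @param props a proportion table from [class_proportions()] computed on
#'   an *oriented* mask (one index).
#' @return A single numeric score in \[0, 1\].
#' @export
score_index <- function(props) {
  stopifnot(is.data.frame(props),
            all(c("class", "n", "frac0", "frac1") %in% names(props)))
  s <- props[props$class == "seedling", , drop = FALSE]
  o <- props[props$class != "seedling", , drop = FALSE]
  if (nrow(s) != 1L || nrow(o) == 0L) {
    stop("proportion table must contain a seedling row and at least one ",
         "other class", call. = FALSE)
  }
  recall <- s$frac1
  rejection <- sum(o$frac0 * o$n) / sum(o$n)
  (recall + rejection) / 2
}

#' Select key vegetation indices
#'
#' Ranks indices by separation score and keeps the best `top_k` (default 6),
#' or all indices at/above `min_score` when given. Ties keep registry
#' order (the order of `scores`). The named preset `"paper"` returns the
#' canonical key set NDVI, RVI, SAVI, EVI2, OSAVI, MCARI regardless of
#' scores.
#'
#' @param scores named numeric vector of separation scores (one per index,
#'   in registry order), e.g. from [screen_indices()].
#' @param top_k number of indices to keep.
#' @param min_score optional score threshold used instead of `top_k`; if no
#'   index qualifies the single best index is kept with a warning.
#' @param preset `NULL` or `"paper"`.
#' @return A `key_vi_selection`: list with `ranked` (data.frame of `index`,
#'   `score`) and `chosen` (character vector).
#' @export
select_key_vis <- function(scores, top_k = 6L, min_score = NULL,
                           preset = NULL) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("no scored indices", call. = FALSE)
  ord <- order(-scores)  # stable: ties keep input (registry) order
  ranked <- data.frame(index = names(scores)[ord], score = scores[ord],
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "paper")
    chosen <- key_vi_preset()
  } else if (!is.null(min_score)) {
    chosen <- ranked$index[ranked$score >= min_score]
    if (length(chosen) == 0L) {
      warning("no index reaches min_score = ", min_score,
              "; keeping the single best index")
      chosen <- ranked$index[1L]
    }
  } else {
    if (top_k > nrow(ranked)) {
      warning("top_k = ", top_k, " exceeds the ", nrow(ranked),
              " available indices; clamping")
      top_k <- nrow(ranked)
    }
    chosen <- ranked$index[seq_len(top_k)]
  }
  structure(list(ranked = ranked, chosen = chosen),
            class = "key_vi_selection")
}

#' @export
print.key_vi_selection <- function(x, ...) {
  cat("<key_vi_selection> ", length(x$chosen), " of ", nrow(x$ranked),
      " indices: ", paste(x$chosen, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Otsu-intersection (OI) fusion of oriented masks
#'
#' Pixelwise logical AND of several oriented seedling masks. Different
#' indices respond to different non-seedling structures (film glare, soil
#' texture, tape shadow), so their intersection retains only pixels every
#' index agrees are seedling — the fused foreground is a subset of every
#' input, monotonically shrinking as masks are added, and independent of
#' mask order.
#'
#' @param masks list of oriented `binary_mask` objects on one pixel grid.
#' @return A fused `binary_mask` with `seedling_is_one = TRUE` and the
#'   source index names recorded in `source`.
#' @export
oi_fuse <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  for (m in masks) {
    if (!inherits(m, "binary_mask")) {
      stop("all inputs must be binary_mask objects", call. = FALSE)
    }
    if (!isTRUE(m$seedling_is_one)) {
      stop("mask `", m$source, "` is not oriented; run orient_mask() first",
           call. = FALSE)
    }
  }
  dims <- lapply(masks, function(m) dim(m$values))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L) {
    stop("mask dimensions differ", call. = FALSE)
  }
  values <- masks[[1L]]$values
  invalid <- masks[[1L]]$invalid
  if (length(masks) > 1L) {
    for (m in masks[-1L]) {
      values <- values * m$values
      invalid <- invalid | m$invalid
    }
  }
  structure(list(values = values, threshold = NA_real_,
                 source = paste(vapply(masks, function(m)
                   as.character(m$source), character(1)), collapse = "+"),
                 seedling_is_one = TRUE, invalid = invalid),
            class = "binary_mask")
}

#' Otsu-screen every layer of an index stack
#'
#' For each layer: Otsu-threshold it, binarize, orient against the labeled
#' seedling pixels, tabulate per-class foreground/background proportions,
#' and score the seedling/background separation. Layers that cannot be
#' thresholded (degenerate or all-invalid) are skipped with a message.
#'
#' @param stack an `index_stack`.
#' @param labels label table (all labeled pixels; the Otsu screen does not
#'   use calibration/validation splits).
#' @return A list: `masks` (named list of oriented `binary_mask`),
#'   `props` (row-bound proportion tables), `scores` (named numeric).
#' @export
screen_indices <- function(stack, labels) {
  stopifnot(inherits(stack, "index_stack"))
  check_labels(labels, stack$dim)
  masks <- list()
  props <- list()
  scores <- numeric(0)
  for (nm in names(stack$layers)) {
    t <- tryCatch(
      otsu_threshold(stack$layers[[nm]], invalid = stack$invalid[[nm]]),
      error = function(e) NA_real_)
    if (is.na(t)) {
      message("screen_indices: skipping `", nm, "` (cannot threshold)")
      next
    }
    m <- binarize(stack$layers[[nm]], t, invalid = stack$invalid[[nm]],
                  source = nm)
    m <- orient_mask(m, labels)
    p <- class_proportions(m, labels)
    masks[[nm]] <- m
    props[[nm]] <- p
    scores[nm] <- score_index(p)
  }
  list(masks = masks, props = do.call(rbind, props), scores = scores)
}
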