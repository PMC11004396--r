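# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the global stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Shift a matrix by (dr, dc), padding exposed borders with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# The 8 (or 4) neighbour offsets for a given connectivity.
neighbour_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  four <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 4L) {
    return(four)
  }
  c(four, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
}

# Validate a label table (data.frame with col,row,class) against an image
# extent; errors list the offending rows. Coordinates are 1-based.
check_labels <- function(labels, dim_hw) {
  stopifnot(is.data.frame(labels))
  need <- c("col", "row", "class")
  missing_cols <- setdiff(need, names(labels))
  if (length(missing_cols)) {
    stop("label table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(labels$row < 1 | labels$row > dim_hw[1] |
                 labels$col < 1 | labels$col > dim_hw[2])
  if (length(bad)) {
    stop("label coordinates out of image bounds at row(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  unknown <- setdiff(unique(as.character(labels$class)), feature_classes())
  if (length(unknown)) {
    stop("unknown label class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Surface feature classes
#'
#' The four surface classes of a mulched cotton field at seedling stage, in
#' the code order used by label rasters (codes 0-3).
#'
#' @return Character vector `c("soil", "seedling", "film", "tape")`.
#' @export
feature_classes <- function() c("soil", "seedling", "film", "tape")
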