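# Vegetation-index bank: 20 visible layers (R, G, B digital numbers plus 17
# visible VIs) and 19 multispectral layers (5 reflectance bands plus 14 VIs).
#
# Symbol conventions follow the field's usage: upper-case R, G, B are raw
# digital numbers of the visible camera; lower-case r, g, b are chromatic
# coordinates r = R/(R+G+B) etc.; rho-band indices (NDVI, SAVI, ...) operate
# on reflectance. Indices written with lower-case symbols in the literature
# (NGRDI, GLI, VARI, ExR/ExG/ExB/ExGR) use chromatic coordinates; CIVE, VEG,
# MExG, IKAW, TGI use raw digital numbers.

# Each registry entry maps a layer name to a pixelwise formula over the
# channel list produced by scene_channels().
vi_registry <- function() {
  vis <- list(
    R = function(ch) ch$R,
    G = function(ch) ch$G,
    B = function(ch) ch$B,
    r = function(ch) ch$r,
    g = function(ch) ch$g,
    b = function(ch) ch$b,
    NGRDI = function(ch) (ch$g - ch$r) / (ch$g + ch$r),
    GLI = function(ch) (2 * ch$g - ch$r - ch$b) / (2 * ch$g + ch$r + ch$b),
    VARI = function(ch) (ch$g - ch$r) / (ch$g + ch$r - ch$b),
    ExR = function(ch) 1.4 * ch$r - ch$g,
    ExG = function(ch) 2 * ch$g - ch$r - ch$b,
    ExB = function(ch) 1.4 * ch$b - ch$g,
    ExGR = function(ch) (2 * ch$g - ch$r - ch$b) - (1.4 * ch$r - ch$g),
    CIVE = function(ch) 0.411 * ch$R - 0.811 * ch$G + 0.385 * ch$B + 18.78745,
    VEG = function(ch) ch$G / (ch$R^0.667 * ch$B^(1 - 0.667)),
    MExG = function(ch) 1.262 * ch$G - 0.884 * ch$R - 0.311 * ch$B,
    IKAW = function(ch) (ch$R - ch$B) / (ch$R + ch$B),
    TGI = function(ch) 0.5 * (0.19 * (ch$R - ch$G) - 0.12 * (ch$R - ch$B)),
    COM1 = function(ch) {
      exg <- 2 * ch$g - ch$r - ch$b
      exr <- 1.4 * ch$r - ch$g
      cive <- 0.411 * ch$R - 0.811 * ch$G + 0.385 * ch$B + 18.78745
      veg <- ch$G / (ch$R^0.667 * ch$B^(1 - 0.667))
      exg + cive + (exg - exr) + veg
    },
    COM2 = function(ch) {
      exg <- 2 * ch$g - ch$r - ch$b
      cive <- 0.411 * ch$R - 0.811 * ch$G + 0.385 * ch$B + 18.78745
      veg <- ch$G / (ch$R^0.667 * ch$B^(1 - 0.667))
      0.36 * exg + 0.47 * cive + 0.17 * veg
    }
  )
  ms <- list(
    Blue = function(ch) ch$Blue,
    Green = function(ch) ch$Green,
    Red = function(ch) ch$Red,
    RedEdge = function(ch) ch$RedEdge,
    NIR = function(ch) ch$NIR,
    NDVI = function(ch) (ch$NIR - ch$Red) / (ch$NIR + ch$Red),
    GNDVI = function(ch) (ch$NIR - ch$Green) / (ch$NIR + ch$Green),
    RVI = function(ch) ch$NIR / ch$Red,
    DVI = function(ch) ch$NIR - ch$Red,
    RDVI = function(ch) (ch$NIR - ch$Red) / sqrt(ch$NIR + ch$Red),
    SAVI = function(ch) 1.5 * (ch$NIR - ch$Red) / (ch$NIR + ch$Red + 0.5),
    CI = function(ch) ch$NIR / ch$Green - 1,
    NLI = function(ch) (ch$NIR^2 - ch$Red) / (ch$NIR^2 + ch$Red),
    MNLI = function(ch) 1.5 * (ch$NIR^2 - ch$Red) / (ch$NIR^2 + ch$Red + 0.5),
    TVI = function(ch) 60 * (ch$NIR - ch$Green) - 100 * (ch$Red - ch$Green),
    EVI2 = function(ch) 2.5 * (ch$NIR - ch$Red) / (ch$NIR + 2.4 * ch$Red + 1),
    MSAVI2 = function(ch) {
      (2 * ch$NIR + 1 - sqrt((2 * ch$NIR + 1)^2 - 8 * (ch$NIR - ch$Red))) / 2
    },
    OSAVI = function(ch) (ch$NIR - ch$Red) / (ch$NIR + ch$Red + 0.16),
    MCARI = function(ch) {
      # standard MCARI2 form
      1.5 * (2.5 * (ch$NIR - ch$Red) - 1.3 * (ch$NIR - ch$Green)) /
        sqrt((2 * ch$NIR + 1)^2 - (6 * ch$NIR - 5 * sqrt(ch$Red)) - 0.5)
    }
  )
  list(visible = vis, multispectral = ms)
}

#' Registered layer names of the vegetation-index bank
#'
#' @param group `"visible"` (20 layers: R, G, B plus 17 visible VIs),
#'   `"multispectral"` (19 layers: 5 bands plus 14 VIs) or `"all"` (39).
#' @return Character vector of layer names in registry order.
#' @export
index_names <- function(group = c("all", "visible", "multispectral")) {
  group <- match.arg(group)
  reg <- vi_registry()
  switch(group,
         visible = names(reg$visible),
         multispectral = names(reg$multispectral),
         all = c(names(reg$visible), names(reg$multispectral)))
}

#' The paper-preset key vegetation indices
#'
#' The six multispectral indices with the best seedling/background
#' separation under Otsu thresholding in the original study.
#'
#' @return `c("NDVI", "RVI", "SAVI", "EVI2", "OSAVI", "MCARI")`.
#' @export
key_vi_preset <- function() c("NDVI", "RVI", "SAVI", "EVI2", "OSAVI", "MCARI")

# Build the channel list for formula evaluation. DN channels are converted
# to double; chromatic coordinates are NaN-flagged where R+G+B == 0.
scene_channels <- function(scene, need = c("visible", "multispectral")) {
  ch <- list()
  if ("visible" %in% need) {
    if (is.null(scene$visible)) {
      stop("scene lacks the visible (R, G, B) channels", call. = FALSE)
    }
    band2d <- function(arr, b) {
      m <- arr[, , b, drop = FALSE] + 0.0
      dim(m) <- dim(arr)[1:2]
      m
    }
    ch$R <- band2d(scene$visible, "R")
    ch$G <- band2d(scene$visible, "G")
    ch$B <- band2d(scene$visible, "B")
    tot <- ch$R + ch$G + ch$B
    ch$r <- ch$R / tot
    ch$g <- ch$G / tot
    ch$b <- ch$B / tot
  }
  if ("multispectral" %in% need) {
    if (is.null(scene$reflectance)) {
      stop("scene lacks the reflectance bands (",
           paste(band_names(), collapse = ", "), ")", call. = FALSE)
    }
    for (b in band_names()) {
      m <- scene$reflectance[, , b, drop = FALSE] + 0.0
      dim(m) <- dim(scene$reflectance)[1:2]
      ch[[b]] <- m
    }
  }
  ch
}

index_group <- function(name) {
  reg <- vi_registry()
  if (name %in% names(reg$visible)) return("visible")
  if (name %in% names(reg$multispectral)) return("multispectral")
  stop("unknown index name: `", name, "` (see index_names())", call. = FALSE)
}

#' Compute one layer of the vegetation-index bank
#'
#' Applies the registered formula pixelwise in double precision. Pixels
#' where the formula is undefined (zero denominator, negative radicand,
#' non-finite operand) are set to `NA` and flagged in the `invalid` mask —
#' they are excluded from Otsu histograms and forced to background after
#' binarization, never silently zeroed.
#'
#' @param scene a [multiband_scene].
#' @param name a registered layer name; see [index_names()].
#' @return A `vi_layer`: list with `name`, `values` (numeric matrix, `NA`
#'   where invalid) and `invalid` (logical matrix).
#' @export
compute_index <- function(scene, name) {
  stopifnot(inherits(scene, "multiband_scene"), is.character(name),
            length(name) == 1L)
  grp <- index_group(name)
  ch <- scene_channels(scene, need = grp)
  reg <- vi_registry()
  values <- reg[[grp]][[name]](ch)
  invalid <- !is.finite(values)
  values[invalid] <- NA_real_
  structure(list(name = name, values = values, invalid = invalid),
            class = "vi_layer")
}

#' Compute a full index stack
#'
#' @param scene a [multiband_scene].
#' @param group which layer group to compute: `"visible"` yields exactly 20
#'   layers, `"multispectral"` 19, `"all"` 39.
#' @return An `index_stack`: list with `layers` (named list of numeric
#'   matrices), `invalid` (named list of logical matrices), `group`, `dim`.
#' @export
compute_stack <- function(scene, group = c("all", "visible",
                                           "multispectral")) {
  group <- match.arg(group)
  nms <- index_names(group)
  need <- unique(vapply(nms, index_group, character(1)))
  scene_channels(scene, need = need)  # fail fast, naming the missing band
  layers <- vector("list", length(nms))
  invalid <- vector("list", length(nms))
  names(layers) <- names(invalid) <- nms
  for (nm in nms) {
    l <- tryCatch(compute_index(scene, nm), error = function(e) {
      stop("index `", nm, "`: ", conditionMessage(e), call. = FALSE)
    })
    layers[[nm]] <- l$values
    invalid[[nm]] <- l$invalid
  }
  structure(list(layers = layers, invalid = invalid, group = group,
                 dim = scene$dim),
            class = "index_stack")
}

#' @export
print.index_stack <- function(x, ...) {
  cat("<index_stack> ", length(x$layers), " layers (", x$group, "), ",
      x$dim[1], "x", x$dim[2], " px\n", sep = "")
  cat("  ", paste(names(x$layers), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Extract per-pixel features from an index stack
#'
#' Looks up every labeled coordinate in every layer of the stack, producing
#' the feature matrix used by the pixel classifiers. Rows with any invalid
#' feature are dropped with a message.
#'
#' @param stack an `index_stack`.
#' @param labels label table with 1-based `col`, `row` columns.
#' @return A list: `features` (numeric matrix, one column per layer),
#'   `labels` (the retained label rows), `n_dropped`.
#' @export
extract_features <- function(stack, labels) {
  stopifnot(inherits(stack, "index_stack"))
  check_labels(labels, stack$dim)
  idx <- cbind(labels$row, labels$col)
  feat <- vapply(stack$layers, function(l) l[idx], numeric(nrow(labels)))
  if (nrow(labels) == 1L) feat <- matrix(feat, nrow = 1L,
                                         dimnames = list(NULL, names(stack$layers)))
  keep <- rowSums(!is.finite(feat)) == 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("extract_features: dropped ", n_dropped,
            " labeled pixel(s) with invalid feature values")
  }
  list(features = feat[keep, , drop = FALSE],
       labels = labels[keep, , drop = FALSE],
       n_dropped = n_dropped)
}
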