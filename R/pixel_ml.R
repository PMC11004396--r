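#' Stratified calibration/validation split of labeled pixels
#'
#' Splits each surface class independently into calibration and validation
#' sets. By default the calibration size per class is
#' `round(fraction * n)`; explicit per-class counts override it (the
#' original study used 200/150/158/133 calibration pixels for
#' seedling/soil/film/tape, which is not a consistent rounding of 2/3).
#' Deterministic for a fixed seed.
#'
#' @param labels label table (`col`, `row`, `class`).
#' @param fraction calibration fraction in (0, 1), default 2/3.
#' @param seed RNG seed.
#' @param counts optional named integer vector of per-class calibration
#'   counts, e.g. `c(seedling = 200, soil = 150, film = 158, tape = 133)`.
#' @return The label table with a `split` column
#'   (`"calibration"`/`"validation"`).
#' @export
split_samples <- function(labels, fraction = 2 / 3, seed = 1L,
                          counts = NULL) {
  stopifnot(is.data.frame(labels), "class" %in% names(labels))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  labels$split <- NA_character_
  with_seed(seed, {
    for (cl in unique(as.character(labels$class))) {
      idx <- which(labels$class == cl)
      n <- length(idx)
      if (n < 2L) {
        stop("class `", cl, "` has fewer than 2 samples", call. = FALSE)
      }
      n_cal <- if (!is.null(counts) && cl %in% names(counts)) {
        as.integer(counts[[cl]])
      } else {
        as.integer(round(fraction * n))
      }
      if (n_cal < 1L || n_cal >= n) {
        stop("calibration count ", n_cal, " for class `", cl,
             "` leaves no validation samples", call. = FALSE)
      }
      cal <- sample(idx, n_cal)
      labels$split[cal] <- "calibration"
      labels$split[setdiff(idx, cal)] <- "validation"
    }
  })
  labels
}

#' Train a pixel classifier on an index-stack feature group
#'
#' Fits a 4-class classifier (seedling, soil, film, tape) on the
#' calibration split of the labeled pixels, using every layer of `stack`
#' as features. Methods: `"svm"` (RBF kernel, cost 1, one-vs-one),
#' `"rf"` (random forest, 100 trees), `"knn"` (k = 5; the "model" stores
#' the calibration features). Features are standardized to calibration
#' mean/SD for SVM and KNN by default, left raw for RF; rows with invalid
#' features are dropped with a message. Training is deterministic given
#' `seed`.
#'
#' @param labels label table with a `split` column (see [split_samples()]).
#' @param stack an `index_stack` defining the feature group
#'   (visible 20 / multispectral 19 / all 39 / key-VI subset).
#' @param method `"svm"`, `"rf"` or `"knn"`.
#' @param seed RNG seed for the stochastic fitters.
#' @param standardize override the per-method default.
#' @param cost,ntree,k hyperparameters (SVM cost, RF trees, KNN
#'   neighbours).
#' @return A `pixel_classifier`.
#' @export
train_classifier <- function(labels, stack, method = c("svm", "rf", "knn"),
                             seed = 1L, standardize = NULL,
                             cost = 1, ntree = 100L, k = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "index_stack"))
  if (!"split" %in% names(labels)) {
    stop("labels lack a `split` column; run split_samples() first",
         call. = FALSE)
  }
  if (is.null(standardize)) standardize <- method %in% c("svm", "knn")
  cal <- labels[labels$split == "calibration", , drop = FALSE]
  if (nrow(cal) == 0L) stop("empty calibration split", call. = FALSE)
  ext <- extract_features(stack, cal)
  x <- ext$features
  y <- factor(as.character(ext$labels$class), levels = feature_classes())
  if (any(table(y) == 0L)) {
    stop("empty calibration class: ",
         paste(names(which(table(y) == 0L)), collapse = ", "), call. = FALSE)
  }
  ctr <- rep(0, ncol(x))
  scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- scale(x, center = ctr, scale = scl)
  }
  fit <- switch(method,
    svm = with_seed(seed,
      e1071::svm(x, y, kernel = "radial", cost = cost, scale = FALSE)),
    rf = with_seed(seed,
      randomForest::randomForest(x, y, ntree = as.integer(ntree))),
    knn = NULL  # lazy learner: calibration set is the model
  )
  structure(
    list(method = method, fit = fit,
         train_x = if (method == "knn") x else NULL,
         train_y = if (method == "knn") y else NULL,
         k = as.integer(k),
         feature_names = colnames(ext$features),
         center = ctr, scale = scl, standardize = standardize,
         seed = as.integer(seed), levels = feature_classes()),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier> ", toupper(x$method), ", ",
      length(x$feature_names), " features",
      if (x$standardize) " (standardized)", "\n", sep = "")
  invisible(x)
}

# Predict class labels for a raw feature matrix (columns must match the
# model's feature group).
predict_pixels <- function(model, features) {
  stopifnot(inherits(model, "pixel_classifier"))
  missing_layers <- setdiff(model$feature_names, colnames(features))
  if (length(missing_layers)) {
    stop("feature matrix lacks layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  x <- features[, model$feature_names, drop = FALSE]
  x <- scale(x, center = model$center, scale = model$scale)
  pred <- switch(model$method,
    svm = predict(model$fit, x),
    rf = predict(model$fit, x),
    knn = with_seed(model$seed,
      class::knn(model$train_x, x, model$train_y, k = model$k))
  )
  factor(as.character(pred), levels = model$levels)
}

#' Classify every pixel of a scene
#'
#' Applies a fitted pixel classifier to all pixels of an index stack,
#' producing a 4-class label map and the seedling-vs-rest binary mask
#' (soil, film and tape collapse to background). Pixels with any invalid
#' feature are assigned to background (soil) without entering the
#' classifier. The stack must contain every layer of the model's feature
#' group; missing layers raise an error naming them.
#'
#' @param model a `pixel_classifier`.
#' @param stack an `index_stack` covering the model's feature group.
#' @return A list: `label_map` (integer matrix of class codes 0-3),
#'   `mask` (oriented `binary_mask` of seedling pixels).
#' @export
classify_scene <- function(model, stack) {
  stopifnot(inherits(model, "pixel_classifier"),
            inherits(stack, "index_stack"))
  missing_layers <- setdiff(model$feature_names, names(stack$layers))
  if (length(missing_layers)) {
    stop("stack lacks layer(s) required by the model: ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  h <- stack$dim[1]
  w <- stack$dim[2]
  n <- h * w
  feat <- vapply(model$feature_names,
                 function(nm) as.vector(stack$layers[[nm]]), numeric(n))
  ok <- rowSums(!is.finite(feat)) == 0L
  codes <- c(soil = 0L, seedling = 1L, film = 2L, tape = 3L)
  lab_vec <- rep(codes[["soil"]], n)
  if (any(ok)) {
    pred <- predict_pixels(model, feat[ok, , drop = FALSE])
    lab_vec[ok] <- codes[as.character(pred)]
  }
  label_map <- matrix(lab_vec, h, w)
  values <- matrix(0L, h, w)
  values[label_map == codes[["seedling"]]] <- 1L
  mask <- structure(
    list(values = values, threshold = NA_real_,
         source = paste0(toupper(model$method), "[",
                         length(model$feature_names), "]"),
         seedling_is_one = TRUE,
         invalid = matrix(!ok, h, w)),
    class = "binary_mask")
  list(label_map = label_map, mask = mask)
}

#' Pixel-sample classification accuracy
#'
#' Accuracy = CS / TS x 100, where CS is the number of correctly labeled
#' pixel samples and TS the total — reported per class and pooled.
#'
#' @param predicted factor/character vector of predicted classes.
#' @param actual factor/character vector of true classes (same length).
#' @return A list: `per_class` (named numeric, percent), `overall`
#'   (percent), `n` (total samples).
#' @export
class_accuracy <- function(predicted, actual) {
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  stopifnot(length(predicted) == length(actual))
  if (length(actual) == 0L) stop("empty sample set", call. = FALSE)
  correct <- predicted == actual
  per_class <- vapply(split(correct, actual), function(z) mean(z) * 100,
                      numeric(1))
  list(per_class = per_class, overall = mean(correct) * 100,
       n = length(actual))
}

#' Validate a classifier on a label split
#'
#' Extracts the features of the requested split, predicts, and reports
#' CS/TS accuracy.
#'
#' @param model a `pixel_classifier`.
#' @param stack the matching `index_stack`.
#' @param labels label table with `split` column.
#' @param split which split to score (default `"validation"`).
#' @return As [class_accuracy()], plus `predicted` and the scored labels.
#' @export
validate_classifier <- function(model, stack, labels,
                                split = "validation") {
  rows <- labels[labels$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("empty split: ", split, call. = FALSE)
  ext <- extract_features(stack, rows)
  pred <- predict_pixels(model, ext$features)
  acc <- class_accuracy(pred, ext$labels$class)
  c(acc, list(predicted = pred, labels = ext$labels))
}
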