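fake_labels <- function(n_per_class) {
  do.call(rbind, lapply(names(n_per_class), function(cl) {
    n <- n_per_class[[cl]]
    data.frame(col = seq_len(n), row = match(cl, feature_classes()),
               class = cl, stringsAsFactors = FALSE)
  }))
}

test_that("stratified split honours explicit per-class counts", {
  lab <- fake_labels(c(seedling = 302L, soil = 224L, film = 237L,
                       tape = 200L))
  sp <- split_samples(lab, seed = 4L,
                      counts = c(seedling = 200L, soil = 150L,
                                 film = 158L, tape = 133L))
  tab <- table(sp$class, sp$split)
  expect_equal(tab["soil", "calibration"], 150L)
  expect_equal(tab["soil", "validation"], 74L)
  expect_equal(tab["seedling", "calibration"], 200L)
  expect_equal(tab["seedling", "validation"], 102L)
  # the per-class calibration counts sum to 641 (and 963 - 322 = 641)
  expect_equal(sum(tab[, "calibration"]), 641L)
  expect_equal(sum(tab[, "validation"]), 322L)
  expect_equal(sum(tab), 963L)
})

test_that("split is a deterministic partition per class", {
  lab <- fake_labels(c(seedling = 10L, soil = 9L))
  a <- split_samples(lab, fraction = 0.5, seed = 7L)
  b <- split_samples(lab, fraction = 0.5, seed = 7L)
  expect_identical(a, b)
  expect_false(identical(a, split_samples(lab, fraction = 0.5, seed = 8L)))
  # fraction 0.5 on n = 10 -> 5/5
  expect_equal(sum(a$split == "calibration" & a$class == "seedling"), 5L)
  expect_true(all(!is.na(a$split)))
  # rounding default: round(2/3 * 9) = 6
  c6 <- split_samples(lab, seed = 1L)
  expect_equal(sum(c6$split == "calibration" & c6$class == "soil"), 6L)
  expect_error(split_samples(fake_labels(c(seedling = 1L, soil = 5L))),
               "fewer than 2")
  expect_error(split_samples(lab, fraction = 1.2), "fraction")
})

test_that("classifiers separate the synthetic classes", {
  out <- bundled_scene()
  stack <- compute_stack(out$scene, "multispectral")
  lab <- split_samples(out$labels, seed = 5L)
  for (method in c("svm", "rf", "knn")) {
    model <- train_classifier(lab, stack, method = method, seed = 5L)
    cal <- validate_classifier(model, stack, lab, split = "calibration")
    val <- validate_classifier(model, stack, lab, split = "validation")
    expect_gte(val$overall, 95, label = paste(method, "validation accuracy"))
    expect_gte(cal$overall, 95, label = paste(method, "calibration accuracy"))
  }
  # KNN with k = 1 memorizes the calibration set
  m1 <- train_classifier(lab, stack, method = "knn", k = 1L, seed = 5L)
  expect_equal(validate_classifier(m1, stack, lab,
                                   split = "calibration")$overall, 100)
})

test_that("training and prediction are deterministic given the seed", {
  out <- bundled_scene()
  stack <- compute_stack(out$scene, "multispectral")
  lab <- split_samples(out$labels, seed = 2L)
  for (method in c("rf", "knn")) {
    m1 <- train_classifier(lab, stack, method = method, seed = 9L)
    m2 <- train_classifier(lab, stack, method = method, seed = 9L)
    v1 <- validate_classifier(m1, stack, lab)
    v2 <- validate_classifier(m2, stack, lab)
    expect_identical(v1$predicted, v2$predicted, info = method)
  }
})

test_that("classify_scene maps classes to a seedling mask", {
  out <- bundled_scene()
  stack <- compute_stack(out$scene, "multispectral")
  lab <- split_samples(out$labels, seed = 3L)
  model <- train_classifier(lab, stack, method = "rf", seed = 3L)
  cls <- classify_scene(model, stack)
  # pixel accuracy against the full ground-truth label map
  acc <- mean(cls$label_map == out$truth$label_map)
  expect_gte(acc, 0.9)
  expect_identical(cls$mask$values,
                   matrix(as.integer(cls$label_map == 1L),
                          nrow(cls$label_map)))
  expect_true(cls$mask$seedling_is_one)

  # a pure-film scene yields zero seedling pixels
  sp <- default_spectra()
  film <- multiband_scene(
    reflectance = array(rep(sp$reflectance["film", ], each = 900),
                        c(30, 30, 5)))
  film_stack <- compute_stack(film, "multispectral")
  expect_equal(sum(classify_scene(model, film_stack)$mask$values), 0L)

  # feature-group contract: 39-feature model on a 19-layer stack fails
  model39 <- train_classifier(lab, compute_stack(out$scene, "all"),
                              method = "rf", seed = 3L)
  expect_error(classify_scene(model39, stack), "lacks layer")
  expect_error(train_classifier(out$labels, stack, method = "rf"), "split")
  expect_error(train_classifier(lab, stack, method = "lda"), "arg")
})

test_that("accuracy is CS/TS x 100, per class and pooled", {
  expect_equal(class_accuracy(rep("soil", 50), rep("soil", 50))$overall, 100)
  expect_equal(class_accuracy(rep("film", 50), rep("soil", 50))$overall, 0)
  pred <- c(rep("seedling", 96), rep("soil", 4))
  actual <- rep("seedling", 100)
  expect_equal(class_accuracy(pred, actual)$overall, 96)
  expect_equal(class_accuracy(pred, actual)$per_class[["seedling"]], 96)
  expect_error(class_accuracy(character(0), character(0)), "empty")
})
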