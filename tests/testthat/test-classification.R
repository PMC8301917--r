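# Small separable 5-class dataset for classifier-protocol tests: three
# informative features plus noise, mimicking the parameter families that
# separate the composite call types.
make_separable <- function(n_per_class = 30, seed = 1) {
  cls <- composite_labels()
  with_seed_test(seed, {
    rows <- lapply(seq_along(cls), function(k) {
      data.frame(
        freq_median_hz = rnorm(n_per_class, c(55000, 55000, 55000, 24000, 25000)[k], 800),
        freq_range_hz = rnorm(n_per_class, c(1000, 12000, 10000, 500, 500)[k], 300),
        n_slope_sign_changes = pmax(0, rnorm(n_per_class, c(0, 1, 8, 0, 0)[k], 0.5)),
        duration_s = rnorm(n_per_class, c(0.08, 0.1, 0.15, 0.7, 0.15)[k], 0.01),
        noise1 = rnorm(n_per_class),
        noise2 = rnorm(n_per_class),
        label = cls[k])
    })
    do.call(rbind, rows)
  })
}

test_that("the Wright scheme maps onto the five-call composite", {
  expect_equal(map_wright_to_composite("Flat"), "FixedFrequency50")
  expect_equal(map_wright_to_composite("Trill with jumps"),
               "FrequencyModulatedTrill50")
  expect_equal(map_wright_to_composite("22-kHz call"), "Long22kHz")
  expect_equal(map_wright_to_composite("Short 22-kHz"), "Short22kHz")
  wright <- c("Flat", "Short", "Upward Ramp", "Downward Ramp", "Split",
              "Step Up", "Step Down", "Multi-step", "Inverted-U", "Complex",
              "Composite", "Trill", "Flat-Trill Combo", "Trill with jumps",
              "22-kHz call", "Short 22-kHz")
  mapped <- map_wright_to_composite(wright)
  expect_equal(as.integer(table(mapped)[composite_labels()]), c(2L, 9L, 3L, 1L, 1L))
  expect_error(map_wright_to_composite("warble"), "valid inputs")
})

test_that("the 70/30 split reproduces the published support sizes", {
  data931 <- data.frame(x = seq_len(931), label = rep(composite_labels(), length.out = 931))
  sp <- split_train_test(data931, test_fraction = 0.30, seed = 1)
  expect_equal(nrow(sp$train), 651)
  expect_equal(nrow(sp$test), 280)
  expect_equal(sort(c(sp$train$x, sp$test$x)), seq_len(931)) # disjoint, exhaustive

  sp2 <- split_train_test(data.frame(x = 1:10, label = "a"), 0.5, seed = 2)
  expect_equal(nrow(sp2$train), 5)
  expect_equal(nrow(sp2$test), 5)

  a <- split_train_test(data931, seed = 7)
  b <- split_train_test(data931, seed = 7)
  expect_identical(a$train$x, b$train$x)

  rare <- data.frame(x = 1:12, label = c(rep("a", 11), "b"))
  seed_missing_b <- NULL
  for (s in 1:100) {
    sp3 <- suppressWarnings(split_train_test(rare, 0.4, seed = s))
    if (!"b" %in% sp3$train$label) { seed_missing_b <- s; break }
  }
  expect_false(is.null(seed_missing_b))
  expect_warning(split_train_test(rare, 0.4, seed = seed_missing_b), "absent")
})

test_that("feature selection keeps informative fields and drops constants", {
  train <- make_separable(40, seed = 2)
  train$constant_field <- 5
  feats <- select_features(train, max_features = 4, seed = 1)
  expect_false("constant_field" %in% feats)
  expect_lte(length(feats), 4)
  expect_true("freq_median_hz" %in% feats)

  # a perfect predictor is ranked first
  train$oracle_feature <- as.integer(factor(train$label))
  feats2 <- select_features(train, max_features = 6, seed = 1)
  expect_equal(feats2[1], "oracle_feature")
})

test_that("grid tuning is deterministic, order-invariant and argmax-consistent", {
  train <- make_separable(20, seed = 3)
  grid <- data.frame(n_trees = c(50L, 120L), max_depth = c(4L, 0L),
                     mtry = c("sqrt", "sqrt"), stringsAsFactors = FALSE)

  single <- tune_and_train(train, grid = grid[2, ], seed = 5)
  expect_equal(single$best$n_trees, 120L)

  m1 <- tune_and_train(train, grid = grid, seed = 5)
  m2 <- tune_and_train(train, grid = grid, seed = 5)
  expect_identical(m1$best, m2$best)
  expect_identical(m1$cv_accuracy, m2$cv_accuracy)
  expect_gte(max(m1$cv_accuracy), m1$cv_accuracy[1])

  # permuting training rows does not change the tuned hyperparameters
  perm <- with_seed_test(99, sample.int(nrow(train)))
  m3 <- tune_and_train(train[perm, ], grid = grid, seed = 5)
  expect_identical(m1$best, m3$best)
  expect_identical(m1$cv_accuracy, m3$cv_accuracy)

  expect_error(tune_and_train(transform(train, label = "a"), grid = grid),
               "single class")
})

test_that("classification returns normalized scores and recalls its training data", {
  train <- make_separable(25, seed = 4)
  model <- tune_and_train(train, grid = data.frame(n_trees = 150L,
                                                   max_depth = 0L,
                                                   mtry = "sqrt"),
                          seed = 6)
  res <- classify(model, train)
  expect_true(all(abs(rowSums(res$scores) - 1) < 1e-9))
  expect_true(all(res$scores >= 0))
  expect_gt(mean(res$label == train$label), 0.98) # memorization check

  expect_error(classify(model, train[, 1:2, drop = FALSE]), "missing feature")

  # per-class supports on a held-out set sum to the test-set size
  sp <- split_train_test(make_separable(30, seed = 5), 0.3, seed = 1)
  model2 <- tune_and_train(sp$train, grid = data.frame(n_trees = 100L,
                                                       max_depth = 0L,
                                                       mtry = "sqrt"),
                           seed = 2)
  pred <- classify(model2, sp$test)
  mt <- metrics_table(confusion_counts(sp$test$label, pred$label,
                                       composite_labels()))
  expect_equal(sum(mt$per_class$support), nrow(sp$test))
  expect_gt(mt$overall$accuracy, 0.9)
})

test_that("models survive a JSON save/load round trip", {
  train <- make_separable(20, seed = 8)
  model <- tune_and_train(train, grid = data.frame(n_trees = 60L,
                                                   max_depth = 8L,
                                                   mtry = "sqrt"),
                          seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$selected_features, model$selected_features)
  expect_identical(back$class_order, model$class_order)
  probe <- make_separable(5, seed = 9)
  expect_equal(classify(back, probe)$scores, classify(model, probe)$scores)
  expect_error(load_model(withr::local_tempfile(fileext = ".json", lines = "{}")),
               "not a usvscore")
})
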