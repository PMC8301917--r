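wright_mapping <- c(
  "Flat" = "FixedFrequency50",
  "Short" = "FixedFrequency50",
  "Upward Ramp" = "FrequencyModulated50",
  "Downward Ramp" = "FrequencyModulated50",
  "Split" = "FrequencyModulated50",
  "Step Up" = "FrequencyModulated50",
  "Step Down" = "FrequencyModulated50",
  "Multi-step" = "FrequencyModulated50",
  "Inverted-U" = "FrequencyModulated50",
  "Complex" = "FrequencyModulated50",
  "Composite" = "FrequencyModulated50",
  "Trill" = "FrequencyModulatedTrill50",
  "Flat-Trill Combo" = "FrequencyModulatedTrill50",
  "Trill with jumps" = "FrequencyModulatedTrill50",
  "22-kHz call" = "Long22kHz",
  "Short 22-kHz" = "Short22kHz")

#' Map Wright et al. call types to the five-call composite
#'
#' Deterministic mapping of the 16 Wright-scheme call types onto the
#' composite scheme: Flat and Short become fixed-frequency 50-kHz; ramps,
#' splits, steps, inverted-U, complex and composite calls become
#' frequency-modulated 50-kHz; trill variants become trilled 50-kHz; the
#' 22-kHz call and its short variant map to the long and short 22-kHz
#' classes.
#'
#' @param wright_label character vector of Wright call-type names.
#' @return Character vector of [composite_labels()] values.
#' @export
map_wright_to_composite <- function(wright_label) {
  bad <- setdiff(wright_label, names(wright_mapping))
  if (length(bad))
    stop("unknown Wright call type(s): ", paste(unique(bad), collapse = ", "),
         "; valid inputs are: ", paste(names(wright_mapping), collapse = ", "))
  unname(wright_mapping[wright_label])
}

#' Split labeled data into training and test sets
#'
#' Seeded unstratified shuffle; the training set holds
#' `floor((1 - test_fraction) * n)` rows (70/30 of 931 calls gives 651/280).
#'
#' @param data data.frame with one row per call, including a `label` column.
#' @param test_fraction fraction held out for testing (0 < f < 1).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames (disjoint, exhaustive).
#'   Warns when a class is absent from the training set.
#' @export
split_train_test <- function(data, test_fraction = 0.3, seed = 1) {
  stopifnot(is.data.frame(data), test_fraction > 0, test_fraction < 1)
  n <- nrow(data)
  if (n < 10) stop("need at least 10 observations to split")
  n_train <- floor((1 - test_fraction) * n)
  idx <- with_seed(seed, sample.int(n))
  train <- data[idx[seq_len(n_train)], , drop = FALSE]
  test <- data[idx[(n_train + 1):n], , drop = FALSE]
  if ("label" %in% names(data)) {
    absent <- setdiff(unique(data$label), unique(train$label))
    if (length(absent))
      warning("class(es) absent from training set: ",
              paste(absent, collapse = ", "))
  }
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Select predictive features by forest importance
#'
#' Drops zero-variance fields, ranks the rest by impurity importance from a
#' preliminary forest, and keeps features in descending importance until
#' `max_features` or until importance falls below `min_importance`.
#'
#' @param train data.frame with feature columns and a `label` column.
#' @param max_features maximum number of features kept.
#' @param min_importance minimum Gini importance to keep a feature.
#' @param n_trees trees in the preliminary forest.
#' @param seed RNG seed.
#' @return Ordered character vector of selected feature names.
#' @export
select_features <- function(train, max_features = 20, min_importance = 0,
                            n_trees = 200, seed = 1) {
  stopifnot("label" %in% names(train))
  if (length(unique(train$label)) < 2)
    stop("feature selection needs at least 2 classes")
  feats <- setdiff(names(train), c("label", "call_id", "scorer_id"))
  feats <- feats[vapply(train[feats], is.numeric, TRUE)]
  variances <- vapply(train[feats], function(z) stats::var(z), 0)
  feats <- feats[is.finite(variances) & variances > 0]
  if (!length(feats)) stop("no informative features after variance filtering")
  fit <- rf_train(train[, feats, drop = FALSE], train$label, n_trees = n_trees,
                  seed = seed)
  imp <- sort(fit$importance, decreasing = TRUE)
  imp <- imp[imp > min_importance]
  head(names(imp), max_features)
}

#' Default hyperparameter lattice
#'
#' Trees in {100, 300}, maximum depth in {unlimited, 10, 20}, features per
#' split in {sqrt(p), 0.3 p}.
#'
#' @return data.frame with one row per lattice point.
#' @export
default_tuning_grid <- function() {
  g <- expand.grid(n_trees = c(100L, 300L), max_depth = c(0L, 10L, 20L),
                   mtry = c("sqrt", "0.3"), stringsAsFactors = FALSE)
  g[order(g$n_trees, g$max_depth, g$mtry), , drop = FALSE]
}

grid_mtry <- function(m) if (m == "sqrt") "sqrt" else as.numeric(m)

#' Tune and train the call-type classifier
#'
#' k-fold cross-validated accuracy is computed at every lattice point on the
#' training data only; the best point (ties broken by smaller forest, then by
#' lattice order) is refit on the full training set. Feature selection runs
#' on the training data when `features` is `NULL`.
#'
#' @param train data.frame with feature columns and a `label` column.
#' @param grid hyperparameter lattice, as [default_tuning_grid()].
#' @param features feature names to use; `NULL` runs [select_features()].
#' @param k_folds number of cross-validation folds.
#' @param class_weights passed to [rf_train()].
#' @param seed RNG seed controlling folds and forests.
#' @return `usv_classifier` with the fitted `forest`, `selected_features`,
#'   `cv_results`, `best` configuration, `class_order`, `seed`.
#' @export
tune_and_train <- function(train, grid = default_tuning_grid(),
                           features = NULL, k_folds = 5,
                           class_weights = "inverse", seed = 1) {
  stopifnot("label" %in% names(train), nrow(grid) >= 1)
  if (length(unique(train$label)) < 2)
    stop("degenerate training set: a single class")
  # canonical row order: folds, bootstraps and hence tuned hyperparameters do
  # not depend on the order the caller stored the training rows in
  num <- names(train)[vapply(train, is.numeric, TRUE)]
  canon <- do.call(order, train[, c("label", num), drop = FALSE])
  train <- train[canon, , drop = FALSE]
  if (is.null(features))
    features <- select_features(train, seed = seed)
  x <- train[, features, drop = FALSE]
  y <- factor(train$label, levels = sort(unique(train$label)))
  n <- nrow(x)
  folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  cv_acc <- numeric(nrow(grid))
  if (nrow(grid) > 1) {
    for (gi in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(k_folds)) {
        tr <- folds != f
        fit <- rf_train(x[tr, , drop = FALSE], y[tr],
                        n_trees = grid$n_trees[gi],
                        mtry = grid_mtry(grid$mtry[gi]),
                        max_depth = grid$max_depth[gi],
                        class_weights = class_weights,
                        seed = seed + 31L * gi + f)
        pred <- predict(fit, x[!tr, , drop = FALSE], type = "class")
        correct <- correct + sum(pred == as.character(y[!tr]))
      }
      cv_acc[gi] <- correct / n
    }
    best <- order(-cv_acc, grid$n_trees, seq_len(nrow(grid)))[1]
  } else {
    best <- 1L
    cv_acc <- NA_real_
  }
  forest <- rf_train(x, y, n_trees = grid$n_trees[best],
                     mtry = grid_mtry(grid$mtry[best]),
                     max_depth = grid$max_depth[best],
                     class_weights = class_weights, seed = seed)
  structure(list(forest = forest, selected_features = features,
                 grid = grid, cv_accuracy = cv_acc,
                 best = grid[best, , drop = FALSE],
                 class_order = levels(y), seed = seed),
            class = "usv_classifier")
}

#' Classify parameterized calls
#'
#' @param model a [tune_and_train()] classifier.
#' @param params one-row or multi-row data.frame of call parameters
#'   containing the model's selected features.
#' @return list with `label` (character vector; argmax with ties to the first
#'   class in `class_order`) and `scores` (matrix, rows sum to 1).
#' @export
classify <- function(model, params) {
  stopifnot(inherits(model, "usv_classifier"))
  params <- as.data.frame(params)
  missing <- setdiff(model$selected_features, colnames(params))
  if (length(missing))
    stop("missing feature(s) required by the model: ",
         paste(missing, collapse = ", "))
  scores <- predict(model$forest, params, type = "prob")
  list(label = model$class_order[apply(scores, 1L, which.max)],
       scores = scores)
}

#' Save / load a classifier as versioned JSON
#'
#' The file embeds the format version, selected features, class order, seed
#' and the full forest, so `load_model(save_model(m, f))` predicts
#' identically.
#'
#' @param model a `usv_classifier`.
#' @param path file path (JSON).
#' @return `path` (save) or the restored `usv_classifier` (load).
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "usvscore-classifier",
    version = 1L,
    selected_features = model$selected_features,
    class_order = model$class_order,
    seed = model$seed,
    best = as.list(model$best),
    forest = list(classes = model$forest$classes,
                  feature_names = model$forest$feature_names,
                  config = model$forest$config,
                  importance = as.list(model$forest$importance),
                  trees = model$forest$trees))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "usvscore-classifier"))
    stop("not a usvscore classifier file: ", path)
  trees <- lapply(p$forest$trees, function(tr) {
    list(feature = vapply(tr$feature, as.integer, 0L),
         threshold = vapply(tr$threshold, as.numeric, 0),
         left = vapply(tr$left, as.integer, 0L),
         right = vapply(tr$right, as.integer, 0L),
         probs = do.call(rbind, lapply(tr$probs, function(row)
           vapply(row, as.numeric, 0))))
  })
  forest <- structure(list(trees = trees,
                           importance = unlist(p$forest$importance),
                           classes = unlist(p$forest$classes),
                           feature_names = unlist(p$forest$feature_names),
                           config = p$forest$config),
                      class = "usv_forest")
  structure(list(forest = forest,
                 selected_features = unlist(p$selected_features),
                 grid = NULL, cv_accuracy = NULL,
                 best = as.data.frame(p$best),
                 class_order = unlist(p$class_order), seed = p$seed),
            class = "usv_classifier")
}

#' @export
print.usv_classifier <- function(x, ...) {
  cat(sprintf("<usv_classifier> %d-class forest (%d trees), %d features\n",
              length(x$class_order), length(x$forest$trees),
              length(x$selected_features)))
  invisible(x)
}
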