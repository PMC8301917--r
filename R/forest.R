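#' Train a random forest classifier
#'
#' Bagged CART trees with Gini impurity and a random feature subset at every
#' split. Class imbalance can be handled with inverse-frequency class weights
#' (applied inside the impurity and the leaf proportions). Reproducible given
#' `seed`.
#'
#' @param x numeric matrix or data.frame of features (rows = observations).
#' @param y factor (or coercible) of class labels; its levels fix the class
#'   order.
#' @param n_trees number of trees.
#' @param mtry features tried per split: `"sqrt"` (default), a fraction in
#'   (0, 1), or an integer count.
#' @param max_depth maximum tree depth; 0 means unlimited.
#' @param min_node minimum node size to attempt a split.
#' @param class_weights `"inverse"` (inverse class frequency), `NULL`
#'   (uniform), or a numeric vector over levels of `y`.
#' @param seed integer RNG seed.
#' @return `usv_forest` with `trees`, `importance` (named Gini decrease),
#'   `classes`, `feature_names`, `config`.
#' @export
rf_train <- function(x, y, n_trees = 300, mtry = "sqrt", max_depth = 0,
                     min_node = 1, class_weights = "inverse", seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  classes <- levels(y)
  if (length(classes) < 2) stop("training data contain a single class")
  yi <- as.integer(y) - 1L
  p <- ncol(x)
  m <- resolve_mtry(mtry, p)
  cw <- if (is.null(class_weights)) rep(1, length(classes))
  else if (identical(class_weights, "inverse")) {
    tab <- table(y)
    as.numeric(length(y) / (length(classes) * tab))
  } else {
    stopifnot(length(class_weights) == length(classes))
    as.numeric(class_weights)
  }
  fit <- rf_train_cpp(x, yi, length(classes), as.integer(n_trees),
                      as.integer(m), as.integer(max_depth),
                      as.integer(min_node), cw, as.integer(seed))
  structure(list(trees = fit$trees,
                 importance = setNames(fit$importance, colnames(x)),
                 classes = classes,
                 feature_names = colnames(x),
                 config = list(n_trees = n_trees, mtry = mtry,
                               max_depth = max_depth, min_node = min_node,
                               class_weights = cw, seed = seed)),
            class = "usv_forest")
}

resolve_mtry <- function(mtry, p) {
  if (identical(mtry, "sqrt")) max(1L, floor(sqrt(p)))
  else if (is.numeric(mtry) && mtry > 0 && mtry < 1) max(1L, floor(mtry * p))
  else if (is.numeric(mtry) && mtry >= 1) min(as.integer(mtry), p)
  else stop("mtry must be 'sqrt', a fraction, or a count")
}

#' Predict from a random forest
#'
#' @param object a [rf_train()] forest.
#' @param newdata matrix or data.frame containing the training features.
#' @param type `"prob"` for the class-score matrix (rows sum to 1) or
#'   `"class"` for labels (argmax, ties to the first class in order).
#' @param ... unused.
#' @return Matrix of scores or character vector of labels.
#' @export
predict.usv_forest <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  pr <- rf_predict_cpp(object$trees, x, length(object$classes))
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  object$classes[apply(pr, 1L, which.max)]
}

#' @export
print.usv_forest <- function(x, ...) {
  cat(sprintf("<usv_forest> %d trees, %d features, classes: %s\n",
              length(x$trees), length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
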