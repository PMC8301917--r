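#' Match predicted call intervals to ground truth
#'
#' Greedy one-to-one matching of predicted to truth intervals. With the
#' `"overlap"` policy (default) candidate pairs are all pairs with positive
#' temporal overlap, taken in order of decreasing overlap (ties: earlier truth
#' start, then earlier predicted start). With the `"midpoint"` policy a pair
#' qualifies when interval midpoints are within `tol_s`, taken in order of
#' increasing midpoint distance. Unmatched truth calls are missed; unmatched
#' predictions are false positives.
#'
#' @param truth,predicted data.frames with `start_s`, `end_s` columns
#'   (half-open intervals).
#' @param policy `"overlap"` or `"midpoint"`.
#' @param tol_s midpoint tolerance in seconds (midpoint policy only).
#' @return `usv_match`: list with counts `detected`, `missed`,
#'   `false_positive` and a `pairs` data.frame (`truth_index`,
#'   `predicted_index`).
#' @export
match_calls <- function(truth, predicted, policy = c("overlap", "midpoint"),
                        tol_s = 0.03) {
  policy <- match.arg(policy)
  check_intervals(truth, "truth")
  check_intervals(predicted, "predicted")
  nt <- nrow(truth)
  np <- nrow(predicted)
  pairs <- data.frame(truth_index = integer(0), predicted_index = integer(0))
  if (nt > 0 && np > 0) {
    if (policy == "overlap") {
      ov <- outer(seq_len(nt), seq_len(np), function(i, j) {
        pmax(0, pmin(truth$end_s[i], predicted$end_s[j]) -
               pmax(truth$start_s[i], predicted$start_s[j]))
      })
      cand <- which(ov > 0, arr.ind = TRUE)
      score <- -ov[cand]
    } else {
      mt <- (truth$start_s + truth$end_s) / 2
      mp <- (predicted$start_s + predicted$end_s) / 2
      d <- abs(outer(mt, mp, "-"))
      cand <- which(d <= tol_s, arr.ind = TRUE)
      score <- d[cand]
    }
    if (nrow(cand)) {
      o <- order(score, truth$start_s[cand[, 1]], predicted$start_s[cand[, 2]])
      cand <- cand[o, , drop = FALSE]
      t_used <- logical(nt)
      p_used <- logical(np)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!t_used[i] && !p_used[j]) {
          t_used[i] <- TRUE
          p_used[j] <- TRUE
          pairs <- rbind(pairs, data.frame(truth_index = i, predicted_index = j))
        }
      }
    }
  }
  structure(list(detected = nrow(pairs), missed = nt - nrow(pairs),
                 false_positive = np - nrow(pairs), pairs = pairs,
                 n_truth = nt, n_predicted = np),
            class = "usv_match")
}

check_intervals <- function(x, what) {
  stopifnot(is.data.frame(x), all(c("start_s", "end_s") %in% names(x)))
  if (nrow(x) && any(x$end_s <= x$start_s))
    stop("malformed ", what, " interval: end_s must exceed start_s")
  invisible(x)
}

#' Detection sensitivity: Detected / (Detected + Missed)
#'
#' @param m a [match_calls()] result.
#' @return Rate in `[0, 1]`.
#' @export
detection_sensitivity <- function(m) {
  if ((m$detected + m$missed) == 0)
    stop("undefined metric: no ground-truth calls")
  m$detected / (m$detected + m$missed)
}

#' Detection precision: Detected / (Detected + False Positive)
#'
#' @param m a [match_calls()] result.
#' @return Rate in `[0, 1]`.
#' @export
detection_precision <- function(m) {
  if ((m$detected + m$false_positive) == 0)
    stop("undefined metric: no predicted calls")
  m$detected / (m$detected + m$false_positive)
}

#' One-vs-rest confusion counts per class
#'
#' For each class A: TP (both raters chose A), TN (neither chose A), FP
#' (classifier chose A, truth did not), FN (truth chose A, classifier did
#' not).
#'
#' @param truth_labels,predicted_labels equal-length label vectors.
#' @param class_order character vector fixing the class order; defaults to the
#'   sorted union of observed labels.
#' @return `usv_confusion`: per-class `tp`, `tn`, `fp`, `fn`, the full
#'   cross-table, `class_order`, `n`.
#' @export
confusion_counts <- function(truth_labels, predicted_labels,
                             class_order = NULL) {
  truth_labels <- as.character(truth_labels)
  predicted_labels <- as.character(predicted_labels)
  stopifnot(length(truth_labels) == length(predicted_labels))
  if (is.null(class_order))
    class_order <- sort(unique(c(truth_labels, predicted_labels)))
  bad <- setdiff(unique(c(truth_labels, predicted_labels)), class_order)
  if (length(bad))
    stop("labels outside class_order: ", paste(bad, collapse = ", "))
  tf <- factor(truth_labels, levels = class_order)
  pf <- factor(predicted_labels, levels = class_order)
  tab <- table(truth = tf, predicted = pf)
  n <- length(truth_labels)
  tp <- diag(tab)
  fn <- rowSums(tab) - tp
  fp <- colSums(tab) - tp
  tn <- n - tp - fn - fp
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, table = tab,
                 class_order = class_order, n = n),
            class = "usv_confusion")
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * p * r / (p + r)`; 0 when both are 0.
#'
#' @param precision,recall rates in `[0, 1]` (vectorized).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Per-class precision/recall/F1/support and overall accuracy
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 the harmonic mean, support
#' the number of true instances. Classes with TP+FP = 0 report precision 0
#' with `undefined_precision = TRUE` so the table always has one row per
#' class. Overall accuracy is the multi-class reading, sum of per-class TP
#' over n.
#'
#' @param cc a [confusion_counts()] result.
#' @return `usv_metrics_table`: `per_class` data.frame and `overall`
#'   (accuracy, total_support).
#' @export
metrics_table <- function(cc) {
  stopifnot(inherits(cc, "usv_confusion"))
  prec <- ifelse(cc$tp + cc$fp > 0, cc$tp / (cc$tp + cc$fp), 0)
  rec <- ifelse(cc$tp + cc$fn > 0, cc$tp / (cc$tp + cc$fn), 0)
  per_class <- data.frame(
    class = cc$class_order,
    precision = as.numeric(prec),
    recall = as.numeric(rec),
    f1 = as.numeric(f1_score(prec, rec)),
    support = as.numeric(cc$tp + cc$fn),
    undefined_precision = as.numeric(cc$tp + cc$fp) == 0,
    row.names = NULL)
  structure(list(per_class = per_class,
                 overall = list(accuracy = sum(cc$tp) / cc$n,
                                total_support = cc$n)),
            class = "usv_metrics_table")
}

#' @export
print.usv_metrics_table <- function(x, digits = 2, ...) {
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df[, c("class", "precision", "recall", "f1", "support")],
        row.names = FALSE)
  cat(sprintf("Overall accuracy %.2f on %d observations\n",
              x$overall$accuracy, x$overall$total_support))
  invisible(x)
}

#' Export a metrics table as CSV
#'
#' One row per class (`class`, `precision`, `recall`, `f1`, `support`,
#' rounded to `digits`) plus a final `Overall` row carrying the accuracy and
#' total support.
#'
#' @param mt a [metrics_table()] result.
#' @param path output path.
#' @param digits display rounding (the in-memory table stays unrounded).
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(mt, path, digits = 2) {
  stopifnot(inherits(mt, "usv_metrics_table"))
  df <- mt$per_class[, c("class", "precision", "recall", "f1", "support")]
  for (col in c("precision", "recall", "f1"))
    df[[col]] <- round(df[[col]], digits)
  df <- rbind(df, data.frame(class = "Overall", precision = NA, recall = NA,
                             f1 = round(mt$overall$accuracy, digits),
                             support = mt$overall$total_support))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cohen's kappa between two labelers
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and chance
#' agreement `p_e` from the marginal label distributions.
#'
#' @param labels_a,labels_b equal-length, non-empty label vectors.
#' @param class_order optional fixed class order.
#' @return `usv_agreement`: `kappa`, `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(labels_a, labels_b, class_order = NULL) {
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  if (is.null(class_order))
    class_order <- sort(unique(c(labels_a, labels_b)))
  fa <- factor(labels_a, levels = class_order)
  fb <- factor(labels_b, levels = class_order)
  n <- length(labels_a)
  p_o <- mean(labels_a == labels_b)
  p_e <- sum((table(fa) / n) * (table(fb) / n))
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else if (p_o == 1) 1 else
    stop("kappa undefined: both raters constant but unequal agreement")
  structure(list(kappa = kappa, p_o = p_o, p_e = as.numeric(p_e), n = n),
            class = "usv_agreement")
}

#' Two-sided pooled two-proportion z-test
#'
#' Compares `x1/n1` with `x2/n2` using the pooled standard error, without
#' continuity correction. Returns 1 when the proportions are equal.
#'
#' @param x1,n1,x2,n2 successes and trials per group.
#' @return Two-sided p-value.
#' @export
compare_proportions <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  if (p1 == p2) return(1)
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  2 * pnorm(-abs(z))
}
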