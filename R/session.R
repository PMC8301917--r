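#' Write scoring results to CSV
#'
#' RFC-4180 CSV with header, UTF-8, '.' decimal. Fixed column order:
#' `call_id`, `start_s`, `end_s`, `call_type`, `confidence_pct`, the
#' [call_parameter_fields()] (minus the duplicated confidence), `comment`.
#' Floats are written with 6 significant digits, so a round-trip through
#' [read_results_csv()] is lossless to that precision.
#'
#' @param records data.frame as built by [results_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(records, path) {
  cols <- results_columns()
  stopifnot(all(cols %in% names(records)))
  out <- records[, cols, drop = FALSE]
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(call_type = "character",
                                comment = "character"))
  df$call_type[is.na(df$call_type)] <- ""
  df$comment[is.na(df$comment)] <- ""
  df
}

results_columns <- function() {
  params <- setdiff(call_parameter_fields(), "confidence_pct")
  c("call_id", "start_s", "end_s", "call_type", "confidence_pct", params,
    "comment")
}

#' Assemble scoring records from a detection
#'
#' @param det a [detect_calls()] result.
#' @param params optional precomputed [parameter_table()] for `det`.
#' @param call_type character vector of labels (empty string = unclassified).
#' @param comment character vector of comments.
#' @return data.frame in the [write_results_csv()] column order.
#' @export
results_records <- function(det, params = NULL, call_type = "", comment = "") {
  if (is.null(params)) params <- parameter_table(det)
  iv <- call_intervals(det)
  n <- nrow(params)
  df <- cbind(data.frame(call_id = params$call_id,
                         start_s = iv$start_s, end_s = iv$end_s,
                         call_type = rep_len(as.character(call_type), n),
                         stringsAsFactors = FALSE),
              params[, setdiff(names(params), "call_id"), drop = FALSE],
              data.frame(comment = rep_len(as.character(comment), n),
                         stringsAsFactors = FALSE))
  df[, results_columns(), drop = FALSE]
}

#' Start a hand-scorer training session
#'
#' The expert's classifications are the teaching signal; the trainee answers
#' call by call with immediate feedback and retries until correct
#' ([record_attempt()]), and the first-attempt accuracy summarizes the
#' session ([first_attempt_accuracy()]).
#'
#' @param expert_key data.frame with `call_id` and `label` columns (the
#'   expert's classification of each training call).
#' @return `usv_training_session`.
#' @export
training_session <- function(expert_key) {
  stopifnot(is.data.frame(expert_key),
            all(c("call_id", "label") %in% names(expert_key)))
  if (anyDuplicated(expert_key$call_id))
    stop("expert key has duplicated call_id values")
  structure(list(expert_key = expert_key,
                 attempts = data.frame(call_id = integer(0),
                                       attempt_number = integer(0),
                                       chosen_label = character(0),
                                       correct = logical(0),
                                       stringsAsFactors = FALSE),
                 done = setNames(rep(FALSE, nrow(expert_key)),
                                 expert_key$call_id),
                 completed = nrow(expert_key) == 0L),
            class = "usv_training_session")
}

#' Record a trainee's classification attempt
#'
#' @param session a [training_session()].
#' @param call_id the call being classified (must be in the key and not yet
#'   complete).
#' @param chosen_label the trainee's classification.
#' @return list with `feedback` (`"correct"`/`"incorrect"`) and the updated
#'   `session`; `session$completed` flips when every call has been answered
#'   correctly.
#' @export
record_attempt <- function(session, call_id, chosen_label) {
  stopifnot(inherits(session, "usv_training_session"))
  key <- session$expert_key
  row <- match(call_id, key$call_id)
  if (is.na(row)) stop("call_id not in the expert key: ", call_id)
  if (session$done[[as.character(call_id)]])
    stop("state error: call ", call_id, " is already complete")
  n_prev <- sum(session$attempts$call_id == call_id)
  correct <- identical(as.character(chosen_label), as.character(key$label[row]))
  session$attempts <- rbind(session$attempts, data.frame(
    call_id = call_id, attempt_number = n_prev + 1L,
    chosen_label = as.character(chosen_label), correct = correct,
    stringsAsFactors = FALSE))
  if (correct) {
    session$done[[as.character(call_id)]] <- TRUE
    session$completed <- all(session$done)
  }
  list(feedback = if (correct) "correct" else "incorrect", session = session)
}

#' First-attempt accuracy of a completed training session
#'
#' @param session a completed [training_session()].
#' @return Fraction of calls answered correctly on attempt 1.
#' @export
first_attempt_accuracy <- function(session) {
  stopifnot(inherits(session, "usv_training_session"))
  if (!session$completed) stop("session not complete")
  first <- session$attempts[session$attempts$attempt_number == 1L, ]
  mean(first$correct)
}
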