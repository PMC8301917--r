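#' Extract the maximal-power ridge of a candidate segment
#'
#' For every frame inside the segment, the ridge frequency is the argmax of
#' power over the segment's frequency rows; a frame is valid when its ridge
#' power exceeds the per-bin detection threshold. Call bounds are refined to
#' the first and last valid frames.
#'
#' @param spec spectrogram.
#' @param seg one-row candidate-segment data.frame.
#' @param noise [estimate_background()] result.
#' @param cfg [detection_config()] (threshold parameters).
#' @return `usv_ridge` with per-frame `times_s`, `freqs_hz`, `powers_db`,
#'   `valid`, plus global `bin_index`/`col_index` into the spectrogram, or
#'   `NULL` when no frame is valid (the segment is a detection false alarm).
#' @export
extract_ridge <- function(spec, seg, noise, cfg = detection_config()) {
  cols <- which(spec$times_s >= seg$t_start_s & spec$times_s < seg$t_end_s)
  rows <- which(spec$freqs_hz >= seg$f_lo_hz & spec$freqs_hz <= seg$f_hi_hz)
  if (!length(cols) || !length(rows)) return(NULL)
  sub <- spec$power_db[rows, cols, drop = FALSE]
  ri <- if (length(rows) == 1L) rep(1L, length(cols)) else
    apply(sub, 2L, which.max)
  bin <- rows[ri]
  powers <- sub[cbind(ri, seq_along(cols))]
  thr <- detection_threshold_db(noise, cfg)
  valid <- powers > thr[bin]
  if (!any(valid)) return(NULL)
  keep <- seq(which(valid)[1], tail(which(valid), 1))
  structure(list(times_s = spec$times_s[cols[keep]],
                 freqs_hz = spec$freqs_hz[bin[keep]],
                 powers_db = powers[keep],
                 valid = valid[keep],
                 bin_index = bin[keep],
                 col_index = cols[keep]),
            class = "usv_ridge")
}

# Split a ridge where an internal invalid run exceeds
# split_gap_factor * max_time_gap_s; each piece is re-trimmed to valid ends.
split_ridge_at_gaps <- function(ridge, cfg, hop_s) {
  max_gap_frames <- ceiling(cfg$split_gap_factor * cfg$max_time_gap_s / hop_s)
  r <- rle(ridge$valid)
  if (!any(!r$values & r$lengths > max_gap_frames)) return(list(ridge))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  big <- which(!r$values & r$lengths > max_gap_frames)
  cut_points <- cbind(c(1L, ends[big] + 1L), c(starts[big] - 1L, length(ridge$valid)))
  pieces <- list()
  for (i in seq_len(nrow(cut_points))) {
    sel <- cut_points[i, 1]:cut_points[i, 2]
    v <- ridge$valid[sel]
    if (!any(v)) next
    sel <- sel[seq(which(v)[1], tail(which(v), 1))]
    pieces[[length(pieces) + 1L]] <- structure(
      lapply(unclass(ridge), function(f) f[sel]), class = "usv_ridge")
  }
  pieces
}

# Assemble a Call from a (possibly split) ridge; enforces the duration and
# pixel gates on the refined bounds.
build_call <- function(ridge, seg, spec, noise, cfg) {
  n_valid <- sum(ridge$valid)
  t_start <- ridge$times_s[1] - spec$window_s / 2
  t_end <- tail(ridge$times_s, 1) + spec$window_s / 2
  if ((t_end - t_start) < cfg$min_duration_s) return(NULL)
  refined <- seg
  refined$t_start_s <- t_start
  refined$t_end_s <- t_end
  refined$f_lo_hz <- min(ridge$freqs_hz[ridge$valid])
  refined$f_hi_hz <- max(ridge$freqs_hz[ridge$valid])
  conf <- detection_confidence(ridge, noise, cfg$snr_mid_db, cfg$snr_scale_db)
  structure(list(segment = refined, ridge = ridge, confidence_pct = conf,
                 call_id = NA_integer_, n_valid = n_valid),
            class = "usv_call")
}

#' Detection confidence from ridge SNR
#'
#' Confidence is a documented logistic map of the call's signal-to-noise
#' ratio: `s` is the median, over valid ridge frames, of ridge power minus the
#' per-bin noise median (dB), and
#' `confidence = 100 / (1 + exp(-(s - snr_mid_db) / snr_scale_db))`.
#' It is strictly increasing in `s`: more acoustic power relative to
#' background means greater call detection certainty.
#'
#' @param ridge a [extract_ridge()] result with at least one valid frame.
#' @param noise [estimate_background()] result.
#' @param snr_mid_db SNR giving 50% confidence.
#' @param snr_scale_db logistic scale (dB).
#' @return Confidence percent in `[0, 100]`.
#' @export
detection_confidence <- function(ridge, noise, snr_mid_db = 10, snr_scale_db = 3) {
  stopifnot(inherits(ridge, "usv_ridge"), any(ridge$valid))
  s <- median(ridge$powers_db[ridge$valid] - noise$median_db[ridge$bin_index[ridge$valid]])
  100 / (1 + exp(-(s - snr_mid_db) / snr_scale_db))
}

#' Partition calls by detection confidence
#'
#' Calls below `threshold_pct` are flagged for manual verification; order is
#' preserved and `kept` plus `flagged` is the input.
#'
#' @param calls list of `usv_call` objects.
#' @param threshold_pct confidence threshold in `[0, 100]`.
#' @return list with `kept` and `flagged`.
#' @export
filter_by_confidence <- function(calls, threshold_pct) {
  stopifnot(threshold_pct >= 0, threshold_pct <= 100)
  conf <- vapply(calls, function(cl) cl$confidence_pct, 0)
  list(kept = calls[conf >= threshold_pct], flagged = calls[conf < threshold_pct])
}
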