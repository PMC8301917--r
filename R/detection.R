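#' Detection configuration
#'
#' Numeric gates for [detect_calls()] and its stages. Defaults are calibrated
#' for stationary broadband noise: per-frequency-bin threshold at
#' `median + max(k_db, k_sigma * spread)` where spread is the scaled median
#' absolute deviation of the bin's dB values over time. For Gaussian noise the
#' per-pixel dB spread is ~5 dB, so `k_sigma = 2.5` places the threshold about
#' 12.4 dB above the per-bin median (noise-pixel tail probability ~6e-6);
#' isolated survivors are removed by the duration and pixel-count gates.
#'
#' @param k_db minimum dB offset above the per-bin median.
#' @param k_sigma multiplier on the per-bin robust spread; the effective
#'   offset is `max(k_db, k_sigma * spread)`.
#' @param connectivity 8 (default) or 4 for component labelling.
#' @param min_duration_s minimum candidate duration (s).
#' @param min_pixels minimum above-threshold pixels per candidate.
#' @param max_time_gap_s,max_freq_gap_hz gaps bridged by morphological
#'   closing before labelling, so briefly interrupted tonal tracks stay one
#'   component.
#' @param pad_s padding added to both ends of each candidate ("several
#'   milliseconds" to capture call onsets/offsets).
#' @param max_duration_s candidates longer than this are split at their widest
#'   internal silent gap.
#' @param split_gap_factor a within-call silent run longer than
#'   `split_gap_factor * max_time_gap_s` splits the call during isolation.
#' @param snr_mid_db,snr_scale_db logistic detection-confidence map: a call
#'   whose median ridge SNR equals `snr_mid_db` scores 50%.
#' @return A list of class `usv_detect_config`.
#' @export
detection_config <- function(k_db = 8, k_sigma = 2.5, connectivity = 8,
                             min_duration_s = 0.005, min_pixels = 12,
                             max_time_gap_s = 0.003, max_freq_gap_hz = 2000,
                             pad_s = 0.005, max_duration_s = 5,
                             split_gap_factor = 4,
                             snr_mid_db = 10, snr_scale_db = 3) {
  stopifnot(k_db > 0, k_sigma >= 0, connectivity %in% c(4, 8),
            min_duration_s >= 0, min_pixels >= 1, pad_s >= 0,
            max_duration_s > 0, split_gap_factor > 0, snr_scale_db > 0)
  structure(list(k_db = k_db, k_sigma = k_sigma, connectivity = connectivity,
                 min_duration_s = min_duration_s, min_pixels = min_pixels,
                 max_time_gap_s = max_time_gap_s,
                 max_freq_gap_hz = max_freq_gap_hz, pad_s = pad_s,
                 max_duration_s = max_duration_s,
                 split_gap_factor = split_gap_factor,
                 snr_mid_db = snr_mid_db, snr_scale_db = snr_scale_db),
            class = "usv_detect_config")
}

#' Estimate the per-bin background noise profile
#'
#' Most spectrogram pixels are background, and calls occupy a minority of
#' frames in any one bin, so the per-bin median and scaled median absolute
#' deviation over time estimate the noise level robustly. One sigma-clipping
#' iteration (pixels more than `clip_db` above the first-pass median are
#' excluded before the statistics are recomputed) keeps the estimate clean
#' even when strong calls cover a sizeable share of a bin's frames.
#'
#' @param spec a [compute_spectrogram()] result with at least 20 frames.
#' @param clip_db clipping offset for the refinement pass; `Inf` disables it.
#' @param max_frames long recordings are subsampled to about this many frames
#'   per bin before the order statistics are taken (a noise estimate from
#'   several thousand frames is statistically indistinguishable from one
#'   using every frame, at a fraction of the cost).
#' @return `usv_noise_profile`: `median_db`, `spread_db` (both length n_freq)
#'   and `band` (Hz).
#' @export
estimate_background <- function(spec, clip_db = 6, max_frames = 5000) {
  stopifnot(inherits(spec, "usv_spectrogram"))
  nt <- ncol(spec$power_db)
  if (nt < 20L)
    stop("insufficient data: background estimation needs at least 20 frames")
  decim <- max(1L, nt %/% as.integer(max_frames))
  P <- if (decim > 1L)
    spec$power_db[, seq(1L, nt, by = decim), drop = FALSE] else spec$power_db
  med <- matrixStats::rowMedians(P)
  spread <- matrixStats::rowMads(P)
  if (is.finite(clip_db)) {
    clipped <- P
    clipped[clipped > med + clip_db] <- NA_real_ # recycles down columns
    med2 <- matrixStats::rowMedians(clipped, na.rm = TRUE)
    spread2 <- matrixStats::rowMads(clipped, na.rm = TRUE)
    ok <- is.finite(med2) & is.finite(spread2)
    med[ok] <- med2[ok]
    spread[ok] <- spread2[ok]
  }
  structure(list(median_db = med, spread_db = spread,
                 band = range(spec$freqs_hz)),
            class = "usv_noise_profile")
}

#' Threshold a spectrogram against the noise profile
#'
#' A pixel is flagged when its power exceeds
#' `median_db(bin) + max(k_db, k_sigma * spread_db(bin))`.
#'
#' @param spec spectrogram.
#' @param noise [estimate_background()] result.
#' @param k_db,k_sigma threshold parameters (see [detection_config()]).
#' @return Logical matrix of the same shape as `spec$power_db`, with
#'   attributes `k_db`, `k_sigma` and `threshold_db` (per-bin threshold).
#' @export
threshold_mask <- function(spec, noise, k_db = 8, k_sigma = 2.5) {
  stopifnot(inherits(spec, "usv_spectrogram"), inherits(noise, "usv_noise_profile"),
            k_db > 0)
  thr <- noise$median_db + pmax(k_db, k_sigma * noise$spread_db)
  mask <- spec$power_db > thr # thr recycles down columns (per-bin rule)
  attr(mask, "k_db") <- k_db
  attr(mask, "k_sigma") <- k_sigma
  attr(mask, "threshold_db") <- thr
  mask
}

# Per-bin detection threshold (dB) used by both masking and ridge validation.
detection_threshold_db <- function(noise, cfg) {
  noise$median_db + pmax(cfg$k_db, cfg$k_sigma * noise$spread_db)
}

#' Extract candidate segments from a thresholded spectrogram
#'
#' Bridges small time/frequency gaps by morphological closing, labels
#' connected components (default 8-connectivity), discards components failing
#' the duration or pixel-count gates, and returns one bounding candidate
#' segment per surviving component. Components longer than
#' `cfg$max_duration_s` are split at their widest internal silent gap.
#'
#' @param mask logical matrix from [threshold_mask()].
#' @param spec the spectrogram the mask was computed from.
#' @param cfg a [detection_config()].
#' @return data.frame with columns `t_start_s`, `t_end_s`, `f_lo_hz`,
#'   `f_hi_hz`, `pixel_count`, `peak_db` (possibly zero rows).
#' @export
extract_components <- function(mask, spec, cfg = detection_config()) {
  stopifnot(identical(dim(mask), dim(spec$power_db)))
  df_hz <- spec$freqs_hz[2] - spec$freqs_hz[1]
  ht <- as.integer(ceiling(cfg$max_time_gap_s / spec$hop_s / 2))
  hf <- as.integer(ceiling(cfg$max_freq_gap_hz / df_hz / 2))
  closed <- close_mask_cpp(mask, hf, ht)
  labels <- label_components_cpp(closed, as.integer(cfg$connectivity))
  n <- attr(labels, "n")
  if (n == 0L) return(empty_segments())
  st <- component_stats_cpp(labels, mask, spec$power_db, n)
  segs <- data.frame(
    t_start_s = spec$times_s[st$col_min] - spec$window_s / 2,
    t_end_s = spec$times_s[st$col_max] + spec$window_s / 2,
    f_lo_hz = spec$freqs_hz[st$row_min] - df_hz / 2,
    f_hi_hz = spec$freqs_hz[st$row_max] + df_hz / 2,
    pixel_count = st$pixel_count,
    peak_db = st$peak_db)
  segs$.col_min <- st$col_min
  segs$.col_max <- st$col_max
  segs$.label <- seq_len(n)
  keep <- (segs$t_end_s - segs$t_start_s) >= cfg$min_duration_s &
    segs$pixel_count >= cfg$min_pixels
  segs <- segs[keep, , drop = FALSE]
  if (nrow(segs) == 0L) return(empty_segments())
  too_long <- which((segs$t_end_s - segs$t_start_s) > cfg$max_duration_s)
  if (length(too_long)) {
    pieces <- lapply(seq_len(nrow(segs)), function(i) {
      if (!(i %in% too_long)) return(segs[i, , drop = FALSE])
      split_long_segment(segs[i, , drop = FALSE], labels, spec, df_hz)
    })
    segs <- do.call(rbind, pieces)
  }
  segs <- segs[order(segs$t_start_s), , drop = FALSE]
  rownames(segs) <- NULL
  segs[, c("t_start_s", "t_end_s", "f_lo_hz", "f_hi_hz", "pixel_count", "peak_db")]
}

empty_segments <- function() {
  data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
             f_lo_hz = numeric(0), f_hi_hz = numeric(0),
             pixel_count = integer(0), peak_db = numeric(0))
}

# Split an over-long component at its widest internal all-silent column gap.
split_long_segment <- function(seg, labels, spec, df_hz) {
  cols <- seg$.col_min:seg$.col_max
  occupied <- colSums(labels[, cols, drop = FALSE] == seg$.label) > 0
  r <- rle(occupied)
  if (all(r$values)) return(seg[, , drop = FALSE])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- which(!r$values & starts > 1L & ends < length(cols))
  if (!length(gaps)) return(seg[, , drop = FALSE])
  g <- gaps[which.max(r$lengths[gaps])]
  cut_lo <- cols[ends[g - 1L]] # last occupied col before the gap
  cut_hi <- cols[starts[g + 1L]] # first occupied col after the gap
  left <- seg
  left$t_end_s <- spec$times_s[cut_lo] + spec$window_s / 2
  left$.col_max <- cut_lo
  right <- seg
  right$t_start_s <- spec$times_s[cut_hi] - spec$window_s / 2
  right$.col_min <- cut_hi
  out <- rbind(left, right)
  # re-split recursively if a half is still too long is rare; one level is
  # enough for the 5-s gate with realistic call trains
  out
}

#' Pad and coalesce candidate segments
#'
#' Extends every segment by `pad_s` on both ends (clipped to the recording
#' bounds), then merges any time-overlapping segments into one whose time
#' bounds are the union; frequency bounds are unioned, pixel counts summed.
#' Output is sorted by start time and pairwise non-overlapping.
#'
#' @param segs data.frame from [extract_components()].
#' @param pad_s padding in seconds (`>= 0`).
#' @param t_min,t_max clipping bounds (s).
#' @return data.frame with the same columns, sorted and disjoint.
#' @export
pad_and_coalesce <- function(segs, pad_s = 0.005, t_min = 0, t_max = Inf) {
  stopifnot(pad_s >= 0)
  if (nrow(segs) == 0L) return(segs)
  s <- pmax(segs$t_start_s - pad_s, t_min)
  e <- pmin(segs$t_end_s + pad_s, t_max)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  segs <- segs[o, , drop = FALSE]
  out <- segs[0, , drop = FALSE]
  cur <- segs[1, , drop = FALSE]
  cur$t_start_s <- s[1]; cur$t_end_s <- e[1]
  for (i in seq_len(nrow(segs))[-1]) {
    if (s[i] < cur$t_end_s) { # half-open intervals: touching is not overlap
      cur$t_end_s <- max(cur$t_end_s, e[i])
      cur$f_lo_hz <- min(cur$f_lo_hz, segs$f_lo_hz[i])
      cur$f_hi_hz <- max(cur$f_hi_hz, segs$f_hi_hz[i])
      cur$pixel_count <- cur$pixel_count + segs$pixel_count[i]
      cur$peak_db <- max(cur$peak_db, segs$peak_db[i])
    } else {
      out <- rbind(out, cur)
      cur <- segs[i, , drop = FALSE]
      cur$t_start_s <- s[i]; cur$t_end_s <- e[i]
    }
  }
  out <- rbind(out, cur)
  rownames(out) <- NULL
  out
}

#' Detect calls in a recording
#'
#' Full detection pipeline: spectrogram, background-noise profile, per-bin
#' thresholding, connected-component candidate extraction, padding and
#' coalescing, ridge-based isolation, and logistic detection confidence.
#'
#' @param rec a [usv_recording()].
#' @param cfg a [detection_config()].
#' @param spec_cfg a [spectrogram_config()].
#' @return `usv_detection`: list with `calls` (list of `usv_call`),
#'   `segments` (candidate segments), `noise`, `spectrogram`, `cfg`.
#' @export
detect_calls <- function(rec, cfg = detection_config(),
                         spec_cfg = spectrogram_config()) {
  spec <- compute_spectrogram(rec, spec_cfg)
  noise <- estimate_background(spec)
  mask <- threshold_mask(spec, noise, cfg$k_db, cfg$k_sigma)
  segs <- extract_components(mask, spec, cfg)
  dur_s <- rec_duration(rec)
  segs <- pad_and_coalesce(segs, cfg$pad_s, 0, dur_s)
  calls <- list()
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      ridge <- extract_ridge(spec, segs[i, ], noise, cfg)
      if (is.null(ridge)) next
      for (piece in split_ridge_at_gaps(ridge, cfg, spec$hop_s)) {
        call <- build_call(piece, segs[i, ], spec, noise, cfg)
        if (!is.null(call)) calls[[length(calls) + 1L]] <- call
      }
    }
  }
  calls <- calls[order(vapply(calls, function(cl) cl$segment$t_start_s, 0))]
  for (k in seq_along(calls)) calls[[k]]$call_id <- k
  structure(list(calls = calls, segments = segs, noise = noise,
                 spectrogram = spec, cfg = cfg),
            class = "usv_detection")
}

rec_duration <- function(rec) length(rec$samples) / rec$rate_hz

#' @export
print.usv_detection <- function(x, ...) {
  cat(sprintf("<usv_detection> %d calls from %d candidate segments\n",
              length(x$calls), nrow(x$segments)))
  invisible(x)
}

#' Export candidate segments as CSV
#'
#' Columns `start_s`, `end_s`, `f_lo_hz`, `f_hi_hz`, `peak_db`.
#'
#' @param segs data.frame from [extract_components()] / [pad_and_coalesce()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segs, path) {
  out <- data.frame(start_s = segs$t_start_s, end_s = segs$t_end_s,
                    f_lo_hz = segs$f_lo_hz, f_hi_hz = segs$f_hi_hz,
                    peak_db = segs$peak_db)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Call time intervals from a detection
#'
#' @param det a [detect_calls()] result.
#' @return data.frame `start_s`, `end_s`, `confidence_pct`, `call_id`.
#' @export
call_intervals <- function(det) {
  if (!length(det$calls))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      confidence_pct = numeric(0), call_id = integer(0)))
  data.frame(
    start_s = vapply(det$calls, function(cl) cl$segment$t_start_s, 0),
    end_s = vapply(det$calls, function(cl) cl$segment$t_end_s, 0),
    confidence_pct = vapply(det$calls, function(cl) cl$confidence_pct, 0),
    call_id = vapply(det$calls, function(cl) cl$call_id, 0L))
}
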