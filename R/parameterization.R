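#' Parameterization configuration
#'
#' @param jump_thresh_hz adjacent-sample frequency change counted as a jump
#'   and excluded from slope statistics (default 8 kHz).
#' @param gap_min_s minimal silent run inside a call counted as a gap.
#' @param slope_dt_s time step of the resampled ridge used for slope
#'   statistics. The DFT bin quantization (~1 kHz) makes per-hop differences
#'   degenerate, so slopes are measured over ~2 ms intervals on a sub-bin
#'   interpolated, median-smoothed ridge.
#' @param smooth_frames running-median length (frames) applied to the ridge
#'   before slope analysis; 1 disables smoothing.
#' @param sign_change_min_slope_hz_s slopes below this magnitude are treated
#'   as flat when counting slope sign changes.
#' @param subbin_interp use quadratic interpolation of the spectral peak for
#'   sub-bin ridge frequencies.
#' @return A list of class `usv_param_config`.
#' @export
parameter_config <- function(jump_thresh_hz = 8000, gap_min_s = 0.002,
                             slope_dt_s = 0.002, smooth_frames = 3,
                             sign_change_min_slope_hz_s = 2e5,
                             subbin_interp = TRUE) {
  stopifnot(jump_thresh_hz > 0, gap_min_s >= 0, slope_dt_s > 0,
            smooth_frames >= 1)
  structure(list(jump_thresh_hz = jump_thresh_hz, gap_min_s = gap_min_s,
                 slope_dt_s = slope_dt_s, smooth_frames = smooth_frames,
                 sign_change_min_slope_hz_s = sign_change_min_slope_hz_s,
                 subbin_interp = subbin_interp),
            class = "usv_param_config")
}

#' Acoustic parameter field names
#'
#' The fixed, documented order of the per-call acoustic parameter record
#' (the classifier contract and CSV payload). Units: seconds for durations,
#' Hz for frequencies, dB re full scale for powers, Hz/s for slopes.
#'
#' @return Character vector of 49 field names.
#' @export
call_parameter_fields <- function() {
  c("duration_s",
    "freq_max_hz", "freq_min_hz", "freq_median_hz", "freq_mean_hz",
    "freq_sd_hz", "freq_iqr_hz", "freq_range_hz", "freq_start_hz",
    "freq_end_hz",
    "freq_mean_first_hz", "freq_mean_middle_hz", "freq_mean_last_hz",
    "power_max_db", "freq_at_power_max_hz", "power_min_db",
    "power_median_ridge_db", "power_mean_ridge_db", "power_sd_ridge_db",
    paste0("slope_", rep(c("whole", "first", "middle", "last"), each = 5), "_",
           rep(c("max", "min", "median", "mean", "sd"), 4)),
    "n_jumps", "n_gaps", "gap_total_s", "gap_max_s",
    "slope_variability_hz_per_s", "n_slope_sign_changes", "slopes_defined",
    "n_valid_frames", "valid_fraction",
    "confidence_pct")
}

# Sub-bin ridge frequencies by quadratic (parabolic) interpolation of the
# spectral peak across the two neighbouring bins, in the dB domain.
interp_ridge_freqs <- function(ridge, spec) {
  rows <- ridge$bin_index
  cols <- ridge$col_index
  df <- spec$freqs_hz[2] - spec$freqs_hz[1]
  f <- spec$freqs_hz[rows]
  ok <- rows > 1L & rows < nrow(spec$power_db)
  if (any(ok)) {
    p0 <- spec$power_db[cbind(rows[ok] - 1L, cols[ok])]
    p1 <- spec$power_db[cbind(rows[ok], cols[ok])]
    p2 <- spec$power_db[cbind(rows[ok] + 1L, cols[ok])]
    den <- p0 - 2 * p1 + p2
    delta <- ifelse(den < 0, 0.5 * (p0 - p2) / den, 0)
    f[ok] <- f[ok] + pmax(pmin(delta, 0.5), -0.5) * df
  }
  f
}

stat5 <- function(x) {
  if (!length(x)) return(c(max = 0, min = 0, median = 0, mean = 0, sd = 0))
  c(max = max(x), min = min(x), median = median(x), mean = mean(x),
    sd = if (length(x) >= 2) sd(x) else 0)
}

#' Compute the acoustic parameter record of one call
#'
#' Frequency statistics are taken over valid ridge frames (sub-bin
#' interpolated, median-smoothed); power statistics along the maximal ridge;
#' slope statistics (max, min, median, mean, SD in Hz/s) for the whole call
#' and for its first, middle and last thirds (partitioned by valid-frame
#' index); jumps (adjacent frequency change above `jump_thresh_hz`, excluded
#' from slope statistics), silent gaps, slope variability (mean absolute
#' slope change) and slope sign changes, which separate trilled from flat and
#' ramped calls.
#'
#' @param call a `usv_call` from [detect_calls()].
#' @param spec the spectrogram the call was detected in.
#' @param cfg a [parameter_config()].
#' @return One-row data.frame with columns [call_parameter_fields()].
#' @export
parameterize <- function(call, spec, cfg = parameter_config()) {
  ridge <- call$ridge
  hop <- spec$hop_s
  v <- ridge$valid
  nv <- sum(v)
  out <- setNames(as.list(numeric(length(call_parameter_fields()))),
                  call_parameter_fields())

  seg <- call$segment
  out$duration_s <- seg$t_end_s - seg$t_start_s
  out$confidence_pct <- call$confidence_pct
  out$n_valid_frames <- nv
  out$valid_fraction <- nv / length(v)

  # gaps: maximal internal runs of invalid frames of at least gap_min_s
  r <- rle(v)
  gap_lens <- r$lengths[!r$values] * hop
  gap_lens <- gap_lens[gap_lens >= cfg$gap_min_s]
  out$n_gaps <- length(gap_lens)
  out$gap_total_s <- sum(gap_lens)
  out$gap_max_s <- if (length(gap_lens)) max(gap_lens) else 0

  f_all <- if (cfg$subbin_interp) interp_ridge_freqs(ridge, spec) else ridge$freqs_hz
  fs <- f_all[v]
  if (cfg$smooth_frames > 1L && nv >= 3L) {
    k <- min(cfg$smooth_frames, nv)
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L) fs <- as.numeric(stats::runmed(fs, k))
  }
  tv <- ridge$times_s[v]
  pw <- ridge$powers_db[v]

  out$freq_max_hz <- max(fs)
  out$freq_min_hz <- min(fs)
  out$freq_median_hz <- median(fs)
  out$freq_mean_hz <- mean(fs)
  out$freq_sd_hz <- if (nv >= 2) sd(fs) else 0
  out$freq_iqr_hz <- unname(diff(quantile(fs, c(0.25, 0.75))))
  out$freq_range_hz <- max(fs) - min(fs)
  out$freq_start_hz <- fs[1]
  out$freq_end_hz <- fs[nv]

  # thirds by valid-frame index; remainder goes to the first and middle blocks
  n1 <- ceiling(nv / 3)
  n3 <- floor(nv / 3)
  n2 <- nv - n1 - n3
  third <- rep(1:3, times = c(n1, n2, n3))
  out$freq_mean_first_hz <- mean(fs[third == 1])
  out$freq_mean_middle_hz <- if (n2 > 0) mean(fs[third == 2]) else mean(fs)
  out$freq_mean_last_hz <- if (n3 > 0) mean(fs[third == 3]) else mean(fs)

  out$power_max_db <- max(pw)
  out$power_min_db <- min(pw)
  out$power_median_ridge_db <- median(pw)
  out$power_mean_ridge_db <- mean(pw)
  out$power_sd_ridge_db <- if (nv >= 2) sd(pw) else 0
  out$freq_at_power_max_hz <- fs[which.max(pw)]

  # slopes on the ridge resampled to ~slope_dt_s
  m <- max(1L, as.integer(round(cfg$slope_dt_s / hop)))
  sel <- unique(c(seq(1L, nv, by = m), nv))
  out$slopes_defined <- as.numeric(length(sel) >= 2 && nv >= 2)
  if (out$slopes_defined > 0) {
    fd <- fs[sel]
    td <- tv[sel]
    dfq <- diff(fd)
    dts <- diff(td)
    jump <- abs(dfq) > cfg$jump_thresh_hz
    out$n_jumps <- sum(jump)
    slopes_all <- dfq / dts
    slopes <- slopes_all[!jump]
    pt_third <- third[sel] # third of the left endpoint of each slope interval
    sl_third <- pt_third[-length(pt_third)]
    sl_third <- sl_third[!jump]
    groups <- list(whole = slopes, first = slopes[sl_third == 1],
                   middle = slopes[sl_third == 2], last = slopes[sl_third == 3])
    for (g in names(groups)) {
      s5 <- stat5(groups[[g]])
      for (nm in names(s5)) out[[paste0("slope_", g, "_", nm)]] <- unname(s5[nm])
    }
    out$slope_variability_hz_per_s <- if (length(slopes) >= 2)
      mean(abs(diff(slopes))) else 0
    sg <- sign(slopes[abs(slopes) > cfg$sign_change_min_slope_hz_s])
    out$n_slope_sign_changes <- if (length(sg) >= 2) sum(diff(sg) != 0) else 0
  }
  as.data.frame(out[call_parameter_fields()])
}

#' Parameter table for a set of calls
#'
#' @param calls list of `usv_call` objects (or a `usv_detection`).
#' @param spec spectrogram (ignored when `calls` is a `usv_detection`).
#' @param cfg a [parameter_config()].
#' @return data.frame with `call_id` then [call_parameter_fields()], one row
#'   per call (zero rows for an empty call list).
#' @export
parameter_table <- function(calls, spec = NULL, cfg = parameter_config()) {
  if (inherits(calls, "usv_detection")) {
    spec <- calls$spectrogram
    calls <- calls$calls
  }
  hdr <- cbind(data.frame(call_id = integer(0)),
               as.data.frame(setNames(rep(list(numeric(0)),
                                          length(call_parameter_fields())),
                                      call_parameter_fields())))
  if (!length(calls)) return(hdr)
  rows <- lapply(calls, function(cl) {
    cbind(data.frame(call_id = cl$call_id), parameterize(cl, spec, cfg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
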