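#' Spectrogram configuration
#'
#' Frame geometry and analysis band for [compute_spectrogram()].
#'
#' Defaults target rat USV recordings sampled at 192--300 kHz: a ~1 ms Hann
#' window (256 samples at 250 kHz, ~977 Hz frequency resolution) with 75%
#' overlap, restricted to 15--100 kHz. The short window keeps fast trill
#' sweeps (up to ~2 MHz/s) within about one frequency bin per frame so trilled
#' calls stay as bright as flat calls.
#'
#' @param window_s analysis window length in seconds (must contain >= 32
#'   samples at the recording rate).
#' @param hop_fraction hop as a fraction of the window (default 0.25).
#' @param f_lo_hz,f_hi_hz analysis band in Hz.
#' @param db_floor floor applied to power values, dB re full-scale sine.
#' @return A list of class `usv_spec_config`.
#' @export
spectrogram_config <- function(window_s = 256 / 250000, hop_fraction = 0.25,
                               f_lo_hz = 15000, f_hi_hz = 100000,
                               db_floor = -120) {
  stopifnot(window_s > 0, hop_fraction > 0, hop_fraction <= 1,
            f_lo_hz > 0, f_hi_hz > f_lo_hz, db_floor < 0)
  structure(list(window_s = window_s, hop_fraction = hop_fraction,
                 f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz, db_floor = db_floor),
            class = "usv_spec_config")
}

#' Compute a dB power spectrogram
#'
#' Short-time Fourier transform with a periodic Hann window. Power is
#' expressed in dB relative to a full-scale sinusoid (a bin-centred sine of
#' amplitude 1 reads 0 dB) and floored at `cfg$db_floor`. Rows are restricted
#' to the analysis band `[f_lo_hz, f_hi_hz]`.
#'
#' @param rec a [usv_recording()].
#' @param cfg a [spectrogram_config()].
#' @return An object of class `usv_spectrogram` with fields `power_db`
#'   (n_freq x n_time matrix), `freqs_hz`, `times_s` (frame centres),
#'   `window_s`, `hop_s`, `rate_hz`, `n_samples`, `db_floor`.
#' @export
compute_spectrogram <- function(rec, cfg = spectrogram_config()) {
  stopifnot(inherits(rec, "usv_recording"))
  rate <- rec$rate_hz
  if (rate < 2 * cfg$f_hi_hz)
    stop(sprintf("sample rate %g Hz is below the Nyquist requirement %g Hz for f_hi = %g Hz",
                 rate, 2 * cfg$f_hi_hz, cfg$f_hi_hz))
  N <- as.integer(round(cfg$window_s * rate))
  if (N < 32L) stop("window too short: must contain at least 32 samples")
  n <- length(rec$samples)
  if (n < N) stop("recording shorter than one analysis window")
  hop <- max(1L, as.integer(round(N * cfg$hop_fraction)))
  n_frames <- 1L + (n - N) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop # 0-based sample offsets
  w <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N)) # periodic Hann
  wsum <- sum(w)
  freqs_full <- (0:(N %/% 2)) * rate / N
  rows <- which(freqs_full >= cfg$f_lo_hz & freqs_full <= cfg$f_hi_hz)
  if (length(rows) < 2L) stop("analysis band contains fewer than 2 frequency bins")
  amp_floor <- 10^(cfg$db_floor / 20)
  P <- matrix(0, length(rows), n_frames)
  chunk <- 4096L
  off <- seq_len(N)
  for (j0 in seq(1L, n_frames, by = chunk)) {
    j1 <- min(n_frames, j0 + chunk - 1L)
    idx <- outer(off, starts[j0:j1], "+")
    X <- stats::mvfft(matrix(rec$samples[idx], nrow = N) * w)
    A <- (2 / wsum) * Mod(X[rows, , drop = FALSE])
    P[, j0:j1] <- 20 * log10(pmax(A, amp_floor))
  }
  structure(list(power_db = P, freqs_hz = freqs_full[rows],
                 times_s = (starts + N / 2) / rate,
                 window_s = N / rate, hop_s = hop / rate,
                 rate_hz = rate, n_samples = n, db_floor = cfg$db_floor),
            class = "usv_spectrogram")
}

#' @export
print.usv_spectrogram <- function(x, ...) {
  cat(sprintf("<usv_spectrogram> %d bins x %d frames, %.1f-%.1f kHz, hop %.3f ms\n",
              nrow(x$power_db), ncol(x$power_db), min(x$freqs_hz) / 1e3,
              max(x$freqs_hz) / 1e3, x$hop_s * 1e3))
  invisible(x)
}
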