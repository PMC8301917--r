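# Shared fixtures, built in code at test time.

# Fake spectrogram with given power matrix (bins x frames), for unit tests of
# background estimation and thresholding that need exact pixel values.
fake_spectrogram <- function(power_db, f0 = 20000, df = 1000, hop_s = 0.001) {
  structure(list(power_db = power_db,
                 freqs_hz = f0 + (seq_len(nrow(power_db)) - 1) * df,
                 times_s = (seq_len(ncol(power_db)) - 0.5) * hop_s,
                 window_s = 2 * hop_s, hop_s = hop_s, rate_hz = 250000,
                 n_samples = NA_integer_, db_floor = -120),
            class = "usv_spectrogram")
}

fake_noise <- function(spec, median_db, spread_db = 0) {
  structure(list(median_db = rep_len(median_db, nrow(spec$power_db)),
                 spread_db = rep_len(spread_db, nrow(spec$power_db)),
                 band = range(spec$freqs_hz)),
            class = "usv_noise_profile")
}

# One-call recording in noise; returns the simulation plus its detection.
single_call_fixture <- function(type = "FixedFrequency50", snr_db = 20,
                                seed = 11, margin_s = 0.25, ...) {
  cs <- call_spec(type, onset_s = margin_s, amplitude = snr_to_amplitude(snr_db), ...)
  recipe <- synth_recipe(length_s = cs$duration_s + 2 * max(margin_s, 1.2 * cs$duration_s),
                         click_rate_per_min = 0, calls = list(cs), seed = seed)
  recipe$calls[[1]]$onset_s <- max(margin_s, 1.2 * cs$duration_s)
  sim <- synthesize_recording(recipe)
  det <- detect_calls(sim$recording)
  list(sim = sim, det = det, spec = det$spectrogram, cs = recipe$calls[[1]])
}

# Amplitude (relative to noise RMS) giving the requested spectrogram-domain
# SNR under the default 256-sample Hann geometry (tone calibration 17.9 dB).
snr_to_amplitude <- function(snr_db, n_window = 256) {
  10^((snr_db - 10 * log10(n_window / (6 * log(2)))) / 20)
}

first_call_params <- function(fx) {
  expect_gte(length(fx$det$calls), 1)
  parameterize(fx$det$calls[[1]], fx$spec)
}

# Brute-force interval merging oracle on sorted endpoints.
merge_intervals_oracle <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  out_s <- s[1]; out_e <- e[1]
  for (i in seq_along(s)[-1]) {
    k <- length(out_s)
    if (s[i] < out_e[k]) out_e[k] <- max(out_e[k], e[i])
    else { out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i]) }
  }
  data.frame(start = out_s, end = out_e)
}

# Exhaustive one-to-one assignment oracle: maximize matched-pair count, then
# total overlap, over all injective truth->predicted assignments.
best_assignment_oracle <- function(truth, predicted) {
  nt <- nrow(truth); np <- nrow(predicted)
  ov <- outer(seq_len(nt), seq_len(np), function(i, j)
    pmax(0, pmin(truth$end_s[i], predicted$end_s[j]) -
           pmax(truth$start_s[i], predicted$start_s[j])))
  best <- list(count = -1, total = -1)
  recurse <- function(i, used, count, total) {
    if (i > nt) {
      if (count > best$count || (count == best$count && total > best$total))
        best <<- list(count = count, total = total)
      return(invisible())
    }
    recurse(i + 1L, used, count, total) # leave truth i unmatched
    for (j in seq_len(np)) {
      if (!used[j] && ov[i, j] > 0) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L, total + ov[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L, 0)
  best
}

# Seeded evaluation without touching the caller's RNG stream.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
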