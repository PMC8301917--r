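#' Five-call composite labels
#'
#' The composite classification scheme: flat/short 50-kHz calls, ramped,
#' stepped and complex frequency-modulated 50-kHz calls, trilled 50-kHz
#' calls, and long (>= 300 ms) and short 22-kHz calls.
#'
#' @return Character vector of the five labels, in fixed order.
#' @export
composite_labels <- function() {
  c("FixedFrequency50", "FrequencyModulated50", "FrequencyModulatedTrill50",
    "Long22kHz", "Short22kHz")
}

#' Specify one synthetic call
#'
#' @param type one of [composite_labels()].
#' @param onset_s,duration_s placement in seconds. Type bounds: 22-kHz long
#'   `>= 0.3 s`, 22-kHz short `< 0.3 s`, 50-kHz types 0.01--0.3 s.
#' @param f0_hz centre/start frequency (22-kHz family 20--30 kHz, 50-kHz
#'   family 40--75 kHz).
#' @param fm_depth_hz,fm_rate_hz sinusoidal modulation (trills).
#' @param ramp_hz signed total frequency sweep (ramps, inverted-U, steps;
#'   `|ramp_hz| <= 2 kHz` for fixed-frequency calls).
#' @param step_count number of plateaus for step calls (`shape = "step"`).
#' @param gap_s silent gap inserted at each plateau boundary of a step call.
#' @param amplitude linear amplitude relative to the noise RMS.
#' @param shape FM subtype: `"ramp"`, `"step"` or `"inverted_u"` (FM 50-kHz
#'   calls only; other types fix their own shape).
#' @return A list of class `usv_call_spec`.
#' @export
call_spec <- function(type, onset_s, duration_s, f0_hz, fm_depth_hz = 0,
                      fm_rate_hz = 0, ramp_hz = 0, step_count = 0, gap_s = 0,
                      amplitude = 1, shape = "ramp") {
  type <- match.arg(type, composite_labels())
  if (type == "Long22kHz" && duration_s < 0.3)
    stop("recipe error: Long22kHz calls must last at least 0.3 s")
  if (type == "Short22kHz" && duration_s >= 0.3)
    stop("recipe error: Short22kHz calls must be shorter than 0.3 s")
  if (grepl("50$", type) && (duration_s < 0.01 || duration_s > 0.3))
    stop("recipe error: 50-kHz call durations must be in [0.01, 0.3] s")
  if (grepl("22kHz$", type) && (f0_hz < 20000 || f0_hz > 30000))
    stop("recipe error: 22-kHz family centre frequency must be in 20-30 kHz")
  if (grepl("50$", type) && (f0_hz < 40000 || f0_hz > 75000))
    stop("recipe error: 50-kHz family centre frequency must be in 40-75 kHz")
  if (type == "FixedFrequency50" && abs(ramp_hz) > 2000)
    stop("recipe error: fixed-frequency calls allow at most 2 kHz drift")
  if (type == "FrequencyModulated50" && shape == "ramp" && abs(ramp_hz) < 8000)
    stop("recipe error: frequency-modulated ramps sweep at least 8 kHz")
  if (type == "FrequencyModulatedTrill50" &&
      (fm_depth_hz < 3000 || fm_rate_hz < 30 || fm_rate_hz > 80))
    stop("recipe error: trills need depth >= 3 kHz and rate in 30-80 Hz")
  structure(list(type = type, onset_s = onset_s, duration_s = duration_s,
                 f0_hz = f0_hz, fm_depth_hz = fm_depth_hz,
                 fm_rate_hz = fm_rate_hz, ramp_hz = ramp_hz,
                 step_count = step_count, gap_s = gap_s,
                 amplitude = amplitude, shape = shape),
            class = "usv_call_spec")
}

#' Synthesize one call as an amplitude sequence
#'
#' Phase-continuous FM tone following the type's frequency law, with
#' raised-cosine onset/offset ramps. Step calls optionally include a silent
#' gap at each plateau boundary (kept inside the stated duration).
#'
#' @param spec a [call_spec()].
#' @param rate_hz sample rate.
#' @param edge_ramp_s raised-cosine edge ramp duration (clipped to a quarter
#'   of the call).
#' @return Numeric vector of `round(duration_s * rate_hz)` samples at the
#'   spec's amplitude.
#' @export
synthesize_call <- function(spec, rate_hz, edge_ramp_s = 0.002) {
  n <- round(spec$duration_s * rate_hz)
  t <- (seq_len(n) - 0.5) / rate_hz
  x01 <- t / spec$duration_s
  env <- rep(1, n)
  f <- switch(spec$type,
    FixedFrequency50 = spec$f0_hz + spec$ramp_hz * x01,
    Long22kHz = spec$f0_hz + spec$ramp_hz * x01,
    Short22kHz = spec$f0_hz + spec$ramp_hz * x01,
    FrequencyModulatedTrill50 =
      spec$f0_hz + spec$fm_depth_hz * sin(2 * pi * spec$fm_rate_hz * t),
    FrequencyModulated50 = switch(spec$shape,
      ramp = spec$f0_hz + spec$ramp_hz * x01,
      inverted_u = spec$f0_hz + spec$ramp_hz * (1 - (2 * x01 - 1)^2),
      step = {
        k <- max(2L, as.integer(spec$step_count))
        plateau <- pmin(floor(x01 * k), k - 1)
        fr <- spec$f0_hz + plateau * spec$ramp_hz / (k - 1)
        if (spec$gap_s > 0) {
          half <- spec$gap_s / 2
          bounds <- spec$duration_s * seq_len(k - 1) / k
          for (b in bounds) env[t > b - half & t < b + half] <- 0
        }
        fr
      },
      stop("recipe error: unknown FM shape ", spec$shape)),
    stop("recipe error: unknown call type"))
  ramp_n <- min(round(edge_ramp_s * rate_hz), floor(n / 4))
  if (ramp_n > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- env[seq_len(ramp_n)] * r
    env[n + 1 - seq_len(ramp_n)] <- env[n + 1 - seq_len(ramp_n)] * r
  }
  phase <- 2 * pi * cumsum(f) / rate_hz
  spec$amplitude * sin(phase) * env
}

#' Build a synthesis recipe
#'
#' @param rate_hz sample rate (>= twice the highest synthesized frequency).
#' @param length_s recording length in seconds.
#' @param noise_db white-noise RMS level in dB re full scale.
#' @param click_rate_per_min Poisson rate of 1-ms broadband transient clicks
#'   (cage-noise artefacts that plague USV detectors).
#' @param click_amplitude click RMS relative to noise RMS.
#' @param calls list of [call_spec()] objects fitting inside the recording.
#' @param seed RNG seed for noise and click placement.
#' @return A list of class `usv_recipe`.
#' @export
synth_recipe <- function(rate_hz = 250000, length_s, noise_db = -40,
                         click_rate_per_min = 10, click_amplitude = 10,
                         calls = list(), seed = 1) {
  for (cs in calls) {
    if (cs$onset_s < 0 || cs$onset_s + cs$duration_s > length_s)
      stop("recipe error: call does not fit inside [0, length_s)")
    f_top <- cs$f0_hz + abs(cs$ramp_hz) + cs$fm_depth_hz
    if (rate_hz < 2 * f_top)
      stop("recipe error: sample rate below Nyquist for synthesized call")
  }
  structure(list(rate_hz = rate_hz, length_s = length_s, noise_db = noise_db,
                 click_rate_per_min = click_rate_per_min,
                 click_amplitude = click_amplitude, calls = calls,
                 seed = as.integer(seed)),
            class = "usv_recipe")
}

#' Synthesize a recording with ground-truth annotations
#'
#' Seeded Gaussian background noise at `noise_db`, Poisson-placed 1-ms
#' broadband clicks, and the recipe's calls summed in at their specified
#' amplitudes (relative to the noise RMS). Identical seeds give bit-identical
#' audio.
#'
#' @param recipe a [synth_recipe()].
#' @return list with `recording` (a [usv_recording()]) and `annotations`
#'   (data.frame `start_s`, `end_s`, `label`, `snr_db`, `overlaps`), sorted by
#'   start time.
#' @export
synthesize_recording <- function(recipe) {
  stopifnot(inherits(recipe, "usv_recipe"))
  n <- round(recipe$length_s * recipe$rate_hz)
  sigma <- 10^(recipe$noise_db / 20)
  x <- with_seed(recipe$seed, {
    x <- rnorm(n, 0, sigma)
    n_clicks <- rpois(1, recipe$click_rate_per_min * recipe$length_s / 60)
    if (n_clicks > 0) {
      click_n <- round(0.001 * recipe$rate_hz)
      starts <- floor(runif(n_clicks, 0, n - click_n)) + 1
      for (s in starts) {
        idx <- s:(s + click_n - 1)
        x[idx] <- x[idx] + rnorm(click_n, 0, recipe$click_amplitude * sigma)
      }
    }
    x
  })
  for (cs in recipe$calls) {
    y <- synthesize_call(cs, recipe$rate_hz)
    i0 <- round(cs$onset_s * recipe$rate_hz)
    idx <- i0 + seq_along(y)
    x[idx] <- x[idx] + sigma * y
  }
  ann <- annotations_from_recipe(recipe)
  list(recording = usv_recording(x, recipe$rate_hz, "synthetic"),
       annotations = ann)
}

annotations_from_recipe <- function(recipe) {
  if (!length(recipe$calls)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0), snr_db = numeric(0),
                      overlaps = logical(0)))
  }
  ann <- data.frame(
    start_s = vapply(recipe$calls, function(cs) cs$onset_s, 0),
    end_s = vapply(recipe$calls, function(cs) cs$onset_s + cs$duration_s, 0),
    label = vapply(recipe$calls, function(cs) cs$type, ""),
    snr_db = vapply(recipe$calls, function(cs) {
      attr_snr <- attr(cs, "snr_db")
      if (is.null(attr_snr)) NA_real_ else attr_snr
    }, 0))
  ann <- ann[order(ann$start_s), , drop = FALSE]
  ann$overlaps <- c(FALSE, ann$start_s[-1] < head(ann$end_s, -1))
  rownames(ann) <- NULL
  ann
}

# Tone calibration: dB offset between 20*log10(amplitude/noise RMS) and the
# spectrogram-domain SNR (ridge power minus per-bin noise median) for the
# Hann window of n_window samples. Median per-bin noise power is
# ln(2) * 6 sigma^2 / N on the full-scale-sine dB scale.
snr_calibration_db <- function(n_window = 256) {
  10 * log10(n_window / (6 * log(2)))
}

# Draw one type-appropriate CallSpec (documented default spreads).
random_call_spec <- function(type, onset_s, snr_db, n_window = 256) {
  amplitude <- 10^((snr_db - snr_calibration_db(n_window)) / 20)
  cs <- switch(type,
    FixedFrequency50 = call_spec(type, onset_s, runif(1, 0.02, 0.15),
                                 f0_hz = runif(1, 45000, 65000),
                                 ramp_hz = runif(1, -1500, 1500),
                                 amplitude = amplitude),
    FrequencyModulated50 = {
      shape <- sample(c("ramp", "step", "inverted_u"), 1)
      sweep <- sample(c(-1, 1), 1) * runif(1, 8000, 18000)
      f0 <- if (sweep > 0) runif(1, 41000, 74000 - sweep) else
        runif(1, 41000 - sweep, 74000)
      call_spec(type, onset_s, runif(1, 0.03, 0.2), f0_hz = f0,
                ramp_hz = sweep, step_count = sample(2:3, 1),
                amplitude = amplitude, shape = shape)
    },
    FrequencyModulatedTrill50 = call_spec(type, onset_s,
                                          runif(1, 0.08, 0.25),
                                          f0_hz = runif(1, 50000, 65000),
                                          fm_depth_hz = runif(1, 3000, 6000),
                                          fm_rate_hz = runif(1, 30, 60),
                                          amplitude = amplitude),
    Long22kHz = call_spec(type, onset_s, runif(1, 0.35, 1.2),
                          f0_hz = runif(1, 22000, 27000),
                          ramp_hz = runif(1, -500, 500),
                          amplitude = amplitude),
    Short22kHz = call_spec(type, onset_s, runif(1, 0.05, 0.25),
                           f0_hz = runif(1, 22000, 27000),
                           ramp_hz = runif(1, -500, 500),
                           amplitude = amplitude),
    stop("unknown composite type: ", type))
  attr(cs, "snr_db") <- snr_db
  cs
}

#' Draw a random synthesis recipe
#'
#' Call types are drawn from `class_mix`, per-call parameters from documented
#' type-specific distributions, SNR uniformly from `snr_db_range`
#' (spectrogram-domain SNR: ridge power over the per-bin noise median), and
#' onsets uniformly without overlap with minimum spacing `min_spacing_s`.
#'
#' @param n_calls number of calls.
#' @param class_mix probabilities over [composite_labels()] (sums to 1).
#' @param snr_db_range two-element range of per-call SNR in dB.
#' @param length_s recording length.
#' @param seed RNG seed (also seeds the noise in [synthesize_recording()]).
#' @param rate_hz,noise_db,click_rate_per_min passed to [synth_recipe()].
#' @param min_spacing_s minimum silence between consecutive calls.
#' @return A [synth_recipe()].
#' @export
random_recipe <- function(n_calls, class_mix = rep(0.2, 5),
                          snr_db_range = c(15, 25), length_s = 60, seed = 1,
                          rate_hz = 250000, noise_db = -40,
                          click_rate_per_min = 10, min_spacing_s = 0.05) {
  stopifnot(length(class_mix) == 5, abs(sum(class_mix) - 1) < 1e-8,
            n_calls >= 0)
  calls <- with_seed(seed, {
    if (n_calls == 0) list() else {
      types <- sample(composite_labels(), n_calls, replace = TRUE,
                      prob = class_mix)
      snrs <- runif(n_calls, snr_db_range[1], snr_db_range[2])
      specs <- lapply(seq_len(n_calls), function(i)
        random_call_spec(types[i], onset_s = 0, snr_db = snrs[i]))
      durs <- vapply(specs, function(cs) cs$duration_s, 0)
      free <- length_s - sum(durs) - (n_calls + 1) * min_spacing_s
      if (free < 0)
        stop("infeasible density: calls plus spacing exceed the recording length")
      g <- runif(n_calls + 1)
      g <- g / sum(g) * free
      onset <- if (n_calls == 1) min_spacing_s + g[1] else
        min_spacing_s + g[1] +
          c(0, cumsum(durs[-n_calls] + min_spacing_s + g[2:n_calls]))
      for (i in seq_len(n_calls)) specs[[i]]$onset_s <- onset[i]
      specs
    }
  })
  synth_recipe(rate_hz = rate_hz, length_s = length_s, noise_db = noise_db,
               click_rate_per_min = click_rate_per_min, calls = calls,
               seed = seed)
}

#' Write / read ground-truth annotations as CSV
#'
#' Dialect shared with the evaluation tools: header `start_s,end_s,label`,
#' UTF-8, '.' decimal separator.
#'
#' @param annotations data.frame with `start_s`, `end_s`, `label`.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations[, c("start_s", "end_s", "label")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a recipe as YAML
#'
#' @param recipe a [synth_recipe()].
#' @param path file path.
#' @return `path` (write) or a [synth_recipe()] (read).
#' @export
write_recipe <- function(recipe, path) {
  lst <- unclass(recipe)
  lst$calls <- lapply(lst$calls, unclass)
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  lst <- yaml::read_yaml(path)
  calls <- lapply(lst$calls, function(cs) do.call(call_spec, cs))
  synth_recipe(rate_hz = lst$rate_hz, length_s = lst$length_s,
               noise_db = lst$noise_db,
               click_rate_per_min = lst$click_rate_per_min,
               click_amplitude = lst$click_amplitude,
               calls = calls, seed = lst$seed)
}
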