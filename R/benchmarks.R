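#' Detection benchmark on seeded synthetic recordings
#'
#' Generates `n_recordings` recordings with [random_recipe()] (uniform class
#' mix, SNR drawn from `snr_db_range`, broadband clicks at
#' `click_rate_per_min`), runs [detect_calls()] with the given configuration,
#' matches detections to ground truth by temporal overlap, and pools
#' Detected/Missed/False-Positive counts across recordings.
#'
#' @param n_recordings,length_s,calls_per_recording benchmark size.
#' @param snr_db_range per-call SNR range (dB over the per-bin noise median).
#' @param click_rate_per_min transient click rate.
#' @param seed master seed; each recording gets an independent derived seed.
#' @param cfg,spec_cfg detection and spectrogram configuration.
#' @param verbose print one line per recording.
#' @return list with pooled `sensitivity`, `precision`, counts, and a
#'   `per_recording` data.frame.
#' @export
detection_benchmark <- function(n_recordings = 20, length_s = 60,
                                calls_per_recording = 40,
                                snr_db_range = c(15, 25),
                                click_rate_per_min = 10, seed = 1,
                                cfg = detection_config(),
                                spec_cfg = spectrogram_config(),
                                verbose = FALSE) {
  seeds <- derive_seeds(seed, n_recordings)
  per <- vector("list", n_recordings)
  for (r in seq_len(n_recordings)) {
    recipe <- random_recipe(calls_per_recording, snr_db_range = snr_db_range,
                            length_s = length_s, seed = seeds[r],
                            click_rate_per_min = click_rate_per_min)
    sim <- synthesize_recording(recipe)
    det <- detect_calls(sim$recording, cfg, spec_cfg)
    m <- match_calls(sim$annotations, call_intervals(det), policy = "overlap")
    per[[r]] <- data.frame(recording = r, detected = m$detected,
                           missed = m$missed,
                           false_positive = m$false_positive)
    if (verbose)
      message(sprintf("recording %d/%d: detected %d missed %d fp %d",
                      r, n_recordings, m$detected, m$missed,
                      m$false_positive))
  }
  per <- do.call(rbind, per)
  detected <- sum(per$detected)
  missed <- sum(per$missed)
  fp <- sum(per$false_positive)
  list(sensitivity = detected / (detected + missed),
       precision = detected / (detected + fp),
       detected = detected, missed = missed, false_positive = fp,
       per_recording = per)
}

#' Generate parameterized, labeled synthetic calls
#'
#' Synthesizes `n_per_class` calls of each composite type, each in its own
#' short noise recording, runs the full detection pipeline, and parameterizes
#' the detected call overlapping the ground truth. Calls the detector misses
#' are dropped (counted in the `n_missed` attribute).
#'
#' @param n_per_class calls per composite class.
#' @param seed master seed.
#' @param snr_db_range per-call SNR range.
#' @param margin_s minimum silence before and after each call; margins grow
#'   with call duration so the call occupies well under half of the fixture
#'   recording (the noise estimator assumes most frames are background).
#' @param cfg,spec_cfg pipeline configuration.
#' @return data.frame: `label` plus [call_parameter_fields()].
#' @export
synthetic_call_parameters <- function(n_per_class = 500, seed = 1,
                                      snr_db_range = c(15, 25),
                                      margin_s = 0.12,
                                      cfg = detection_config(),
                                      spec_cfg = spectrogram_config()) {
  types <- rep(composite_labels(), each = n_per_class)
  n <- length(types)
  seeds <- derive_seeds(seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- with_seed(seeds[i], {
      snr <- runif(1, snr_db_range[1], snr_db_range[2])
      random_call_spec(types[i], onset_s = 0, snr_db = snr)
    })
    margin <- max(margin_s, 1.2 * cs$duration_s)
    cs$onset_s <- margin
    recipe <- synth_recipe(length_s = cs$duration_s + 2 * margin,
                           click_rate_per_min = 0, calls = list(cs),
                           seed = seeds[i])
    sim <- synthesize_recording(recipe)
    det <- detect_calls(sim$recording, cfg, spec_cfg)
    if (!length(det$calls)) next
    m <- match_calls(sim$annotations, call_intervals(det))
    if (m$detected == 0) next
    call <- det$calls[[m$pairs$predicted_index[1]]]
    rows[[i]] <- cbind(data.frame(label = types[i]),
                       parameterize(call, det$spectrogram))
  }
  missed <- sum(vapply(rows, is.null, TRUE))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "n_missed") <- missed
  out
}

#' Classification benchmark on synthetic calls
#'
#' Generates `n_per_class` parameterized calls per class (see
#' [synthetic_call_parameters()]), splits 70/30, selects features and tunes
#' the random forest on the training portion only, and reports held-out
#' accuracy, the per-class metrics table and Cohen's kappa against the
#' generating labels.
#'
#' @param n_per_class calls per composite class.
#' @param seed master seed (data, split, folds, forests).
#' @param test_fraction held-out fraction.
#' @param grid hyperparameter lattice.
#' @param snr_db_range per-call SNR range.
#' @param data optional precomputed [synthetic_call_parameters()] table.
#' @return list with `accuracy`, `metrics` ([metrics_table()]), `kappa`,
#'   `model`, `n_train`, `n_test`, `n_missed`.
#' @export
classification_benchmark <- function(n_per_class = 500, seed = 1,
                                     test_fraction = 0.3,
                                     grid = default_tuning_grid(),
                                     snr_db_range = c(15, 25), data = NULL) {
  if (is.null(data))
    data <- synthetic_call_parameters(n_per_class, seed = seed,
                                      snr_db_range = snr_db_range)
  sp <- split_train_test(data, test_fraction = test_fraction, seed = seed)
  model <- tune_and_train(sp$train, grid = grid, seed = seed)
  pred <- classify(model, sp$test)
  cc <- confusion_counts(sp$test$label, pred$label,
                         class_order = composite_labels())
  mt <- metrics_table(cc)
  list(accuracy = mean(pred$label == sp$test$label),
       metrics = mt,
       kappa = cohens_kappa(sp$test$label, pred$label,
                            class_order = composite_labels())$kappa,
       model = model, n_train = nrow(sp$train), n_test = nrow(sp$test),
       n_missed = attr(data, "n_missed"))
}
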