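test_that("background estimation is robust and matches sort-based oracles", {
  # constant spectrogram
  spec <- fake_spectrogram(matrix(-80, 12, 60))
  noise <- estimate_background(spec)
  expect_equal(noise$median_db, rep(-80, 12))
  expect_equal(noise$spread_db, rep(0, 12))

  # one bin elevated in 10% of frames: median equals the explicit sorted
  # median of the uncontaminated level
  P <- matrix(-90, 10, 200)
  P[4, 1:20] <- -60
  spec <- fake_spectrogram(P)
  noise <- estimate_background(spec, clip_db = Inf)
  oracle <- sort(P[4, ])[100:101]
  expect_equal(noise$median_db[4], mean(oracle))
  expect_equal(noise$median_db[4], -90)
  # and the clipping refinement agrees here
  expect_equal(estimate_background(spec)$median_db[4], -90)

  expect_error(estimate_background(fake_spectrogram(matrix(-80, 5, 10))),
               "insufficient")
})

test_that("background estimation recovers Gaussian dB noise parameters", {
  P <- matrix(with_seed_test(7, rnorm(40 * 2000, -90, 3)), 40, 2000)
  spec <- fake_spectrogram(P)
  for (clip in c(Inf, 6)) {
    noise <- estimate_background(spec, clip_db = clip)
    expect_true(all(abs(noise$median_db + 90) < 0.5))
    expect_true(all(abs(noise$spread_db - 3) < 0.5))
  }
})

test_that("threshold mask follows the per-bin rule and the noise tail", {
  floor_spec <- fake_spectrogram(matrix(-120, 8, 50))
  noise <- fake_noise(floor_spec, -120)
  expect_false(any(threshold_mask(floor_spec, noise)))

  # tone 20 dB above the floor with k_db = 8 is masked along its track
  P <- matrix(-90, 8, 50)
  P[5, ] <- -70
  spec <- fake_spectrogram(P)
  m <- threshold_mask(spec, fake_noise(spec, -90), k_db = 8)
  expect_true(all(m[5, ]))
  expect_false(any(m[-5, ]))

  # Gaussian-dB noise: masked fraction within 2x of the normal tail
  P <- matrix(with_seed_test(8, rnorm(50 * 4000, -90, 3)), 50, 4000)
  spec <- fake_spectrogram(P)
  noise <- estimate_background(spec, clip_db = Inf)
  m <- threshold_mask(spec, noise, k_db = 8, k_sigma = 2.5)
  p_analytic <- pnorm(8 / 3, lower.tail = FALSE) # k_db dominates: 2.5*3 < 8
  frac <- mean(m)
  expect_gt(frac, p_analytic / 2)
  expect_lt(frac, p_analytic * 2)
})

test_that("mask pixel count is monotone in k_db", {
  P <- matrix(with_seed_test(9, rnorm(30 * 500, -90, 4)), 30, 500)
  spec <- fake_spectrogram(P)
  noise <- estimate_background(spec, clip_db = Inf)
  counts <- vapply(c(14, 12, 10, 8, 6, 4, 2),
                   function(k) sum(threshold_mask(spec, noise, k_db = k,
                                                  k_sigma = 0.1)), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("component extraction finds synthetic calls and honours gaps", {
  empty <- matrix(FALSE, 10, 50)
  expect_equal(nrow(extract_components(empty, fake_spectrogram(matrix(-90, 10, 50)))), 0)

  # one 100-ms flat call at SNR 20
  fx <- single_call_fixture("FixedFrequency50", snr_db = 20, seed = 21,
                            duration_s = 0.1, f0_hz = 50000)
  truth <- fx$sim$annotations
  spec <- fx$spec
  noise <- estimate_background(spec)
  mask <- threshold_mask(spec, noise)
  segs <- extract_components(mask, spec)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$t_start_s - truth$start_s), 0.004)
  expect_lt(abs(segs$t_end_s - truth$end_s), 0.004)
  expect_true(segs$f_lo_hz < 50000 && segs$f_hi_hz > 50000)

  # two calls separated by 50 ms stay two components
  amp <- snr_to_amplitude(20)
  calls <- list(call_spec("FixedFrequency50", 0.2, 0.05, 50000, amplitude = amp),
                call_spec("FixedFrequency50", 0.3, 0.05, 50000, amplitude = amp))
  sim <- synthesize_recording(synth_recipe(length_s = 0.8, calls = calls,
                                           click_rate_per_min = 0, seed = 3))
  spec2 <- compute_spectrogram(sim$recording)
  noise2 <- estimate_background(spec2)
  segs2 <- extract_components(threshold_mask(spec2, noise2), spec2,
                              detection_config(max_time_gap_s = 0.005))
  expect_equal(nrow(segs2), 2)
})

test_that("padding and coalescing merge overlaps exactly and idempotently", {
  segs <- data.frame(t_start_s = c(0.10, 0.40), t_end_s = c(0.20, 0.50),
                     f_lo_hz = 40000, f_hi_hz = 60000, pixel_count = 10L,
                     peak_db = -50)
  expect_equal(pad_and_coalesce(segs, 0), segs)

  segs2 <- data.frame(t_start_s = c(0.10, 0.205), t_end_s = c(0.20, 0.30),
                      f_lo_hz = c(40000, 45000), f_hi_hz = c(60000, 65000),
                      pixel_count = c(10L, 12L), peak_db = c(-50, -40))
  out <- pad_and_coalesce(segs2, 0.005)
  expect_equal(nrow(out), 1)
  expect_equal(out$t_start_s, 0.095)
  expect_equal(out$t_end_s, 0.305)
  expect_equal(out$f_lo_hz, 40000)
  expect_equal(out$f_hi_hz, 65000)

  # 100 random segments vs the sorted-endpoint merging oracle
  s <- with_seed_test(10, runif(100, 0, 10))
  e <- s + with_seed_test(11, runif(100, 0.001, 0.5))
  rand <- data.frame(t_start_s = s, t_end_s = e, f_lo_hz = 40000,
                     f_hi_hz = 60000, pixel_count = 1L, peak_db = -50)
  merged <- pad_and_coalesce(rand, 0.002)
  oracle <- merge_intervals_oracle(pmax(s - 0.002, 0), e + 0.002)
  expect_equal(merged$t_start_s, oracle$start)
  expect_equal(merged$t_end_s, oracle$end)
  expect_true(all(merged$t_start_s[-1] >= head(merged$t_end_s, -1)))
  # idempotent: a second pass with zero padding changes nothing
  expect_equal(pad_and_coalesce(merged, 0), merged)
})

test_that("detection on clean fixtures recalls every call with few false alarms", {
  recipe <- random_recipe(8, length_s = 10, seed = 5)
  sim <- synthesize_recording(recipe)
  det <- detect_calls(sim$recording)
  m <- match_calls(sim$annotations, call_intervals(det))
  expect_equal(detection_sensitivity(m), 1.0)
  expect_setequal(m$pairs$truth_index, 1:8) # every truth call matched once

  # pure noise with clicks: candidate rate stays under 5 per minute
  noise_sim <- synthesize_recording(synth_recipe(length_s = 30,
                                                 click_rate_per_min = 10,
                                                 calls = list(), seed = 99))
  det0 <- detect_calls(noise_sim$recording)
  expect_lte(length(det0$calls), 2)
})
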