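test_that("call matching handles identity, empties and crafted overlaps", {
  truth <- data.frame(start_s = c(0.1, 0.5, 1.0), end_s = c(0.2, 0.6, 1.1))
  m <- match_calls(truth, truth)
  expect_equal(m$detected, 3)
  expect_equal(m$missed, 0)
  expect_equal(m$false_positive, 0)

  m0 <- match_calls(truth, truth[0, ])
  expect_equal(m0$missed, 3)
  expect_equal(m0$detected, 0)

  expect_error(match_calls(data.frame(start_s = 1, end_s = 1), truth),
               "malformed")

  # 6 truth vs 7 predicted with partial overlaps: greedy matching equals the
  # exhaustive maximum-assignment oracle on this instance
  truth6 <- data.frame(start_s = c(0.0, 0.3, 0.6, 1.0, 1.5, 2.0),
                       end_s = c(0.1, 0.45, 0.75, 1.2, 1.6, 2.3))
  pred7 <- data.frame(start_s = c(0.05, 0.28, 0.42, 0.7, 1.15, 1.52, 2.25),
                      end_s = c(0.12, 0.41, 0.5, 0.8, 1.25, 1.62, 2.4))
  m67 <- match_calls(truth6, pred7)
  oracle <- best_assignment_oracle(truth6, pred7)
  expect_equal(m67$detected, oracle$count)
  expect_equal(m67$detected + m67$missed, 6)
  expect_equal(m67$detected + m67$false_positive, 7)
  expect_false(any(duplicated(m67$pairs$truth_index)))
  expect_false(any(duplicated(m67$pairs$predicted_index)))
})

test_that("matching conservation holds on random interval sets", {
  for (seed in 1:5) {
    nt <- 10 + seed
    np <- 14 - seed
    truth <- with_seed_test(seed, {
      s <- sort(runif(nt, 0, 10)); data.frame(start_s = s, end_s = s + runif(nt, 0.01, 0.4))
    })
    pred <- with_seed_test(seed + 100, {
      s <- sort(runif(np, 0, 10)); data.frame(start_s = s, end_s = s + runif(np, 0.01, 0.4))
    })
    for (policy in c("overlap", "midpoint")) {
      m <- match_calls(truth, pred, policy = policy)
      expect_equal(m$detected + m$missed, nt)
      expect_equal(m$detected + m$false_positive, np)
      expect_false(any(duplicated(m$pairs$truth_index)))
      expect_false(any(duplicated(m$pairs$predicted_index)))
    }
  }
})

test_that("sensitivity and precision match their defining formulas", {
  mk <- function(d, mi, fp) structure(list(detected = d, missed = mi,
                                           false_positive = fp),
                                      class = "usv_match")
  expect_equal(detection_sensitivity(mk(10, 0, 0)), 1.0)
  expect_equal(detection_sensitivity(mk(3, 1, 5)), 0.75)
  expect_equal(detection_precision(mk(10, 2, 0)), 1.0)
  expect_equal(detection_precision(mk(1, 0, 3)), 0.25)
  expect_error(detection_sensitivity(mk(0, 0, 4)), "undefined")
  expect_error(detection_precision(mk(0, 3, 0)), "undefined")
  for (seed in 1:10) {
    v <- with_seed_test(seed, sample(0:30, 3, replace = TRUE)) + c(1, 0, 0)
    m <- mk(v[1], v[2], v[3])
    expect_equal(detection_sensitivity(m), v[1] / (v[1] + v[2]))
    expect_equal(detection_precision(m), v[1] / (v[1] + v[3]))
  }
})

test_that("confusion counts agree with a pairwise-counting oracle", {
  cls <- composite_labels()
  cc0 <- confusion_counts(cls, cls, cls)
  expect_true(all(cc0$fp == 0) && all(cc0$fn == 0))

  cc1 <- confusion_counts("A", "B", c("A", "B", "C"))
  expect_equal(unname(cc1$fn["A"]), 1)
  expect_equal(unname(cc1$fp["B"]), 1)
  expect_equal(unname(cc1$tn["C"]), 1)

  expect_error(confusion_counts("A", "Z", c("A", "B")), "outside")

  for (seed in 1:5) {
    n <- 150
    truth <- with_seed_test(seed, sample(cls, n, replace = TRUE))
    pred <- with_seed_test(seed + 50, sample(cls, n, replace = TRUE))
    cc <- confusion_counts(truth, pred, cls)
    for (k in cls) {
      expect_equal(unname(cc$tp[k]), sum(truth == k & pred == k))
      expect_equal(unname(cc$fp[k]), sum(truth != k & pred == k))
      expect_equal(unname(cc$fn[k]), sum(truth == k & pred != k))
      expect_equal(unname(cc$tn[k]), sum(truth != k & pred != k))
      expect_equal(unname(cc$tp[k] + cc$tn[k] + cc$fp[k] + cc$fn[k]), n)
    }
  }
})

test_that("metrics tables reproduce printed F1 arithmetic and brute force", {
  # harmonic-mean checks at the printed precision
  expect_equal(round(f1_score(0.77, 0.69), 2), 0.73)
  expect_equal(round(f1_score(0.92, 0.87), 2), 0.89)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)

  cls <- composite_labels()
  for (seed in 1:5) {
    n <- with_seed_test(seed, sample(20:200, 1))
    truth <- with_seed_test(seed + 10, sample(cls, n, replace = TRUE))
    pred <- with_seed_test(seed + 20, sample(cls, n, replace = TRUE))
    mt <- metrics_table(confusion_counts(truth, pred, cls))
    # brute-force recount
    for (i in seq_along(cls)) {
      k <- cls[i]
      tp <- sum(truth == k & pred == k)
      fp <- sum(truth != k & pred == k)
      fn <- sum(truth == k & pred != k)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      expect_equal(mt$per_class$precision[i], prec)
      expect_equal(mt$per_class$recall[i], rec)
      expect_equal(mt$per_class$f1[i],
                   if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
      expect_equal(mt$per_class$support[i], sum(truth == k))
    }
    expect_equal(sum(mt$per_class$support), n)
    expect_equal(mt$overall$accuracy, mean(truth == pred))
    expect_equal(mt$overall$total_support, n)
  }
})

test_that("Cohen's kappa honours its identity and independence limits", {
  x <- rep(composite_labels(), 10)
  expect_equal(cohens_kappa(x, x)$kappa, 1.0)

  # 2x2 confusion [[20, 5], [10, 15]]: p_o = 0.70, p_e = 0.50, kappa = 0.40
  a <- c(rep("P", 25), rep("N", 25))
  b <- c(rep("P", 20), rep("N", 5), rep("P", 10), rep("N", 15))
  k <- cohens_kappa(a, b, c("P", "N"))
  expect_equal(k$p_o, 0.70)
  expect_equal(k$p_e, 0.50)
  expect_equal(k$kappa, 0.40)

  # independent random labelings: kappa near 0
  la <- with_seed_test(1, sample(composite_labels(), 10000, replace = TRUE))
  lb <- with_seed_test(2, sample(composite_labels(), 10000, replace = TRUE))
  expect_lt(abs(cohens_kappa(la, lb)$kappa), 0.05)

  # kappa <= 1 and equals 1 only for identical sequences
  for (seed in 1:5) {
    la <- with_seed_test(seed + 5, sample(c("x", "y", "z"), 60, replace = TRUE))
    lb <- with_seed_test(seed + 55, sample(c("x", "y", "z"), 60, replace = TRUE))
    kk <- cohens_kappa(la, lb)$kappa
    expect_lte(kk, 1)
    if (!identical(la, lb)) expect_lt(kk, 1)
  }
  expect_equal(cohens_kappa(rep("q", 5), rep("q", 5))$kappa, 1)
})

test_that("two-proportion test matches the pooled-z oracle and is symmetric", {
  expect_equal(compare_proportions(30, 100, 15, 50), 1.0)
  p <- (90 + 50) / 200
  z <- (0.9 - 0.5) / sqrt(p * (1 - p) * (1 / 100 + 1 / 100))
  expect_equal(compare_proportions(90, 100, 50, 100), 2 * pnorm(-abs(z)))
  expect_equal(compare_proportions(90, 100, 50, 100),
               compare_proportions(50, 100, 90, 100))
  expect_error(compare_proportions(1, 0, 1, 10))
})

test_that("metrics and segment CSV exports carry the documented columns", {
  cls <- composite_labels()
  truth <- rep(cls, times = c(4, 3, 2, 2, 1))
  pred <- truth
  pred[1] <- cls[2]
  mt <- metrics_table(confusion_counts(truth, pred, cls))
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(mt, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(names(back), c("class", "precision", "recall", "f1", "support"))
  expect_equal(back$class, c(cls, "Overall"))
  expect_equal(back$support, c(4, 3, 2, 2, 1, 12))
  expect_equal(back$f1[6], round(11 / 12, 2))

  segs <- data.frame(t_start_s = c(0.1, 0.5), t_end_s = c(0.2, 0.7),
                     f_lo_hz = c(40000, 22000), f_hi_hz = c(60000, 26000),
                     pixel_count = c(30L, 40L), peak_db = c(-40, -45))
  write_segments_csv(segs, f)
  seg_back <- read.csv(f)
  expect_equal(names(seg_back), c("start_s", "end_s", "f_lo_hz", "f_hi_hz", "peak_db"))
  expect_equal(seg_back$start_s, c(0.1, 0.5))
})
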