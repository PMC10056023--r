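test_that("segmentation produces fixed 1000-sample windows, remainder dropped", {
  r <- clean_record(hr = 72, seed = 4, duration = 180, noise_sd = 0.03)
  ws <- segment_windows(r$record, 10)
  expect_length(ws, 18L)
  expect_true(all(vapply(ws, function(w) length(w$samples), integer(1)) == 1000L))
  short <- r$record
  short$samples <- short$samples[1:900]
  expect_warning(empty <- segment_windows(short, 10), "shorter")
  expect_length(empty, 0L)
})

test_that("fiducials on clean healthy beats match generator ground truth", {
  r <- clean_record(hr = 75, seed = 3, duration = 20)
  x <- r$record$samples[1:1000]
  fids <- detect_fiducials(x, fs = 100, fid_smooth = 1)
  expect_gt(length(fids), 8L)
  gt <- r$ground_truth
  for (f in fids) {
    expect_false(f$notch_missing)
    near <- function(idx, gt_idx) min(abs(stats::na.omit(gt_idx) - idx))
    expect_lte(near(f$systolic_idx, gt$systolic_idx), 2)
    expect_lte(near(f$notch_idx, gt$notch_idx), 2)
    expect_lte(near(f$dicrotic_idx, gt$dicrotic_idx), 2)
    expect_true(f$trough_idx < f$systolic_idx &&
                f$systolic_idx < f$notch_idx &&
                f$notch_idx < f$dicrotic_idx)
  }
})

test_that("beats without a dicrotic wave are flagged missing, never fabricated", {
  tpl <- beat_template(dicrotic_present = FALSE)
  p <- subject_profile("S2", "hypertensive", 76, template = tpl,
                       noise_sd = 0, drift_amp = 0, rng_seed = 12)
  r <- generate_record(p, 20, 100)
  fids <- detect_fiducials(r$record$samples[1:1000], fs = 100)
  expect_gt(length(fids), 5L)
  expect_true(all(vapply(fids, function(f) f$notch_missing, logical(1))))
  expect_true(all(vapply(fids, function(f) f$dicrotic_missing, logical(1))))
  # a monotonic ramp has no beats at all
  expect_length(detect_fiducials(seq(0, 1, length.out = 1000), fs = 100),
                0L)
})

test_that("feature arithmetic is exact on programmed fiducials", {
  mk_fid <- function(trough, sys, notch, dic, next_tr, tr_amp, sys_amp,
                     notch_amp, dic_amp) {
    structure(list(trough_idx = trough, trough_amp = tr_amp,
                   trough_next_idx = next_tr, systolic_idx = sys,
                   systolic_amp = sys_amp, notch_idx = notch,
                   notch_amp = notch_amp, dicrotic_idx = dic,
                   dicrotic_amp = dic_amp, notch_missing = FALSE,
                   dicrotic_missing = FALSE), class = "beat_fiducials")
  }
  # two identical beats, x = 2, y = 1, z = 0.6, 100 Hz
  fids <- list(
    mk_fid(1L, 21L, 41L, 51L, 101L, 0, 2, 0.6, 1),
    mk_fid(101L, 121L, 141L, 151L, 201L, 0, 2, 0.6, 1),
    mk_fid(201L, 221L, 241L, 251L, 301L, 0, 2, 0.6, 1))
  win <- sin(2 * pi * 1.2 * seq(0, 9.99, by = 0.01))  # content for fft/entropy
  f <- extract_features(win, fiducials = fids, fs = 100)
  expect_false(is_discarded(f))
  expect_length(f, 20L)
  expect_equal(unname(f["y_over_x"]), 0.5)
  expect_equal(unname(f["xy_over_x"]), 0.5)
  expect_equal(unname(f["x"]), 2)
  expect_equal(unname(f["t1"]), 0.20)
  expect_equal(unname(f["t2"]), 0.40)
  expect_equal(unname(f["t3"]), 0.50)
  expect_equal(unname(f["t4"]), 1.00)
  expect_equal(unname(f["tpp"]), 1.00)
  expect_equal(unname(f["dT"]), 0.30)
  expect_equal(unname(f["t1_over_tpp"]), 0.20)
  expect_equal(unname(f["dT_over_tpp"]), 0.30)
})

test_that("durations match generator ground truth on a clean 60 bpm record", {
  # the generator oracle is exact on the clean signal, so features are
  # extracted from a raw (unfiltered) window here
  r <- clean_record(hr = 60, seed = 7, duration = 30, jitter = 0)
  w <- r$record$samples[1001:2000]
  f <- extract_features(w, fiducials = detect_fiducials(w, fs = 100,
                                                        fid_smooth = 1),
                        fs = 100)
  expect_false(is_discarded(f))
  expect_lte(abs(f[["tpp"]] - 1.00), 0.01 + 1e-9)
  expect_lte(abs(f[["t4"]] - 1.00), 0.02 + 1e-9)
  # generator's landmark spacing (realised trough to peak), within
  # 2 samples
  gt <- r$ground_truth
  k <- 3L  # a beat with a preceding realised trough
  tr_prev <- max(gt$trough_idx[gt$trough_idx < gt$systolic_idx[k]])
  t1_gt <- (gt$systolic_idx[k] - tr_prev) / 100
  t3_gt <- (gt$dicrotic_idx[k] - tr_prev) / 100
  dT_gt <- (gt$dicrotic_idx[k] - gt$systolic_idx[k]) / 100
  expect_lte(abs(f[["t1"]] - t1_gt), 0.02)
  expect_lte(abs(f[["t3"]] - t3_gt), 0.02)
  expect_lte(abs(f[["dT"]] - dT_gt), 0.02)
})

test_that("windows with too few complete beats are discarded with a reason", {
  tpl <- beat_template(dicrotic_present = FALSE)
  p <- subject_profile("S2", "hypertensive", 76, template = tpl,
                       noise_sd = 0.03, rng_seed = 12)
  r <- generate_record(p, 30, 100)
  w <- segment_windows(preprocess_record(r$record), 10)[[2L]]
  f <- extract_features(w)
  expect_true(is_discarded(f))
  expect_match(discard_reason(f), "missing_notch|missing_dicrotic")
})

test_that("fft peaks recover programmed tones within one bin", {
  fs <- 100; t <- seq(0, 9.99, by = 1 / fs)
  x <- 3 * sin(2 * pi * 1.2 * t) + 2 * sin(2 * pi * 2.4 * t) +
    1 * sin(2 * pi * 3.6 * t)
  pk <- fft_peaks(x, fs)
  bin <- fs / length(t)
  expect_lte(abs(pk[["Fre1"]] - 1.2), bin + 1e-9)
  expect_lte(abs(pk[["Fre2"]] - 2.4), bin + 1e-9)
  expect_lte(abs(pk[["Fre3"]] - 3.6), bin + 1e-9)
  # single tone: only the first peak is defined
  pk1 <- fft_peaks(sin(2 * pi * 2 * t), fs)
  expect_lte(abs(pk1[["Fre1"]] - 2), bin + 1e-9)
  expect_true(is.na(pk1[["Fre2"]]) || pk1[["Fre2"]] != pk1[["Fre1"]])
  # clean 75 bpm beat train: fundamental at 1.25 Hz
  r <- clean_record(hr = 75, seed = 2, duration = 10, jitter = 0)
  pk2 <- fft_peaks(r$record$samples[1:1000], fs)
  expect_lte(abs(pk2[["Fre1"]] - 1.25), bin + 1e-9)
  expect_error(fft_peaks(rnorm(100), fs), "256")
})

test_that("entropies match closed forms and a brute-force oracle", {
  # equal mass in all 16 bins -> 4 bits exactly
  x <- rep(seq(0.5, 15.5, by = 1) / 16, times = 10)
  e <- entropy_features(x)
  expect_equal(unname(e["e1"]), 4)
  # constant window: amplitude entropy 0, spectral entropy undefined
  expect_warning(e0 <- entropy_features(rep(2, 100)), "constant")
  expect_equal(unname(e0["e1"]), 0)
  expect_true(is.na(e0["e2"]))
  # arbitrary seeded window vs an independent direct-sum oracle
  set.seed(99)
  w <- rnorm(1000)
  e <- entropy_features(w, n_bins = 16)
  cnt <- table(cut(w, breaks = seq(min(w), max(w), length.out = 17),
                   include.lowest = TRUE))
  p <- as.numeric(cnt) / sum(cnt); p <- p[p > 0]
  expect_equal(unname(e["e1"]), -sum(p * log2(p)), tolerance = 1e-9)
  psd <- Mod(stats::fft(w - mean(w))[2:500])^2
  q <- psd / sum(psd)
  expect_equal(unname(e["e2"]), -sum(q * log2(q)), tolerance = 1e-9)
  # bounds
  expect_gte(e[["e1"]], 0); expect_lte(e[["e1"]], 4)
})

test_that("feature vectors have 20 finite values and are scale covariant", {
  r <- clean_record(hr = 72, seed = 4, duration = 40, noise_sd = 0.02)
  pp <- preprocess_record(r$record)
  w <- segment_windows(pp, 10)[[2L]]
  f1 <- extract_features(w)
  expect_length(f1, 20L)
  expect_identical(names(f1), ppg_feature_names())
  expect_true(all(is.finite(f1)))
  f2 <- extract_features(3 * w$samples, fs = 100)
  scale_feats <- c("x", "y", "z")
  invariant <- setdiff(ppg_feature_names(), c(scale_feats, "e1", "e2"))
  expect_equal(unname(f2[scale_feats]), unname(3 * f1[scale_feats]),
               tolerance = 1e-6)
  expect_equal(unname(f2[invariant]), unname(f1[invariant]),
               tolerance = 1e-6)
  # ratio invariants
  expect_true(f1[["y_over_x"]] >= 0 && f1[["y_over_x"]] <= 1)
  expect_equal(f1[["y_over_x"]] + f1[["xy_over_x"]], 1, tolerance = 1e-12)
  ratios <- f1[c("t1_over_tpp", "t2_over_tpp", "t3_over_tpp", "dT_over_tpp")]
  expect_true(all(ratios > 0 & ratios < 1))
})

test_that("raising the dicrotic-absence probability never lowers the discard rate", {
  rates <- vapply(c(0, 0.5, 1), function(pa) {
    co <- generate_cohort(2, 1, 60, seed = 21, p_dicrotic_absent = pa)
    ft <- build_feature_table(co)
    nrow(ft$discards) / (nrow(ft$discards) + NROW(ft$features))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("heart-rate estimation is within 2% of the programmed rate", {
  # exact case
  r <- clean_record(hr = 75, seed = 5, duration = 30, jitter = 0)
  expect_lte(abs(estimate_heart_rate(r$record) - 75), 0.5)
  # default-noise records across rates
  for (hr in c(60, 72, 90)) {
    p <- subject_profile("S", "healthy", hr, noise_sd = 0.03,
                         drift_amp = 0.3, rng_seed = hr + 1)
    rec <- generate_record(p, 60, 100)$record
    expect_lte(abs(estimate_heart_rate(rec) - hr) / hr, 0.02)
  }
  empty <- clean_record()$record
  empty$samples <- rep(0.5, 400)
  expect_warning(hr <- estimate_heart_rate(empty), "fewer than 3")
  expect_true(is.na(hr))
})

test_that("the cohort feature table keeps both classes and logs discards", {
  ft <- fixture("feature_table", function() build_feature_table(std_cohort()))
  expect_true(all(ppg_feature_names() %in% names(ft$features)))
  expect_setequal(unique(ft$features$label), c("healthy", "hypertensive"))
  expect_gt(nrow(ft$discards), 0L)
  expect_true(all(ft$discards$reason %in%
    c("no_beats", "missing_notch", "missing_dicrotic",
      "too_few_complete_beats")))
})
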