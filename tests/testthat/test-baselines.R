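test_that("R-peak detection respects the refractory contract and edge cases", {
  rec <- make_clean_record(hr = 90, dur = 30, fs = 256, seed = 4)
  pk <- detect_rpeaks(rec)
  expect_true(all(diff(pk) > 0))
  expect_true(all(diff(pk) >= 0.2 * 256))
  expect_lt(abs(length(pk) - 45), 3)

  expect_warning(out <- detect_rpeaks(rep(0, 1000), fs = 128), "no detectable")
  expect_length(out, 0)
  expect_error(detect_rpeaks(stats::rnorm(100), fs = 128), "2 s")
  expect_error(detect_rpeaks(stats::rnorm(1000), fs = 32), "64")
})

test_that("HRV time-domain features match hand-computed closed forms", {
  fs <- 1000
  # constant RR of 1000 ms
  pk <- seq(1, by = 1000, length.out = 10)
  f <- hrv_features(pk, fs)
  expect_equal(f$HR, 60)
  expect_equal(f$AVNN, 1000)
  expect_equal(f$SDNN, 0)
  expect_equal(f$RMSSD, 0)
  expect_equal(f$pNN50, 0)
  expect_true(is.na(f$TP))  # 9 s span: frequency features missing, not zero

  # RR = 1000, 1050, 1000 -> RMSSD = sqrt((50^2 + 50^2)/2) = 50
  pk2 <- cumsum(c(1, 1000, 1050, 1000))
  expect_equal(hrv_features(pk2, fs)$RMSSD, 50, tolerance = 1e-9)

  # successive differences 30, 60 -> pNN50 = 0.5
  pk3 <- cumsum(c(1, 1000, 1030, 1090))
  expect_equal(hrv_features(pk3, fs)$pNN50, 0.5)

  expect_error(hrv_features(c(1, 500), fs), "at least 3")
  expect_error(hrv_features(c(1, 500, 400), fs), "increasing")
})

test_that("total spectral power is conserved across the three bands", {
  withr::local_seed(6)
  for (rep in 1:5) {
    rr <- 900 + cumsum(stats::rnorm(120, 0, 20))  # wandering RR series, ~2 min
    rr <- pmin(pmax(rr, 500), 1500)
    pk <- cumsum(c(1, rr))
    f <- hrv_features(pk, fs = 1000)
    expect_false(is.na(f$TP))
    expect_equal(f$TP, f$VLF + f$LF + f$HF, tolerance = 1e-6 * max(f$TP, 1))
    expect_true(all(c(f$VLF, f$LF, f$HF) >= 0))
  }
})

test_that("feature-space SVM separates clusters and collapses to chance on noise", {
  withr::local_seed(9)
  n <- 150
  labs <- rep(0:2, each = n / 3)
  sep_feats <- data.frame(HR = 60 + labs * 25 + stats::rnorm(n),
                          RMSSD = 80 - labs * 25 + stats::rnorm(n),
                          SDNN = 50 + labs * 20 + stats::rnorm(n))
  rep1 <- svm_baseline(sep_feats, labs, test_ratio = 0.2, n_folds = 5, seed = 2)
  expect_equal(rep1$mean_accuracy, 1.0)

  noise_feats <- data.frame(HR = stats::rnorm(n), RMSSD = stats::rnorm(n),
                            SDNN = stats::rnorm(n))
  shuffled <- sample(labs)
  rep2 <- svm_baseline(noise_feats, shuffled, test_ratio = 0.2, n_folds = 10, seed = 3)
  expect_lt(abs(rep2$mean_accuracy - 1 / 3),
            max(3 * rep2$sd_accuracy, 0.15))

  # all-NA columns (e.g. frequency powers on 5 s windows) are dropped cleanly
  sep_feats$TP <- NA_real_
  rep3 <- svm_baseline(sep_feats, labs, test_ratio = 0.2, n_folds = 3, seed = 4)
  expect_equal(rep3$mean_accuracy, 1.0)
})

test_that("per-segment HRV features expose the programmed condition contrast", {
  prof <- subject_profile(baseline_hr = 64, hr_shift = c("0" = 0, "2" = 22),
                          rr_jitter_sd = c("0" = 0.05, "2" = 0.015),
                          noise_sd = 0.03)
  rec <- gen_ecg_record(prof, condition_schedule(c(0L, 2L), c(120, 120)),
                        fs = 128, seed = 17)
  segs <- window_record(rec, 10)
  feats <- hrv_segment_features(segs)
  expect_identical(names(feats)[1:5], c("HR", "RMSSD", "AVNN", "SDNN", "pNN50"))
  ok <- !is.na(feats$HR)
  hr0 <- mean(feats$HR[ok & segs$labels == 0L])
  hr2 <- mean(feats$HR[ok & segs$labels == 2L])
  expect_lt(abs(hr0 - 64), 2)
  expect_lt(abs(hr2 - 86), 2)
})

test_that("supervised baseline reaches high accuracy on separable data", {
  cfg <- tiny_encoder_cfg(l2 = 0)
  segs <- make_sine_segments(100, 128, n_classes = 2L, sep = 4, seed = 23)
  rep_ <- supervised_baseline(segs, ecfg = cfg,
                              tcfg = train_config(1e-3, 16L, 25L),
                              test_ratio = 0.1, n_folds = 3, base_seed = 5)
  expect_gte(rep_$mean_accuracy, 0.9)
  expect_length(rep_$fold_accuracies, 3)
  expect_identical(rep_$config_echo$pipeline, "supervised")
  expect_equal(sum(rep_$confusion), 3 * 10)  # pooled over folds
})
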