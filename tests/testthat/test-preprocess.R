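test_that("resampling preserves duration, content and label alignment", {
  rec <- ecg_record(sin(2 * pi * 5 * (0:6999) / 700), rep(0L, 7000), fs = 700)
  out <- resample_record(rec, 256)
  expect_length(out$signal, 2560)
  expect_length(out$labels, 2560)
  # dominant spectral peak stays at 5 Hz (within one FFT bin)
  sp <- Mod(stats::fft(out$signal))^2
  f <- (seq_along(sp) - 1) * 256 / length(sp)
  peak <- f[which.max(sp[seq_len(length(sp) %/% 2)])]
  expect_lt(abs(peak - 5), 256 / 2560 + 1e-9)

  expect_identical(resample_record(rec, 700), rec)  # identity at equal rates
  expect_warning(resample_record(rec, 1400), "upsampl")
  expect_error(resample_record(rec, -1), "positive")

  # label boundaries move with the rate
  rec2 <- ecg_record(stats::rnorm(1400), rep(c(0L, 1L), each = 700), fs = 700)
  out2 <- resample_record(rec2, 256)
  expect_equal(sum(out2$labels == 0L), 256, tolerance = 0.01)
})

test_that("high-pass removes drift but passes cardiac-band content", {
  fs <- 256
  t <- (0:(100 * fs - 1)) / fs
  const <- ecg_record(rep(2.5, length(t)), rep(0L, length(t)), fs)
  out <- highpass_baseline(const)
  expect_lt(max(abs(out$signal)), 1e-6 * 2.5)

  s5 <- ecg_record(sin(2 * pi * 5 * t), rep(0L, length(t)), fs)
  g5 <- sqrt(mean(highpass_baseline(s5)$signal^2)) / sqrt(mean(s5$signal^2))
  expect_lt(abs(g5 - 1), 0.05)

  s01 <- ecg_record(sin(2 * pi * 0.1 * t), rep(0L, length(t)), fs)
  g01 <- sqrt(mean(highpass_baseline(s01)$signal^2)) / sqrt(mean(s01$signal^2))
  expect_lt(g01, 0.10)

  expect_length(out$signal, length(t))
  expect_error(highpass_baseline(ecg_record(1:100, rep(0L, 100), fs = 1)), "Nyquist")
})

test_that("z-scoring is per subject with no cross-subject pooling", {
  withr::local_seed(4)
  r1 <- ecg_record(stats::rnorm(1000, mean = 10, sd = 2), rep(0L, 1000), 100, "A")
  r2 <- ecg_record(stats::rnorm(1000, mean = -5, sd = 0.5), rep(0L, 1000), 100, "B")
  zs <- zscore_per_subject(list(r1, r2))
  for (z in zs) {
    expect_lt(abs(mean(z$signal)), 1e-8)
    expect_lt(abs(stats::sd(z$signal) - 1), 1e-8)
  }
  # pooled statistics would NOT standardize each record individually
  pooled <- c(r1$signal, r2$signal)
  pz <- (r1$signal - mean(pooled)) / stats::sd(pooled)
  expect_gt(abs(mean(pz)), 0.1)

  # idempotence
  z2 <- zscore_per_subject(zs)
  expect_equal(z2[[1]]$signal, zs[[1]]$signal, tolerance = 1e-8)

  flat <- ecg_record(rep(1, 100), rep(0L, 100), 100)
  expect_error(zscore_per_subject(list(flat)), "zero variance")
})

test_that("saturation clipping touches only out-of-bound samples", {
  x <- c(stats::rnorm(100), 50, -30)
  rec <- ecg_record(x, rep(0L, 102), 100)
  out <- clip_saturation(rec, bound_sd = 10)
  expect_equal(out$signal[101], 10)
  expect_equal(out$signal[102], -10)
  expect_identical(out$signal[1:100], x[1:100])
  inb <- clip_saturation(ecg_record(stats::rnorm(50), rep(0L, 50), 100), 10)
  expect_equal(max(abs(inb$signal)) <= 10, TRUE)
  expect_error(clip_saturation(rec, bound_sd = -1), "positive")
})

test_that("windowing emits uniform-label non-overlapping segments", {
  fs <- 256
  rec <- ecg_record(stats::rnorm(60 * fs), rep(0L, 60 * fs), fs)
  segs <- window_record(rec, 10)
  expect_equal(dim(segs$segments), c(6L, 2560L))

  rec12 <- ecg_record(stats::rnorm(12 * fs), rep(0L, 12 * fs), fs)
  expect_equal(nrow(window_record(rec12, 5)$segments), 2L)

  # label change at 7 s: the 5-10 s window is discarded
  lab <- rep(c(0L, 1L), c(7 * fs, 8 * fs))
  rec15 <- ecg_record(stats::rnorm(15 * fs), lab, fs)
  segs15 <- window_record(rec15, 5)
  expect_equal(nrow(segs15$segments), 2L)
  expect_identical(segs15$labels, c(0L, 1L))

  expect_warning(out <- window_record(ecg_record(stats::rnorm(100), rep(0L, 100), fs), 5),
                 "shorter")
  expect_equal(nrow(out$segments), 0L)

  # sample conservation: windows * L never exceeds the record
  expect_lte(nrow(segs$segments) * 2560, 60 * fs)
})

test_that("SMOTE balances to the majority with convex synthetic rows", {
  withr::local_seed(10)
  counts <- c(24L, 9L, 5L)
  L <- 20L
  m <- do.call(rbind, lapply(1:3, function(cl) {
    matrix(stats::rnorm(counts[cl] * L, mean = cl * 3), counts[cl], L)
  }))
  segs <- segment_set(m, rep(0:2, counts), rep("S", sum(counts)), fs = 4, window_s = 5)
  bal <- smote_balance(segs, seed = 2)
  expect_equal(as.integer(table(bal$labels)), rep(24L, 3))

  # originals preserved verbatim, in order
  expect_identical(bal$segments[seq_len(sum(counts)), ], segs$segments)

  # synthetic rows stay inside the componentwise envelope of their class
  synth_idx <- (sum(counts) + 1L):nrow(bal$segments)
  for (i in synth_idx) {
    cls_rows <- segs$segments[segs$labels == bal$labels[i], , drop = FALSE]
    expect_true(all(bal$segments[i, ] >= apply(cls_rows, 2, min) - 1e-12))
    expect_true(all(bal$segments[i, ] <= apply(cls_rows, 2, max) + 1e-12))
  }

  # deterministic given seed; balanced input unchanged
  bal2 <- smote_balance(segs, seed = 2)
  expect_identical(bal$segments, bal2$segments)
  expect_identical(smote_balance(bal, seed = 7), bal)

  one <- segment_set(m[1:24, ], rep(0L, 24), rep("S", 24), 4, 5)
  expect_warning(same <- smote_balance(one), "single-class")
  expect_identical(same, one)

  tiny <- segment_set(m[c(1:10, 25), ], c(rep(0L, 10), 1L), rep("S", 11), 4, 5)
  expect_error(smote_balance(tiny), "single member")
})

test_that("segment set CSV/JSON round trip preserves content", {
  segs <- make_sine_segments(12, 64, seed = 3)
  base <- file.path(withr::local_tempdir(), "segs")
  write_segment_set(segs, base)
  back <- read_segment_set(base)
  expect_equal(unname(back$segments), unname(segs$segments), tolerance = 1e-12)
  expect_identical(back$labels, segs$labels)
  expect_identical(back$subject_ids, segs$subject_ids)
})
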