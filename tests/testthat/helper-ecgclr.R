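# Shared fixtures and independent oracles, built in code at test time.

# Small encoder that keeps CNN tests fast while exercising every layer type.
tiny_encoder_cfg <- function(L = 128L, dropout = 0.1, l2 = 0) {
  encoder_config(input_length = L, filters = c(4L, 6L, 8L),
                 kernels = c(16L, 8L, 4L), pool_size = 2L,
                 dropout_rate = dropout, dense_units = 8L, l2_coeff = l2)
}

# Labeled segments with class-dependent structure: class c is a sine of
# frequency (c+1)*f0 plus noise. `sep` scales the signal-to-noise separation.
make_sine_segments <- function(n, L, n_classes = 3L, sep = 2, fs = 64,
                               window_s = L / fs, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(seq_len(n_classes) - 1L, length.out = n)
    tt <- seq_len(L) / fs
    m <- t(vapply(labels, function(cl) {
      sep * sin(2 * pi * (cl + 1) * 2 * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(L)
    }, numeric(L)))
    segment_set(m, labels, rep(sprintf("S%02d", seq_len(4)), length.out = n),
                fs = fs, window_s = window_s)
  })
}

# Brute-force NT-Xent oracle: explicit double loop over anchors and
# denominator terms, independent of the vectorized implementation.
ntxent_oracle <- function(Z, tau) {
  n2 <- nrow(Z)
  cs <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  losses <- numeric(n2)
  for (a in seq_len(n2)) {
    pos <- if (a %% 2 == 1) a + 1L else a - 1L
    den <- 0
    for (y in seq_len(n2)) {
      if (y != a) den <- den + exp(cs(Z[a, ], Z[y, ]) / tau)
    }
    losses[a] <- -log(exp(cs(Z[a, ], Z[pos, ]) / tau) / den)
  }
  mean(losses)
}

# Clean single-condition record for R-peak ground-truth checks.
make_clean_record <- function(hr = 60, dur = 60, fs = 256, seed = 7) {
  prof <- subject_profile(baseline_hr = hr, hr_shift = c("0" = 0),
                          rr_jitter_sd = c("0" = 0), wander_amplitude = 0.1,
                          noise_sd = 0.02)
  gen_ecg_record(prof, condition_schedule(0L, dur), fs = fs, seed = seed)
}
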