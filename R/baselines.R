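#' Detect R peaks in an ECG trace
#'
#' Pan-Tompkins-style detector: zero-phase 5-15 Hz Butterworth band-pass,
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' peak picking with running signal/noise level estimates and a 200 ms
#' refractory period. Each detection is refined to the local maximum of the
#' band-passed signal.
#'
#' @param x An [ecg_record()] or a numeric vector.
#' @param fs Sampling rate in Hz (>= 64); taken from the record when `x` is
#'   an [ecg_record()]. The trace must be at least 2 s long.
#' @return Strictly increasing integer sample indices of the detected R
#'   peaks; empty (with a warning) when nothing is detectable.
#' @export
detect_rpeaks <- function(x, fs = NULL) {
  if (inherits(x, "ecg_record")) { fs <- x$fs; x <- x$signal }
  if (is.null(fs) || fs < 64) stop("`fs` must be given and >= 64 Hz", call. = FALSE)
  n <- length(x)
  if (n < 2 * fs) stop("signal must be at least 2 s long", call. = FALSE)
  if (all(x == x[1])) {
    warning("no detectable peaks in a constant signal")
    return(integer(0))
  }

  bp <- filtfilt_padded(signal::butter(3, c(5, 15) / (fs / 2), type = "pass"), x,
                        pad = round(fs))
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  if (max(integ) <= 0) {
    warning("no detectable peaks")
    return(integer(0))
  }

  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0L) {
    warning("no detectable peaks")
    return(integer(0))
  }

  init <- integ[seq_len(min(n, 2L * round(fs)))]
  spki <- max(init)
  npki <- mean(init) / 2
  refr <- 0.2 * fs
  peaks <- integer(0)
  for (i in cand) {
    p <- integ[i]
    thr <- npki + 0.25 * (spki - npki)
    if (p > thr) {
      if (length(peaks) == 0L || (i - peaks[length(peaks)]) >= refr) {
        peaks <- c(peaks, i)
        spki <- 0.125 * p + 0.875 * spki
      } else if (p > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
      }
    } else {
      npki <- 0.125 * p + 0.875 * npki
    }
  }
  if (length(peaks) == 0L) {
    warning("no detectable peaks")
    return(integer(0))
  }

  # refine to the band-passed R wave apex
  half <- round(0.1 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory constraint after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  while (!all(keep)) {
    drop <- which(!keep)[1]
    if (bp[refined[drop]] > bp[refined[drop - 1L]]) {
      refined <- refined[-(drop - 1L)]
    } else {
      refined <- refined[-drop]
    }
    keep <- c(TRUE, diff(refined) >= refr)
  }
  refined
}

# Welch periodogram-averaging PSD estimate with a Hann window and 50% overlap.
# Returns freq (Hz) and psd (input-units^2 / Hz), one-sided.
welch_psd <- function(x, fs, seg_len = min(256L, length(x))) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  norm <- fs * sum(win^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(stats::fft(seg))^2 / norm
    P <- P[seq_len(nf)]
    if (seg_len %% 2L == 0L) P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)] else
      P[2:nf] <- 2 * P[2:nf]
    acc <- acc + P
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = acc / length(starts))
}

#' Classical HRV features from detected R peaks
#'
#' Time-domain features from the RR (N-N) interval series in milliseconds:
#' AVNN (mean), SDNN (standard deviation), RMSSD (root-mean-square of
#' successive differences), pNN50 (fraction of successive differences
#' exceeding 50 ms) and HR = 60000 / AVNN. Frequency-domain powers (ms^2)
#' come from a Welch PSD of the 4 Hz-interpolated, linearly detrended RR
#' series, integrated over VLF 0.0033-0.04, LF 0.04-0.15 and HF 0.15-0.4 Hz,
#' with TP their sum; they are reported as `NA` (missing, not zero) when the
#' peak series spans less than 30 s.
#'
#' @param rpeaks Strictly increasing R-peak sample indices (>= 3).
#' @param fs Sampling rate in Hz.
#' @return An object of class `hrv_features`: a named list with fields `HR`,
#'   `RMSSD`, `AVNN`, `SDNN`, `pNN50`, `VLF`, `LF`, `HF`, `TP`.
#' @export
hrv_features <- function(rpeaks, fs) {
  if (length(rpeaks) < 3L) stop("need at least 3 R peaks for HRV features", call. = FALSE)
  if (any(diff(rpeaks) <= 0)) stop("`rpeaks` must be strictly increasing", call. = FALSE)
  rr <- diff(rpeaks) / fs * 1000  # ms
  avnn <- mean(rr)
  sdnn <- stats::sd(rr)
  drr <- diff(rr)
  rmssd <- if (length(drr)) sqrt(mean(drr^2)) else 0
  pnn50 <- if (length(drr)) mean(abs(drr) > 50) else 0
  hr <- 60000 / avnn

  span_s <- (rpeaks[length(rpeaks)] - rpeaks[1]) / fs
  vlf <- lf <- hf <- tp <- NA_real_
  if (span_s >= 30) {
    t_rr <- (rpeaks[-1] - rpeaks[1]) / fs
    grid <- seq(t_rr[1], t_rr[length(t_rr)], by = 1 / 4)
    x <- stats::approx(t_rr, rr, xout = grid)$y
    x <- stats::residuals(stats::lm(x ~ grid))  # linear detrend
    ps <- welch_psd(x, fs = 4)
    df <- ps$freq[2] - ps$freq[1]
    band <- function(lo, hi) sum(ps$psd[ps$freq >= lo & ps$freq < hi]) * df
    vlf <- band(0.0033, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.40)
    tp <- vlf + lf + hf
  }
  structure(list(HR = hr, RMSSD = rmssd, AVNN = avnn, SDNN = sdnn, pNN50 = pnn50,
                 VLF = vlf, LF = lf, HF = hf, TP = tp),
            class = "hrv_features")
}

#' Per-segment HRV feature matrix
#'
#' Runs [detect_rpeaks()] and [hrv_features()] on every segment row. Segments
#' where fewer than 3 peaks are found yield all-`NA` rows.
#'
#' @param segs A [segment_set()].
#' @return A data frame with the nine named HRV columns, one row per segment.
#' @export
hrv_segment_features <- function(segs) {
  stopifnot(inherits(segs, "segment_set"))
  cols <- c("HR", "RMSSD", "AVNN", "SDNN", "pNN50", "VLF", "LF", "HF", "TP")
  out <- matrix(NA_real_, nrow(segs$segments), length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_len(nrow(segs$segments))) {
    pk <- suppressWarnings(tryCatch(detect_rpeaks(segs$segments[i, ], segs$fs),
                                    error = function(e) integer(0)))
    if (length(pk) >= 3L) {
      f <- hrv_features(pk, segs$fs)
      out[i, ] <- unlist(f)[cols]
    }
  }
  as.data.frame(out)
}

#' HRV-feature SVM baseline
#'
#' Classical-machine-learning comparison arm: an RBF-kernel SVM on the nine
#' HRV features, evaluated over repeated random shuffled splits. Feature
#' columns that are entirely missing (e.g. frequency powers on short
#' windows) are dropped; remaining features are standardized with
#' training-fold statistics only.
#'
#' @param features Data frame or matrix of HRV features (rows = segments).
#' @param labels Condition codes aligned with `features` rows.
#' @param test_ratio Fraction of rows held out for testing in each fold.
#' @param n_folds Number of random splits (default 10).
#' @param seed Base RNG seed.
#' @param cost SVM cost parameter C (default 1).
#' @return A `fold_report` (see [evaluate_pipeline()]) with the fitted final
#'   model in `$model`.
#' @export
svm_baseline <- function(features, labels, test_ratio = 0.1, n_folds = 10L,
                         seed = 1L, cost = 1) {
  features <- as.data.frame(features)
  keep_col <- vapply(features, function(cc) !all(is.na(cc)), logical(1))
  F_ <- as.matrix(features[, keep_col, drop = FALSE])
  valid <- stats::complete.cases(F_)
  classes <- sort(unique(labels))
  if (length(unique(labels[valid])) < 2L) {
    stop("need at least 2 classes with valid features", call. = FALSE)
  }

  last_fit <- NULL
  fold_fn <- function(train_idx, test_idx, fold_seed) {
    tr <- train_idx[valid[train_idx]]
    te <- test_idx[valid[test_idx]]
    pred <- rep(NA_integer_, length(test_idx))
    if (length(unique(labels[tr])) < 2L || length(te) == 0L) return(pred)
    Xtr <- F_[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, stats::sd); sg[sg == 0] <- 1
    fit <- with_seed(fold_seed,
      e1071::svm(scale(Xtr, mu, sg), factor(labels[tr], levels = classes),
                 kernel = "radial", cost = cost, scale = FALSE))
    last_fit <<- fit
    p <- stats::predict(fit, scale(F_[te, , drop = FALSE], mu, sg))
    pred[match(te, test_idx)] <- as.integer(as.character(p))
    pred
  }

  rep_ <- run_folds(length(labels), labels, test_ratio, n_folds, seed, fold_fn,
                    config_echo = list(pipeline = "hrv-svm", cost = cost,
                                       features = colnames(F_),
                                       test_ratio = test_ratio,
                                       n_folds = n_folds, base_seed = seed))
  rep_$model <- last_fit
  rep_
}

#' Fully supervised CNN baseline
#'
#' Identical architecture and training to the downstream classifier; the only
#' difference from the contrastive pipeline is the lack of upstream
#' pretraining (random initialization).
#'
#' @param segs A labeled [segment_set()].
#' @param ecfg An [encoder_config()].
#' @param tcfg Downstream [train_config()].
#' @param test_ratio Held-out fraction per fold.
#' @param n_folds Number of random splits.
#' @param base_seed Base RNG seed.
#' @return A `fold_report`.
#' @export
supervised_baseline <- function(segs, ecfg = encoder_config(ncol(segs$segments)),
                                tcfg = train_config(1e-3, 128L, 150L),
                                test_ratio = 0.1, n_folds = 10L, base_seed = 1L) {
  evaluate_pipeline(segs, pipeline = "supervised", test_ratio = test_ratio,
                    n_folds = n_folds, base_seed = base_seed,
                    encoder_cfg = ecfg, downstream_cfg = tcfg)
}
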