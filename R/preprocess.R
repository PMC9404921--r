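#' Windowed ECG segment container
#'
#' Rows of `segments` are fixed-length model-ready windows; `labels` and
#' `subject_ids` align row-for-row.
#'
#' @param segments n x L numeric matrix.
#' @param labels Integer condition codes, length n.
#' @param subject_ids Character subject ids, length n.
#' @param fs Sampling rate in Hz.
#' @param window_s Window duration in seconds; `L` must equal
#'   `round(fs * window_s)`.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, labels, subject_ids, fs, window_s) {
  segments <- as.matrix(segments)
  n <- nrow(segments)
  if (length(labels) != n || length(subject_ids) != n) {
    stop("`labels` and `subject_ids` must match the number of segment rows", call. = FALSE)
  }
  if (n > 0 && ncol(segments) != round(fs * window_s)) {
    stop("segment length must equal round(fs * window_s)", call. = FALSE)
  }
  if (n > 0 && any(!is.finite(segments))) stop("all segment values must be finite", call. = FALSE)
  structure(list(segments = segments, labels = as.integer(labels),
                 subject_ids = as.character(subject_ids),
                 fs = fs, window_s = window_s),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d samples (%g s @ %g Hz); class counts: %s\n",
              nrow(x$segments), ncol(x$segments), x$window_s, x$fs,
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)), collapse = " ")))
  invisible(x)
}

# Zero-phase IIR filtering with odd-reflection edge padding (tames the edge
# transients of plain forward-backward filtering on short records).
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

#' Resample an ECG record to a new rate
#'
#' Polyphase rational resampling with an anti-aliasing FIR low-pass (via
#' [signal::resample()]); the rational factor is reduced from the integer
#' sampling rates (e.g. 700 -> 256 Hz uses 64/175). Labels are carried over by
#' nearest-neighbour lookup so the label stream keeps the signal's length.
#'
#' @param rec An [ecg_record()].
#' @param fs_out Target rate in Hz (positive). Upsampling is allowed with a
#'   warning.
#' @return A resampled [ecg_record()].
#' @export
resample_record <- function(rec, fs_out) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.numeric(fs_out) || fs_out <= 0) stop("`fs_out` must be positive", call. = FALSE)
  if (fs_out == rec$fs) return(rec)
  if (fs_out > rec$fs) warning("upsampling above the original rate adds no information")

  p <- round(fs_out * 1000)
  q <- round(rec$fs * 1000)
  g <- .gcd(p, q)
  p <- p / g; q <- q / g
  y <- as.numeric(signal::resample(rec$signal, p, q))
  n_out <- round(length(rec$signal) * fs_out / rec$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))

  src <- pmin(length(rec$labels), pmax(1L, round((seq_len(n_out) - 1) * rec$fs / fs_out) + 1L))
  ecg_record(signal = y, labels = rec$labels[src], fs = fs_out,
             subject_id = rec$subject_id, metadata = rec$metadata,
             r_peaks = if (!is.null(rec$r_peaks)) {
               pmax(1L, pmin(n_out, round((rec$r_peaks - 1L) * fs_out / rec$fs) + 1L))
             })
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Remove baseline wander with a zero-phase Chebyshev type-II high-pass
#'
#' Order-4 Chebyshev type-II design with 40 dB stop-band attenuation and
#' stop-band edge at `passband_hz`, applied forward-backward (zero phase, so
#' R-peak timing is untouched). The record mean is removed before filtering,
#' so a constant input maps to exactly zero.
#'
#' @param rec An [ecg_record()].
#' @param passband_hz Pass-band edge in Hz (default 0.8); must be below
#'   Nyquist.
#' @return The filtered [ecg_record()], same length.
#' @export
highpass_baseline <- function(rec, passband_hz = 0.8) {
  stopifnot(inherits(rec, "ecg_record"))
  if (passband_hz <= 0) stop("`passband_hz` must be positive", call. = FALSE)
  if (rec$fs <= 2 * passband_hz) {
    stop("`passband_hz` must be below the Nyquist frequency", call. = FALSE)
  }
  ch <- signal::cheby2(4, 40, passband_hz / (rec$fs / 2), type = "high")
  x <- rec$signal - mean(rec$signal)
  y <- filtfilt_padded(ch, x, pad = round(3 * rec$fs / passband_hz))
  rec$signal <- y
  rec
}

#' Per-subject z-score normalization
#'
#' Standardizes each record with its own mean and standard deviation; no
#' statistics are pooled across subjects.
#'
#' @param recs A list of [ecg_record()] objects (a single record is accepted).
#' @return A list of standardized records (mean 0, sd 1 within each record).
#' @export
zscore_per_subject <- function(recs) {
  if (inherits(recs, "ecg_record")) recs <- list(recs)
  lapply(recs, function(r) {
    if (length(r$signal) < 2L) stop("record must have more than one sample", call. = FALSE)
    s <- stats::sd(r$signal)
    if (s == 0) stop(sprintf("record %s has zero variance; cannot z-score", r$subject_id),
                     call. = FALSE)
    r$signal <- (r$signal - mean(r$signal)) / s
    r
  })
}

#' Clip sensor-saturation excursions
#'
#' On a z-scored record, samples beyond `bound_sd` standard deviations are set
#' to the bound, flattening saturation plateaus without touching other samples.
#'
#' @param rec A z-scored [ecg_record()].
#' @param bound_sd Positive clip bound in SD units (default 10).
#' @return The clipped [ecg_record()].
#' @export
clip_saturation <- function(rec, bound_sd = 10) {
  stopifnot(inherits(rec, "ecg_record"))
  if (bound_sd <= 0) stop("`bound_sd` must be positive", call. = FALSE)
  rec$signal <- pmin(pmax(rec$signal, -bound_sd), bound_sd)
  rec
}

#' Window a record into fixed-length labeled segments
#'
#' Cuts consecutive windows of `round(fs * window_s)` samples with stride
#' `stride_s` (default: non-overlapping). A window is emitted only when all
#' its per-sample labels agree; windows spanning a condition change are
#' discarded so segment supervision is unambiguous.
#'
#' @param rec An [ecg_record()].
#' @param window_s Window length in seconds.
#' @param stride_s Stride between window starts in seconds (default
#'   `window_s`, i.e. non-overlapping).
#' @return A [segment_set()]; empty (with a warning) if the record is shorter
#'   than one window.
#' @export
window_record <- function(rec, window_s, stride_s = window_s) {
  stopifnot(inherits(rec, "ecg_record"))
  L <- round(rec$fs * window_s)
  stride <- max(1L, round(rec$fs * stride_s))
  n <- length(rec$signal)
  if (n < L) {
    warning("record shorter than one window; returning empty segment set")
    return(segment_set(matrix(numeric(0), 0, L), integer(0), character(0),
                       rec$fs, window_s))
  }
  starts <- seq.int(1L, n - L + 1L, by = stride)
  segs <- vector("list", length(starts))
  labs <- integer(length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    lw <- rec$labels[idx]
    if (lw[1] == lw[L] && all(lw == lw[1])) {
      segs[[i]] <- rec$signal[idx]
      labs[i] <- lw[1]
      keep[i] <- TRUE
    }
  }
  m <- if (any(keep)) do.call(rbind, segs[keep]) else matrix(numeric(0), 0, L)
  segment_set(m, labs[keep], rep(rec$subject_id, sum(keep)), rec$fs, window_s)
}

#' Window and pool several records
#'
#' @param recs List of [ecg_record()] objects.
#' @inheritParams window_record
#' @return A pooled [segment_set()].
#' @export
window_records <- function(recs, window_s, stride_s = window_s) {
  sets <- lapply(recs, window_record, window_s = window_s, stride_s = stride_s)
  bind_segment_sets(sets)
}

#' Concatenate segment sets row-wise
#'
#' @param sets List of [segment_set()] objects with matching `fs`/`window_s`.
#' @return A single [segment_set()].
#' @export
bind_segment_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s$segments) > 0, sets)
  if (length(sets) == 0L) stop("no non-empty segment sets to bind", call. = FALSE)
  fs <- sets[[1]]$fs; ws <- sets[[1]]$window_s
  ok <- vapply(sets, function(s) s$fs == fs && s$window_s == ws, logical(1))
  if (!all(ok)) stop("segment sets disagree on fs or window_s", call. = FALSE)
  segment_set(do.call(rbind, lapply(sets, `[[`, "segments")),
              unlist(lapply(sets, `[[`, "labels")),
              unlist(lapply(sets, `[[`, "subject_ids")), fs, ws)
}

#' Subset a segment set by row index
#'
#' @param segs A [segment_set()].
#' @param idx Integer row indices.
#' @return The row-subset [segment_set()].
#' @export
subset_segments <- function(segs, idx) {
  segment_set(segs$segments[idx, , drop = FALSE], segs$labels[idx],
              segs$subject_ids[idx], segs$fs, segs$window_s)
}

#' Balance class counts with SMOTE
#'
#' Synthetic Minority Oversampling: every minority class is grown to the
#' majority count by convex combinations `s_i + u * (s_j - s_i)`, `u ~ U(0,1)`,
#' of a random minority segment and one of its `k_neighbors` nearest minority
#' neighbours (Euclidean distance). Original rows are preserved verbatim; the
#' majority class is never altered. With the three-level stress counts
#' 242/88/48 this yields 726 segments in total.
#'
#' @param segs A [segment_set()].
#' @param k_neighbors Number of nearest neighbours (reduced to class size - 1
#'   for very small classes).
#' @param seed Integer RNG seed; output is deterministic given the seed.
#' @return A class-balanced [segment_set()]; synthetic rows carry subject id
#'   `"smote:<parent id>"`.
#' @export
smote_balance <- function(segs, k_neighbors = 5, seed = 1) {
  stopifnot(inherits(segs, "segment_set"))
  counts <- table(segs$labels)
  if (length(counts) < 2L) {
    warning("single-class input; returning unchanged")
    return(segs)
  }
  maj <- max(counts)
  if (all(counts == maj)) return(segs)

  with_seed(seed, {
    new_rows <- list(); new_labs <- integer(0); new_ids <- character(0)
    for (cls in as.integer(names(counts))) {
      n_c <- as.integer(counts[as.character(cls)])
      need <- maj - n_c
      if (need == 0L) next
      if (n_c < 2L) stop(sprintf("class %d has a single member; SMOTE needs at least 2", cls),
                         call. = FALSE)
      k <- min(k_neighbors, n_c - 1L)
      rows <- which(segs$labels == cls)
      X <- segs$segments[rows, , drop = FALSE]
      D <- as.matrix(stats::dist(X))
      nn <- t(apply(D, 1L, function(d) order(d)[2:(k + 1L)]))
      synth <- matrix(0, need, ncol(X))
      parents <- integer(need)
      for (m in seq_len(need)) {
        i <- sample.int(n_c, 1L)
        j <- nn[i, sample.int(k, 1L)]
        u <- stats::runif(1)
        synth[m, ] <- X[i, ] + u * (X[j, ] - X[i, ])
        parents[m] <- rows[i]
      }
      new_rows[[length(new_rows) + 1L]] <- synth
      new_labs <- c(new_labs, rep(cls, need))
      new_ids <- c(new_ids, paste0("smote:", segs$subject_ids[parents]))
    }
    segment_set(rbind(segs$segments, do.call(rbind, new_rows)),
                c(segs$labels, new_labs),
                c(segs$subject_ids, new_ids), segs$fs, segs$window_s)
  })
}

#' Run the full preprocessing chain on raw records
#'
#' Fixed order: resample -> high-pass -> per-subject z-score -> saturation
#' clip -> window -> (optional) SMOTE.
#'
#' @param recs List of raw [ecg_record()] objects.
#' @param fs_out Target sampling rate (Hz).
#' @param highpass_hz High-pass pass-band edge (Hz).
#' @param clip_sd Saturation clip bound in SD units.
#' @param window_s Window length (s).
#' @param stride_s Window stride (s), default non-overlapping.
#' @param smote Apply SMOTE class balancing to the pooled segments.
#' @param seed RNG seed (SMOTE only).
#' @return A [segment_set()].
#' @export
preprocess_records <- function(recs, fs_out = 256, highpass_hz = 0.8,
                               clip_sd = 10, window_s = 10, stride_s = window_s,
                               smote = FALSE, seed = 1) {
  if (inherits(recs, "ecg_record")) recs <- list(recs)
  recs <- lapply(recs, function(r) {
    if (r$fs != fs_out) r <- resample_record(r, fs_out)
    highpass_baseline(r, highpass_hz)
  })
  recs <- zscore_per_subject(recs)
  recs <- lapply(recs, clip_saturation, bound_sd = clip_sd)
  segs <- window_records(recs, window_s, stride_s)
  if (smote) segs <- smote_balance(segs, seed = seed)
  segs
}

#' Write / read a segment set as CSV + JSON sidecar
#'
#' `<basepath>.csv` holds one segment per row (columns `label`, `subject_id`,
#' then the samples); `<basepath>.json` holds `fs` and `window_s`.
#'
#' @param segs A [segment_set()].
#' @param basepath Path without extension.
#' @return `write_segment_set` returns `basepath` invisibly.
#' @export
write_segment_set <- function(segs, basepath) {
  stopifnot(inherits(segs, "segment_set"))
  df <- data.frame(label = segs$labels, subject_id = segs$subject_ids,
                   segs$segments, check.names = FALSE)
  utils::write.csv(df, paste0(basepath, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = segs$fs, window_s = segs$window_s),
                       paste0(basepath, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(basepath)
}

#' @rdname write_segment_set
#' @export
read_segment_set <- function(basepath) {
  d <- utils::read.csv(paste0(basepath, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(basepath, ".json"), simplifyVector = TRUE)
  segment_set(as.matrix(d[, -(1:2), drop = FALSE]), d$label, d$subject_id,
              meta$fs, meta$window_s)
}
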