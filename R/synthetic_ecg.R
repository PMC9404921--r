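#' Subject profile for the synthetic ECG generator
#'
#' Describes one simulated wearer: resting heart rate, per-condition heart-rate
#' shifts and RR-interval jitter (the knobs that create condition-dependent
#' HR/HRV structure), plus baseline-wander, sensor-noise and amplitude
#' parameters. Condition maps are named numeric vectors keyed by the condition
#' code as a string (e.g. `c("0" = 0, "1" = 12)`).
#'
#' Defaults emulate a mild laboratory stress protocol: condition 0 is neutral,
#' higher codes raise heart rate (+12, +25 beats/min) and *reduce* beat-to-beat
#' variability (RR jitter 50 -> 35 -> 20 ms), the canonical autonomic stress
#' signature.
#'
#' @param subject_id Subject identifier string.
#' @param baseline_hr Resting heart rate in beats/min, in \[40, 200\].
#' @param hr_shift Named numeric map condition -> heart-rate delta (beats/min).
#' @param rr_jitter_sd Named numeric map condition -> RR jitter SD (seconds),
#'   all non-negative.
#' @param wander_amplitude Baseline-wander amplitude in signal units.
#' @param noise_sd White sensor-noise SD in signal units (non-negative).
#' @param amplitude_gain Dimensionless multiplier on beat amplitudes.
#' @param saturation_level Optional hard sensor ceiling (signal units); beats
#'   exceeding it are flat-topped. `Inf` (default) disables saturation.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            baseline_hr = 70,
                            hr_shift = c("0" = 0, "1" = 12, "2" = 25),
                            rr_jitter_sd = c("0" = 0.050, "1" = 0.035, "2" = 0.020),
                            wander_amplitude = 0.15,
                            noise_sd = 0.05,
                            amplitude_gain = 1,
                            saturation_level = Inf) {
  if (baseline_hr < 40 || baseline_hr > 200) {
    stop("`baseline_hr` must lie in [40, 200] beats/min", call. = FALSE)
  }
  if (any(rr_jitter_sd < 0)) stop("all `rr_jitter_sd` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), baseline_hr = baseline_hr,
         hr_shift = hr_shift, rr_jitter_sd = rr_jitter_sd,
         wander_amplitude = wander_amplitude, noise_sd = noise_sd,
         amplitude_gain = amplitude_gain, saturation_level = saturation_level),
    class = "subject_profile"
  )
}

#' Ordered schedule of condition blocks
#'
#' @param conditions Integer condition codes, one per block.
#' @param durations_s Block durations in seconds, all positive.
#' @return An object of class `condition_schedule`.
#' @export
condition_schedule <- function(conditions, durations_s) {
  if (length(conditions) < 1L) stop("schedule must contain at least one block", call. = FALSE)
  if (length(conditions) != length(durations_s)) {
    stop("`conditions` and `durations_s` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("all block durations must be positive", call. = FALSE)
  }
  structure(list(conditions = as.integer(conditions), durations_s = as.numeric(durations_s)),
            class = "condition_schedule")
}

#' Single-subject ECG record container
#'
#' @param signal Numeric vector of ECG samples (sensor units).
#' @param labels Integer per-sample condition codes, same length as `signal`.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param metadata Named character vector of free-form annotations.
#' @param r_peaks Optional ground-truth R-peak sample indices (generator only).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, labels, fs, subject_id = "S01",
                       metadata = character(), r_peaks = NULL) {
  if (length(signal) != length(labels)) {
    stop("`signal` and `labels` must have equal length", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (any(!is.finite(signal))) stop("all samples must be finite", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), fs = fs,
         signal = as.numeric(signal), labels = as.integer(labels),
         metadata = metadata, r_peaks = r_peaks),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject %s: %d samples @ %g Hz (%.1f s), conditions {%s}\n",
              x$subject_id, length(x$signal), x$fs, length(x$signal) / x$fs,
              paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

# P-Q-R-S-T beat template: relative offsets (s, per unit RR), amplitudes and
# Gaussian widths (s). Widths scale with sqrt(RR) so fast beats stay rendered.
.beat_offsets <- c(-0.22, -0.035, 0.0, 0.035, 0.28)
.beat_amps    <- c(0.12, -0.12, 1.0, -0.18, 0.30)
.beat_widths  <- c(0.050, 0.012, 0.016, 0.014, 0.070)

#' Generate a synthetic single-lead ECG record
#'
#' Beats are a sum-of-Gaussians P-Q-R-S-T template placed at RR-interval
#' onsets. The RR series is `60 / (baseline_hr + hr_shift(cond))` plus AR(1)
#' jitter (coefficient `ar_coeff`) with stationary SD `rr_jitter_sd(cond)`,
#' so stressful conditions can raise heart rate while lowering HRV. Sinusoidal
#' baseline wander (< 0.5 Hz) and white sensor noise are added, and an
#' optional hard saturation ceiling produces flat-top plateaus. Output is
#' bit-reproducible for a given `seed`.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [condition_schedule()].
#' @param fs Sampling rate in Hz, at least 64 (below that the QRS complex
#'   cannot be rendered).
#' @param seed Integer RNG seed.
#' @param ar_coeff AR(1) coefficient of the RR jitter process.
#' @return An [ecg_record()] with per-sample labels following the schedule and
#'   ground-truth R-peak indices in `$r_peaks`.
#' @export
gen_ecg_record <- function(profile, schedule, fs = 256, seed = 1, ar_coeff = 0.8) {
  stopifnot(inherits(profile, "subject_profile"), inherits(schedule, "condition_schedule"))
  if (fs < 64) stop("`fs` must be >= 64 Hz to render the QRS complex", call. = FALSE)
  total_s <- sum(schedule$durations_s)
  n <- round(total_s * fs)
  if (n < 1) stop("schedule duration too short", call. = FALSE)

  bounds <- round(cumsum(schedule$durations_s) * fs)
  bounds[length(bounds)] <- n
  labels <- integer(n)
  lo <- 1L
  for (k in seq_along(bounds)) {
    if (bounds[k] >= lo) labels[lo:bounds[k]] <- schedule$conditions[k]
    lo <- bounds[k] + 1L
  }

  cond_key <- function(map, cond) {
    v <- map[as.character(cond)]
    if (is.na(v)) 0 else unname(v)
  }

  with_seed(seed, {
    # --- RR series and beat times -----------------------------------------
    t_beat <- numeric(0)
    rr_beat <- numeric(0)
    t <- stats::runif(1, 0.1, 0.6)
    j <- 0
    innov_scale <- sqrt(1 - ar_coeff^2)
    while (t < total_s) {
      cond <- labels[min(n, floor(t * fs) + 1L)]
      hr <- profile$baseline_hr + cond_key(profile$hr_shift, cond)
      hr <- min(max(hr, 30), 220)
      mean_rr <- 60 / hr
      sd_c <- cond_key(profile$rr_jitter_sd, cond)
      j <- ar_coeff * j + innov_scale * sd_c * stats::rnorm(1)
      rr <- min(max(mean_rr + j, 0.25), 2.5)
      t_beat <- c(t_beat, t)
      rr_beat <- c(rr_beat, rr)
      t <- t + rr
    }

    # --- render beats ------------------------------------------------------
    sig <- numeric(n)
    for (b in seq_along(t_beat)) {
      rr <- rr_beat[b]
      tr <- t_beat[b]
      i0 <- max(1L, floor((tr - 0.45 * rr) * fs) + 1L)
      i1 <- min(n, ceiling((tr + 0.65 * rr) * fs) + 1L)
      if (i1 < i0) next
      tt <- (seq.int(i0, i1) - 1) / fs
      w <- .beat_widths * sqrt(rr)
      acc <- numeric(length(tt))
      for (g in 1:5) {
        acc <- acc + .beat_amps[g] * exp(-((tt - tr - .beat_offsets[g] * rr)^2) / (2 * w[g]^2))
      }
      sig[i0:i1] <- sig[i0:i1] + profile$amplitude_gain * acc
    }

    # --- baseline wander + sensor noise -----------------------------------
    tt_all <- (seq_len(n) - 1) / fs
    f_w <- stats::runif(1, 0.10, 0.45)
    sig <- sig + profile$wander_amplitude * sin(2 * pi * f_w * tt_all + stats::runif(1, 0, 2 * pi))
    if (profile$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, profile$noise_sd)
    if (is.finite(profile$saturation_level)) {
      sig <- pmin(pmax(sig, -profile$saturation_level), profile$saturation_level)
    }

    ecg_record(
      signal = sig, labels = labels, fs = fs, subject_id = profile$subject_id,
      metadata = c(seed = as.character(seed), generator = "sum-of-gaussians-pqrst"),
      r_peaks = pmin(n, round(t_beat * fs) + 1L)
    )
  })
}

#' Generate a multi-subject synthetic ECG dataset
#'
#' One record per subject with randomly perturbed subject profiles (resting
#' heart rate, noise, gain), so inter-subject variability overlaps the
#' condition effects as it does in real cohorts. When `class_counts` is given,
#' per-subject block durations are exact multiples of `window_s` distributed
#' across subjects so that non-overlapping windowing at `window_s` reproduces
#' the requested per-class segment counts (emulating imbalanced cohorts such
#' as a 242:88:48 three-level stress study).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param schedule_template [condition_schedule()] used for every subject when
#'   `class_counts` is NULL.
#' @param fs Sampling rate in Hz.
#' @param class_counts Optional named integer map condition -> desired total
#'   segment count after windowing at `window_s`.
#' @param seed Integer RNG seed.
#' @param window_s Window length (s) that `class_counts` is calibrated for.
#' @param profile_template Optional [subject_profile()] whose condition maps
#'   and amplitudes are inherited by all subjects.
#' @return A list of [ecg_record()] objects with distinct subject ids.
#' @export
gen_dataset <- function(n_subjects,
                        schedule_template = condition_schedule(c(0L, 1L, 2L), c(120, 90, 60)),
                        fs = 256, class_counts = NULL, seed = 1,
                        window_s = 5, profile_template = subject_profile()) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (is.null(class_counts) && is.null(schedule_template)) {
    stop("schedule must be non-empty", call. = FALSE)
  }

  schedules <- vector("list", n_subjects)
  if (!is.null(class_counts)) {
    conds <- as.integer(names(class_counts))
    per_subj <- matrix(0L, n_subjects, length(conds))
    for (ci in seq_along(conds)) {
      cnt <- as.integer(class_counts[[ci]])
      base <- cnt %/% n_subjects
      extra <- cnt %% n_subjects
      per_subj[, ci] <- base + as.integer(seq_len(n_subjects) <= extra)
    }
    for (s in seq_len(n_subjects)) {
      keep <- per_subj[s, ] > 0L
      if (!any(keep)) keep[1] <- TRUE  # degenerate: give one window of class 1
      schedules[[s]] <- condition_schedule(conds[keep],
                                           pmax(per_subj[s, keep], 1L) * window_s)
    }
  } else {
    for (s in seq_len(n_subjects)) schedules[[s]] <- schedule_template
  }

  with_seed(seed, {
    subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    records <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      prof <- profile_template
      prof$subject_id <- sprintf("S%02d", s)
      prof$baseline_hr <- stats::runif(1, 62, 78)
      prof$hr_shift <- prof$hr_shift + stats::runif(length(prof$hr_shift), -2, 2)
      prof$hr_shift[1] <- 0
      prof$noise_sd <- prof$noise_sd * stats::runif(1, 0.8, 1.2)
      prof$wander_amplitude <- prof$wander_amplitude * stats::runif(1, 0.7, 1.3)
      prof$amplitude_gain <- prof$amplitude_gain * stats::runif(1, 0.9, 1.1)
      records[[s]] <- gen_ecg_record(prof, schedules[[s]], fs = fs, seed = subj_seeds[s])
    }
    records
  })
}

#' Write / read an ECG record as CSV + JSON sidecar
#'
#' `write_ecg_record` writes `<basepath>.csv` with columns `value,label` and
#' `<basepath>.json` holding the sampling rate, subject id and metadata.
#'
#' @param rec An [ecg_record()].
#' @param basepath Path without extension.
#' @return `write_ecg_record` returns `basepath` invisibly; `read_ecg_record`
#'   returns an [ecg_record()].
#' @export
write_ecg_record <- function(rec, basepath) {
  stopifnot(inherits(rec, "ecg_record"))
  utils::write.csv(data.frame(value = rec$signal, label = rec$labels),
                   paste0(basepath, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, fs = rec$fs,
         metadata = as.list(rec$metadata), r_peaks = rec$r_peaks),
    paste0(basepath, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(basepath)
}

#' @rdname write_ecg_record
#' @export
read_ecg_record <- function(basepath) {
  d <- utils::read.csv(paste0(basepath, ".csv"))
  meta <- jsonlite::read_json(paste0(basepath, ".json"), simplifyVector = TRUE)
  ecg_record(signal = d$value, labels = d$label, fs = meta$fs,
             subject_id = meta$subject_id,
             metadata = unlist(meta$metadata) %||% character(),
             r_peaks = meta$r_peaks)
}
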