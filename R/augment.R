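#' Label-free ECG segment augmentations
#'
#' Six stochastic transformations used to create the altered view `x'` of a
#' segment for contrastive pretraining: amplitude scaling, negation,
#' horizontal flipping (time reversal), additive Gaussian noise at a target
#' SNR, chunk permutation, and smooth time warping. All operators preserve
#' segment length; `negate`/`hflip` are involutions and `permute`/`hflip`
#' preserve the value multiset.
#'
#' @param x Numeric segment.
#' @param factor_range Scaling factor range `(lo, hi)`, `0 < lo <= hi`; the
#'   factor is drawn uniformly.
#' @param seed Optional seed; `NULL` draws from the ambient RNG stream (used
#'   by the pretraining loop for fresh views every epoch).
#' @return The transformed segment, same length as `x`.
#' @name augmentations
NULL

#' @rdname augmentations
#' @export
aug_scale <- function(x, factor_range = c(0.5, 2.0), seed = NULL) {
  if (factor_range[1] <= 0 || factor_range[2] < factor_range[1]) {
    stop("scaling factors must be positive with lo <= hi", call. = FALSE)
  }
  with_seed(seed, stats::runif(1, factor_range[1], factor_range[2]) * x)
}

#' @rdname augmentations
#' @export
aug_negate <- function(x, seed = NULL) -x

#' @rdname augmentations
#' @export
aug_hflip <- function(x, seed = NULL) rev(x)

#' @rdname augmentations
#' @param snr_db Target signal-to-noise ratio in dB; the added white Gaussian
#'   noise has power `power(x) / 10^(snr_db/10)`.
#' @export
aug_noise_snr <- function(x, snr_db = 15, seed = NULL) {
  p <- mean(x^2)
  if (p == 0) stop("zero-power segment; SNR noise undefined", call. = FALSE)
  sigma <- sqrt(p / 10^(snr_db / 10))
  with_seed(seed, x + stats::rnorm(length(x), 0, sigma))
}

#' @rdname augmentations
#' @param n_segments Number of contiguous chunks to shuffle (>= 2; 1 is the
#'   identity).
#' @export
aug_permute <- function(x, n_segments = 20, seed = NULL) {
  L <- length(x)
  if (n_segments == 1) return(x)
  if (n_segments < 1 || n_segments > L) {
    stop("`n_segments` must lie in [1, length(x)]", call. = FALSE)
  }
  bounds <- floor(seq(0, L, length.out = n_segments + 1))
  with_seed(seed, {
    ord <- sample.int(n_segments)
    unlist(lapply(ord, function(k) x[(bounds[k] + 1L):bounds[k + 1L]]),
           use.names = FALSE)
  })
}

#' @rdname augmentations
#' @param n_knots Number of interior knots of the warp (>= 1).
#' @param warp_sd SD of the knot speeds around 1 (>= 0; 0 is the identity
#'   warp). Speeds are drawn `N(1, warp_sd^2)` and clipped positive, a cubic
#'   spline interpolates them to a smooth instantaneous rate, and the segment
#'   is re-read along the cumulative (monotone) time map and re-interpolated
#'   to its original length.
#' @export
aug_timewarp <- function(x, n_knots = 4, warp_sd = 0.2, seed = NULL) {
  if (n_knots < 1) stop("`n_knots` must be >= 1", call. = FALSE)
  if (warp_sd < 0) stop("`warp_sd` must be >= 0", call. = FALSE)
  L <- length(x)
  if (warp_sd == 0) return(x)
  with_seed(seed, {
    anchors <- seq(0, 1, length.out = n_knots + 2L)
    speeds <- pmax(stats::rnorm(n_knots + 2L, 1, warp_sd), 0.05)
    v <- stats::spline(anchors, speeds, xout = seq(0, 1, length.out = L))$y
    v <- pmax(v, 0.05)
    cum <- cumsum(v)
    pos <- 1 + (cum - cum[1]) / (cum[L] - cum[1]) * (L - 1)
    stats::approx(seq_len(L), x, xout = pos)$y
  })
}

.aug_registry <- list(
  scale = aug_scale, negate = aug_negate, hflip = aug_hflip,
  noise_snr = aug_noise_snr, timewarp = aug_timewarp, permute = aug_permute
)

#' Augmentation specification
#'
#' An ordered list of one or two named operators (with optional parameter
#' overrides) applied sequentially to every segment, plus a seed.
#'
#' @param ops Either a character vector of operator names (e.g.
#'   `c("timewarp", "scale")`, the composition found most effective for
#'   affect detection) or a list of `list(name =, params = list(...))`.
#' @param seed Integer seed used by [apply_spec()].
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(ops, seed = 1) {
  if (is.character(ops)) ops <- lapply(ops, function(nm) list(name = nm, params = list()))
  if (length(ops) < 1L || length(ops) > 2L) {
    stop("an augmentation spec holds one or two operators", call. = FALSE)
  }
  for (op in ops) {
    if (!op$name %in% names(.aug_registry)) {
      stop(sprintf("unknown augmentation '%s' (known: %s)", op$name,
                   paste(names(.aug_registry), collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(ops = ops, seed = seed), class = "augmentation_spec")
}

#' Parse a `"name"` or `"name1+name2"` string into an [augmentation_spec()]
#'
#' @param s String such as `"timewarp+scale"`.
#' @param seed Seed for the resulting spec.
#' @return An [augmentation_spec()].
#' @export
parse_augment <- function(s, seed = 1) {
  augmentation_spec(strsplit(s, "+", fixed = TRUE)[[1]], seed = seed)
}

# Apply the spec's operators (in order) to each row of a matrix using the
# ambient RNG stream: every row gets fresh random draws.
apply_ops_matrix <- function(ops, m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    for (op in ops) {
      f <- .aug_registry[[op$name]]
      row <- do.call(f, c(list(row), op$params))
    }
    out[i, ] <- row
  }
  out
}

#' Apply an augmentation spec to every segment
#'
#' Each row of `segs` is transformed by `spec$ops` in order with fresh random
#' draws per row; row `i` of the output is the altered view `x'` of row `i`
#' of the input. Labels and subject ids are carried through unchanged.
#'
#' @param spec An [augmentation_spec()].
#' @param segs A [segment_set()].
#' @return A [segment_set()] of altered views, row-aligned with the input.
#' @export
apply_spec <- function(spec, segs) {
  stopifnot(inherits(spec, "augmentation_spec"), inherits(segs, "segment_set"))
  out <- with_seed(spec$seed, apply_ops_matrix(spec$ops, segs$segments))
  segment_set(out, segs$labels, segs$subject_ids, segs$fs, segs$window_s)
}
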