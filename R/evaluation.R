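#' Random shuffled train/test split
#'
#' Disjoint, exhaustive index sets with `round(n * test_ratio)` test rows
#' (clamped so both sides are non-empty); the permutation is deterministic
#' given `fold_seed`.
#'
#' @param n Number of rows (>= 2).
#' @param test_ratio Held-out fraction, strictly between 0 and 1. Note the
#'   protocol convention: a "70-30" experiment holds out 70% for testing and
#'   trains on 30%.
#' @param fold_seed Integer seed for this fold's permutation.
#' @return A list with integer vectors `train` and `test`.
#' @export
shuffle_split <- function(n, test_ratio, fold_seed = 1L) {
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (test_ratio <= 0 || test_ratio >= 1) {
    stop("`test_ratio` must lie strictly between 0 and 1", call. = FALSE)
  }
  n_test <- min(n - 1L, max(1L, round(n * test_ratio)))
  with_seed(fold_seed, {
    perm <- sample.int(n)
    list(train = sort(perm[(n_test + 1L):n]), test = sort(perm[seq_len(n_test)]))
  })
}

#' Fold report container
#'
#' @param test_ratio Held-out fraction used.
#' @param fold_accuracies Accuracy per fold.
#' @param confusion C x C count matrix pooled over folds (rows = true class).
#' @param config_echo List echoing the full run configuration.
#' @return An object of class `fold_report` with `mean_accuracy` and
#'   `sd_accuracy` (computed over fold accuracies, not pooled predictions).
#' @export
fold_report <- function(test_ratio, fold_accuracies, confusion, config_echo = list()) {
  structure(list(test_ratio = test_ratio,
                 fold_accuracies = fold_accuracies,
                 mean_accuracy = mean(fold_accuracies),
                 sd_accuracy = stats::sd(fold_accuracies),
                 confusion = confusion,
                 config_echo = config_echo),
            class = "fold_report")
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("<fold_report> %d folds @ test ratio %.2f: accuracy %.2f%% +/- %.2f%%\n",
              length(x$fold_accuracies), x$test_ratio,
              100 * x$mean_accuracy, 100 * x$sd_accuracy))
  invisible(x)
}

# Generic repeated-random-split evaluation driver.
# fold_fn(train_idx, test_idx, fold_seed) must return predicted labels for
# test_idx (NA entries are excluded from accuracy and confusion counts).
# A fold whose training half misses a class is re-drawn (at most 5 times).
run_folds <- function(n, labels, test_ratio, n_folds, base_seed, fold_fn,
                      config_echo = list(), subject_ids = NULL, subject_wise = FALSE) {
  classes <- sort(unique(labels))
  C_ <- length(classes)
  conf <- matrix(0L, C_, C_, dimnames = list(true = classes, pred = classes))
  seeds <- with_seed(base_seed, sample.int(2^30, n_folds * 6L))
  accs <- numeric(n_folds)
  si <- 0L
  for (f in seq_len(n_folds)) {
    for (attempt in seq_len(6L)) {
      si <- si + 1L
      fold_seed <- seeds[si]
      sp <- if (subject_wise) {
        subject_split(subject_ids, test_ratio, fold_seed)
      } else {
        shuffle_split(n, test_ratio, fold_seed)
      }
      if (length(unique(labels[sp$train])) == C_) break
      if (attempt == 6L) stop("could not draw a fold with every class in training after 5 redraws",
                              call. = FALSE)
    }
    pred <- fold_fn(sp$train, sp$test, fold_seed)
    truth <- labels[sp$test]
    ok <- !is.na(pred)
    accs[f] <- mean(pred[ok] == truth[ok])
    tab <- table(factor(truth[ok], levels = classes),
                 factor(pred[ok], levels = classes))
    conf <- conf + as.matrix(tab)
  }
  fold_report(test_ratio, accs, conf, config_echo)
}

# Split whole subjects between train and test (leakage-safe alternative to
# the segment-level protocol).
subject_split <- function(subject_ids, test_ratio, fold_seed) {
  subs <- unique(subject_ids)
  if (length(subs) < 2L) stop("subject-wise split needs >= 2 subjects", call. = FALSE)
  n_test <- min(length(subs) - 1L, max(1L, round(length(subs) * test_ratio)))
  with_seed(fold_seed, {
    test_subs <- sample(subs, n_test)
    list(train = which(!subject_ids %in% test_subs),
         test = which(subject_ids %in% test_subs))
  })
}

#' Evaluate a pipeline under the repeated random-split protocol
#'
#' Runs `n_folds` independent random train/test splits at `test_ratio`
#' (Monte-Carlo cross-validation: the ratio sweep of the ablation studies is
#' incompatible with partition-based k-fold). Per fold the chosen pipeline is
#' trained on the training half and scored on the held-out half; accuracies
#' are aggregated as mean and standard deviation over folds, and a pooled
#' confusion matrix is accumulated. Splits are segment-level by default
#' (matching the protocol; `subject_wise = TRUE` gives the leakage-safe
#' variant).
#'
#' Pipelines: `"contrastive-ssl"` initializes the classifier from a
#' pretrained encoder (pretraining once on all segments when `pretrained` is
#' NULL - upstream training uses no labels), `"supervised"` trains the same
#' architecture from random initialization, `"hrv-svm"` extracts HRV features
#' and fits an RBF SVM. A function `pipeline(train_set, test_set, fold_seed)`
#' returning predicted labels is also accepted.
#'
#' @param segs A labeled [segment_set()].
#' @param pipeline One of `"contrastive-ssl"`, `"supervised"`, `"hrv-svm"`,
#'   or a function.
#' @param test_ratio Held-out fraction per fold.
#' @param n_folds Number of random splits (default 10).
#' @param base_seed Base RNG seed; the full run is deterministic given it.
#' @param encoder_cfg [encoder_config()] for the CNN pipelines.
#' @param aug_spec [augmentation_spec()] used when pretraining is needed.
#' @param upstream_cfg [train_config()] for pretraining.
#' @param downstream_cfg [train_config()] for fine-tuning.
#' @param pretrained Optional `encoder_weights` to reuse across folds.
#' @param svm_cost SVM cost parameter for `"hrv-svm"`.
#' @param subject_wise Split whole subjects instead of segments.
#' @return A [fold_report()].
#' @export
evaluate_pipeline <- function(segs, pipeline, test_ratio, n_folds = 10L,
                              base_seed = 1L,
                              encoder_cfg = NULL, aug_spec = NULL,
                              upstream_cfg = train_config(1e-4, 32L, 20L),
                              downstream_cfg = train_config(1e-3, 128L, 150L),
                              pretrained = NULL, svm_cost = 1,
                              subject_wise = FALSE) {
  stopifnot(inherits(segs, "segment_set"))
  n <- nrow(segs$segments)
  labels <- segs$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("segments must cover at least 2 classes", call. = FALSE)
  if (is.null(encoder_cfg) && !is.function(pipeline) && pipeline != "hrv-svm") {
    encoder_cfg <- encoder_config(input_length = ncol(segs$segments))
  }

  echo <- list(pipeline = if (is.function(pipeline)) "custom" else pipeline,
               test_ratio = test_ratio, n_folds = n_folds, base_seed = base_seed,
               subject_wise = subject_wise,
               encoder = encoder_cfg, upstream = upstream_cfg,
               downstream = downstream_cfg,
               augment = if (!is.null(aug_spec)) {
                 vapply(aug_spec$ops, `[[`, character(1), "name")
               })

  if (is.function(pipeline)) {
    fold_fn <- function(train_idx, test_idx, fold_seed) {
      pipeline(subset_segments(segs, train_idx), subset_segments(segs, test_idx),
               fold_seed)
    }
  } else if (pipeline == "hrv-svm") {
    feats <- hrv_segment_features(segs)
    keep_col <- vapply(feats, function(cc) !all(is.na(cc)), logical(1))
    F_ <- as.matrix(feats[, keep_col, drop = FALSE])
    valid <- stats::complete.cases(F_)
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
                   kernel = "radial", cost = svm_cost, scale = FALSE))
      p <- stats::predict(fit, scale(F_[te, , drop = FALSE], mu, sg))
      pred[match(te, test_idx)] <- as.integer(as.character(p))
      pred
    }
  } else if (pipeline %in% c("contrastive-ssl", "supervised")) {
    if (pipeline == "contrastive-ssl" && is.null(pretrained)) {
      if (is.null(aug_spec)) stop("`aug_spec` is required to pretrain", call. = FALSE)
      ucfg <- upstream_cfg; ucfg$seed <- base_seed
      pretrained <- pretrain(segs, aug_spec, ecfg = encoder_cfg,
                             tcfg = ucfg)$weights
    }
    fold_fn <- function(train_idx, test_idx, fold_seed) {
      init <- if (pipeline == "contrastive-ssl") pretrained else "random"
      model <- build_classifier(encoder_cfg, n_classes = length(classes),
                                init = init, seed = fold_seed)
      dcfg <- downstream_cfg; dcfg$seed <- fold_seed
      fit <- finetune(model, subset_segments(segs, train_idx), tcfg = dcfg)
      stats::predict(fit$model, subset_segments(segs, test_idx))$labels
    }
  } else {
    stop(sprintf("unknown pipeline '%s'", pipeline), call. = FALSE)
  }

  run_folds(n, labels, test_ratio, n_folds, base_seed, fold_fn,
            config_echo = echo, subject_ids = segs$subject_ids,
            subject_wise = subject_wise)
}

#' Test-train-ratio ablation
#'
#' For each single augmentation (plus a no-augmentation control) and each
#' held-out ratio: pretrain with that augmentation, fine-tune at the ratio,
#' and evaluate. The control column trains the downstream model from random
#' initialization with the same seeds, so at each ratio it equals the fully
#' supervised baseline by construction.
#'
#' @param segs A labeled [segment_set()].
#' @param augmentations Named list of [augmentation_spec()] objects; an
#'   entry named `"none"` (or a NULL element) is the control.
#' @param ratios Held-out fractions to sweep (default 0.1 ... 0.9).
#' @param n_folds Folds per cell.
#' @param base_seed Base RNG seed.
#' @param encoder_cfg,upstream_cfg,downstream_cfg Configurations shared by
#'   all cells.
#' @return A data frame of mean accuracies, one row per ratio and one column
#'   per augmentation (control first); per-cell [fold_report()]s are attached
#'   as attribute `"reports"`.
#' @export
ratio_ablation <- function(segs,
                           augmentations = c(list(none = NULL),
                                             stats::setNames(lapply(names(.aug_registry),
                                                                    augmentation_spec),
                                                             names(.aug_registry))),
                           ratios = seq(0.1, 0.9, by = 0.1),
                           n_folds = 10L, base_seed = 1L,
                           encoder_cfg = encoder_config(ncol(segs$segments)),
                           upstream_cfg = train_config(1e-4, 32L, 20L),
                           downstream_cfg = train_config(1e-3, 128L, 150L)) {
  res <- matrix(NA_real_, length(ratios), length(augmentations),
                dimnames = list(sprintf("%.1f", ratios), names(augmentations)))
  reports <- list()
  for (ai in seq_along(augmentations)) {
    spec <- augmentations[[ai]]
    pretrained <- NULL
    if (!is.null(spec)) {
      ucfg <- upstream_cfg; ucfg$seed <- base_seed
      pretrained <- pretrain(segs, spec, ecfg = encoder_cfg, tcfg = ucfg)$weights
    }
    for (ri in seq_along(ratios)) {
      rep_ <- evaluate_pipeline(
        segs,
        pipeline = if (is.null(spec)) "supervised" else "contrastive-ssl",
        test_ratio = ratios[ri], n_folds = n_folds, base_seed = base_seed,
        encoder_cfg = encoder_cfg, downstream_cfg = downstream_cfg,
        pretrained = pretrained)
      res[ri, ai] <- rep_$mean_accuracy
      reports[[paste(names(augmentations)[ai], ratios[ri], sep = "@")]] <- rep_
    }
  }
  out <- as.data.frame(res)
  attr(out, "reports") <- reports
  out
}

#' Augmentation-composition ablation grid
#'
#' Cell (i, j) pretrains with augmentation i followed by augmentation j
#' (diagonal cells use the single augmentation) and reports the fine-tuned
#' mean accuracy at the stated split. Order matters, so the grid is not
#' symmetric. The default ratio holds out 70% (the "70-30" protocol where
#' pretraining helps most).
#'
#' @param segs A labeled [segment_set()].
#' @param aug_names Augmentation names forming the grid axes.
#' @param test_ratio Held-out fraction (default 0.7).
#' @param n_folds Folds per cell.
#' @param base_seed Base RNG seed.
#' @param encoder_cfg,upstream_cfg,downstream_cfg Shared configurations.
#' @return A `length(aug_names)` square matrix of mean accuracies (first
#'   augmentation on rows), with per-cell reports as attribute `"reports"`.
#' @export
augmentation_grid <- function(segs,
                              aug_names = names(.aug_registry),
                              test_ratio = 0.7, n_folds = 10L, base_seed = 1L,
                              encoder_cfg = encoder_config(ncol(segs$segments)),
                              upstream_cfg = train_config(1e-4, 32L, 20L),
                              downstream_cfg = train_config(1e-3, 128L, 150L)) {
  k <- length(aug_names)
  res <- matrix(NA_real_, k, k, dimnames = list(first = aug_names, second = aug_names))
  reports <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ops <- if (i == j) aug_names[i] else c(aug_names[i], aug_names[j])
      spec <- augmentation_spec(ops)
      rep_ <- evaluate_pipeline(segs, "contrastive-ssl", test_ratio = test_ratio,
                                n_folds = n_folds, base_seed = base_seed,
                                encoder_cfg = encoder_cfg, aug_spec = spec,
                                upstream_cfg = upstream_cfg,
                                downstream_cfg = downstream_cfg)
      res[i, j] <- rep_$mean_accuracy
      reports[[paste(ops, collapse = "+")]] <- rep_
    }
  }
  attr(res, "reports") <- reports
  res
}
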