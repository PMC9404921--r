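#' Default run configuration
#'
#' Full-pipeline defaults: 256 Hz, 0.8 Hz high-pass, 10 s windows, the
#' timewarp-then-scale augmentation pair, the standard encoder (filters
#' 32/64/128, kernels 32/16/8), upstream Adam at 1e-4 (20 epochs, batch 32,
#' temperature 0.1) and downstream Adam at 1e-3 (250 epochs, batch 128).
#' For short-record three-level stress studies the 5 s window / 25 upstream /
#' 150 downstream epoch variant can be set in the YAML file.
#'
#' @return A nested list of defaults (see [load_config()]).
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "runs",
    synth = list(n_subjects = 4L, fs = 256, schedule = "0:120,1:90,2:60"),
    preprocess = list(fs_out = 256, highpass_hz = 0.8, clip_sd = 10,
                      window_s = 10, stride_s = 0, smote = FALSE,
                      smote_train_only = FALSE),  # stride 0 = non-overlapping
    augment = list(list(name = "timewarp", params = list()),
                   list(name = "scale", params = list())),
    encoder = list(filters = c(32L, 64L, 128L), kernels = c(32L, 16L, 8L),
                   pool_size = 4L, dropout_rate = 0.1, dense_units = 80L,
                   l2_coeff = 3.0),
    projection = list(units = 256L, activation = "softmax"),
    upstream = list(learning_rate = 1e-4, batch_size = 32L, epochs = 20L,
                    temperature = 0.1),
    downstream = list(learning_rate = 1e-3, batch_size = 128L, epochs = 250L),
    evaluation = list(n_folds = 10L, test_ratio = 0.1, subject_wise = FALSE)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration key `%s`", full), call. = FALSE)
    }
    if (key == "augment") {
      defaults[[key]] <- user[[key]]
    } else if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid configuration at `%s`: %s", field, msg), call. = FALSE)
  }
  chk(cfg$upstream$temperature > 0, "upstream.temperature", "must be positive")
  chk(cfg$upstream$learning_rate > 0, "upstream.learning_rate", "must be positive")
  chk(cfg$downstream$learning_rate > 0, "downstream.learning_rate", "must be positive")
  chk(cfg$preprocess$window_s > 0, "preprocess.window_s", "must be positive")
  chk(cfg$preprocess$highpass_hz > 0, "preprocess.highpass_hz", "must be positive")
  chk(cfg$evaluation$test_ratio > 0 && cfg$evaluation$test_ratio < 1,
      "evaluation.test_ratio", "must lie strictly between 0 and 1")
  chk(cfg$synth$n_subjects >= 1, "synth.n_subjects", "must be >= 1")
  for (op in cfg$augment) {
    chk(!is.null(op$name) && op$name %in% names(.aug_registry),
        "augment", sprintf("unknown augmentation '%s'", op$name %||% "<missing name>"))
  }
  invisible(cfg)
}

#' Load and validate a YAML run configuration
#'
#' Missing keys fall back to [default_run_config()]; unknown keys and invalid
#' values are rejected with the offending field path. An empty (or NULL) file
#' yields the all-defaults configuration.
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

#' Save a run configuration as YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

parse_schedule <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  condition_schedule(vapply(parts, function(p) as.integer(p[1]), integer(1)),
                     vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

config_to_specs <- function(cfg, input_length) {
  list(
    encoder = encoder_config(input_length = input_length,
                             filters = cfg$encoder$filters,
                             kernels = cfg$encoder$kernels,
                             pool_size = cfg$encoder$pool_size,
                             dropout_rate = cfg$encoder$dropout_rate,
                             dense_units = cfg$encoder$dense_units,
                             l2_coeff = cfg$encoder$l2_coeff),
    projection = projection_config(units = cfg$projection$units,
                                   activation = cfg$projection$activation),
    upstream = train_config(cfg$upstream$learning_rate, cfg$upstream$batch_size,
                            cfg$upstream$epochs, cfg$upstream$temperature,
                            seed = cfg$seed),
    downstream = train_config(cfg$downstream$learning_rate,
                              cfg$downstream$batch_size,
                              cfg$downstream$epochs, seed = cfg$seed),
    augment = augmentation_spec(lapply(cfg$augment, function(op) {
      list(name = op$name, params = op$params %||% list())
    }), seed = cfg$seed)
  )
}

#' Serialize encoder weights to a JSON archive
#'
#' Writes parameter arrays together with a shape manifest and the
#' architecture configuration, at full double precision.
#'
#' @param w An `encoder_weights` object.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_weights <- function(w, path) {
  stopifnot(inherits(w, "encoder_weights"))
  payload <- list(
    config = unclass(w$config),
    manifest = lapply(w$params, function(p) dim(p) %||% length(p)),
    params = lapply(w$params, function(p) {
      if (is.matrix(p)) unclass(p) else as.numeric(p)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(encoder_config, payload$config[c("input_length", "filters",
                                                  "kernels", "pool_size",
                                                  "dropout_rate", "dense_units",
                                                  "l2_coeff")])
  params <- payload$params
  for (nm in names(params)) {
    want <- unlist(payload$manifest[[nm]])
    p <- params[[nm]]
    if (length(want) == 2L) {
      if (!is.matrix(p)) p <- matrix(as.numeric(p), want[1], want[2], byrow = TRUE)
      if (!all(dim(p) == want)) {
        stop(sprintf("weight archive shape mismatch at '%s'", nm), call. = FALSE)
      }
    } else {
      p <- as.numeric(p)
    }
    params[[nm]] <- p
  }
  structure(list(config = cfg, params = params, shapes = encoder_shapes(cfg)),
            class = "encoder_weights")
}

#' Run a configured end-to-end experiment
#'
#' Executes synthesize -> preprocess -> pretrain -> fine-tune/evaluate and
#' writes a report bundle into `cfg$out_dir`: the echoed configuration and
#' its hash, the fold report (JSON) with confusion matrix (CSV), upstream
#' loss curve (CSV), encoder weights (JSON) and a log of every seed used.
#'
#' @param cfg A configuration from [load_config()].
#' @param dry_run Validate and echo the plan without computing.
#' @return Invisibly, a list with the `fold_report`, the pretrain result and
#'   the output directory.
#' @export
run_experiment <- function(cfg, dry_run = FALSE) {
  validate_config(cfg)
  if (dry_run) {
    message("configuration valid; dry run requested, nothing computed")
    return(invisible(list(config = cfg)))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  schedule <- parse_schedule(cfg$synth$schedule)
  records <- gen_dataset(cfg$synth$n_subjects, schedule, fs = cfg$synth$fs,
                         seed = cfg$seed)
  segs <- preprocess_records(records, fs_out = cfg$preprocess$fs_out,
                             highpass_hz = cfg$preprocess$highpass_hz,
                             clip_sd = cfg$preprocess$clip_sd,
                             window_s = cfg$preprocess$window_s,
                             stride_s = if (cfg$preprocess$stride_s > 0) {
                               cfg$preprocess$stride_s
                             } else cfg$preprocess$window_s,
                             smote = isTRUE(cfg$preprocess$smote) &&
                               !isTRUE(cfg$preprocess$smote_train_only),
                             seed = cfg$seed)

  sp <- config_to_specs(cfg, input_length = ncol(segs$segments))
  pre <- pretrain(segs, sp$augment, ecfg = sp$encoder, pcfg = sp$projection,
                  tcfg = sp$upstream)
  report <- evaluate_pipeline(segs, "contrastive-ssl",
                              test_ratio = cfg$evaluation$test_ratio,
                              n_folds = cfg$evaluation$n_folds,
                              base_seed = cfg$seed,
                              encoder_cfg = sp$encoder,
                              downstream_cfg = sp$downstream,
                              pretrained = pre$weights,
                              subject_wise = isTRUE(cfg$evaluation$subject_wise))

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  save_config(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = cfg$seed,
         test_ratio = report$test_ratio,
         fold_accuracies = report$fold_accuracies,
         mean_accuracy = report$mean_accuracy,
         sd_accuracy = report$sd_accuracy),
    file.path(cfg$out_dir, "fold_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(cfg$out_dir, "confusion.csv"), row.names = FALSE)
  utils::write.csv(data.frame(epoch = seq_along(pre$loss_history),
                              nt_xent = pre$loss_history),
                   file.path(cfg$out_dir, "upstream_loss.csv"), row.names = FALSE)
  save_weights(pre$weights, file.path(cfg$out_dir, "encoder_weights.json"))
  writeLines(c(sprintf("config_hash: %s", cfg_hash),
               sprintf("seed: %d", cfg$seed),
               sprintf("segments: %d", nrow(segs$segments)),
               sprintf("mean_accuracy: %.4f", report$mean_accuracy)),
             file.path(cfg$out_dir, "run.log"))
  invisible(list(report = report, pretrain = pre, out_dir = cfg$out_dir))
}
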