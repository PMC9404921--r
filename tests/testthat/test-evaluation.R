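test_that("shuffled splits are disjoint, exhaustive and seed-controlled", {
  sp <- shuffle_split(100, 0.1, fold_seed = 1)
  expect_length(sp$test, 10)
  expect_length(sp$train, 90)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  sp2 <- shuffle_split(100, 0.1, fold_seed = 2)
  expect_false(identical(sp$test, sp2$test))
  expect_identical(shuffle_split(100, 0.1, fold_seed = 1), sp)
  expect_error(shuffle_split(1, 0.5), ">= 2")
  expect_error(shuffle_split(10, 1.5), "between 0 and 1")
})

test_that("oracle and random pipelines bracket the accuracy range", {
  segs <- make_sine_segments(120, 64, n_classes = 4L, seed = 3)
  oracle <- function(train_set, test_set, fold_seed) test_set$labels
  rep1 <- evaluate_pipeline(segs, oracle, test_ratio = 0.25, n_folds = 5,
                            base_seed = 7)
  expect_equal(rep1$mean_accuracy, 1.0)
  expect_equal(rep1$sd_accuracy, 0)
  expect_true(all(diag(rep1$confusion) == rowSums(rep1$confusion)))

  rand <- function(train_set, test_set, fold_seed) {
    with_seed(fold_seed, sample(0:3, nrow(test_set$segments), replace = TRUE))
  }
  rep2 <- evaluate_pipeline(segs, rand, test_ratio = 0.25, n_folds = 10,
                            base_seed = 9)
  expect_lt(abs(rep2$mean_accuracy - 0.25), max(3 * rep2$sd_accuracy, 0.15))

  # count conservation: pooled confusion total = sum of fold test sizes
  expect_equal(sum(rep2$confusion), 10 * 30)
})

test_that("full evaluation runs are deterministic given the base seed", {
  segs <- make_sine_segments(60, 64, seed = 5)
  noisy <- function(train_set, test_set, fold_seed) {
    with_seed(fold_seed, sample(0:2, nrow(test_set$segments), replace = TRUE))
  }
  r1 <- evaluate_pipeline(segs, noisy, test_ratio = 0.3, n_folds = 4, base_seed = 11)
  r2 <- evaluate_pipeline(segs, noisy, test_ratio = 0.3, n_folds = 4, base_seed = 11)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("subject-wise splitting keeps subjects exclusive to one side", {
  segs <- make_sine_segments(80, 64, seed = 6)
  probe <- function(train_set, test_set, fold_seed) {
    expect_length(intersect(unique(train_set$subject_ids),
                            unique(test_set$subject_ids)), 0)
    test_set$labels
  }
  evaluate_pipeline(segs, probe, test_ratio = 0.3, n_folds = 3, base_seed = 2,
                    subject_wise = TRUE)
  succeed()
})

test_that("CNN pipelines run end to end and SSL reuses the pretrained encoder", {
  cfg <- tiny_encoder_cfg()
  segs <- make_sine_segments(48, 128, n_classes = 2L, sep = 3, seed = 8)
  pre <- pretrain(segs, augmentation_spec("timewarp"), ecfg = cfg,
                  pcfg = projection_config(8L),
                  tcfg = train_config(1e-3, 8L, 2L, 0.1, seed = 4))
  rep_ <- evaluate_pipeline(segs, "contrastive-ssl", test_ratio = 0.3,
                            n_folds = 2, base_seed = 3, encoder_cfg = cfg,
                            pretrained = pre$weights,
                            downstream_cfg = train_config(1e-3, 16L, 8L))
  expect_length(rep_$fold_accuracies, 2)
  expect_true(all(rep_$fold_accuracies >= 0 & rep_$fold_accuracies <= 1))
  expect_identical(rep_$config_echo$pipeline, "contrastive-ssl")
})

test_that("hrv-svm pipeline classifies rate-contrasted synthetic segments", {
  prof <- subject_profile(baseline_hr = 62, hr_shift = c("0" = 0, "2" = 25),
                          rr_jitter_sd = c("0" = 0.04, "2" = 0.015),
                          noise_sd = 0.03)
  recs <- lapply(1:2, function(s) {
    prof$subject_id <- paste0("S", s)
    gen_ecg_record(prof, condition_schedule(c(0L, 2L), c(100, 100)), fs = 128,
                   seed = 40 + s)
  })
  segs <- window_records(zscore_per_subject(recs), window_s = 10)
  rep_ <- evaluate_pipeline(segs, "hrv-svm", test_ratio = 0.3, n_folds = 3,
                            base_seed = 6)
  expect_gt(rep_$mean_accuracy, 0.8)
})

test_that("ratio ablation table has the stated layout and a supervised control", {
  cfg <- tiny_encoder_cfg()
  segs <- make_sine_segments(40, 128, n_classes = 2L, sep = 3, seed = 10)
  augs <- list(none = NULL, timewarp = augmentation_spec("timewarp"))
  tab <- ratio_ablation(segs, augs, ratios = c(0.3, 0.6), n_folds = 2,
                        base_seed = 13, encoder_cfg = cfg,
                        upstream_cfg = train_config(1e-3, 8L, 1L),
                        downstream_cfg = train_config(1e-3, 16L, 4L))
  expect_equal(dim(tab), c(2L, 2L))
  expect_identical(colnames(tab), c("none", "timewarp"))
  expect_true(all(unlist(tab) >= 0 & unlist(tab) <= 1))

  sup <- supervised_baseline(segs, ecfg = cfg,
                             tcfg = train_config(1e-3, 16L, 4L),
                             test_ratio = 0.3, n_folds = 2, base_seed = 13)
  expect_equal(tab["0.3", "none"], sup$mean_accuracy)  # definitional equality
})

test_that("augmentation grid covers ordered compositions on the diagonal convention", {
  cfg <- tiny_encoder_cfg()
  segs <- make_sine_segments(30, 128, n_classes = 2L, sep = 3, seed = 12)
  g <- augmentation_grid(segs, aug_names = c("negate", "scale"), test_ratio = 0.5,
                         n_folds = 1, base_seed = 3, encoder_cfg = cfg,
                         upstream_cfg = train_config(1e-3, 8L, 1L),
                         downstream_cfg = train_config(1e-3, 8L, 3L))
  expect_equal(dim(g), c(2L, 2L))
  expect_identical(rownames(g), c("negate", "scale"))
  expect_true(all(g >= 0 & g <= 1))
  expect_length(attr(g, "reports"), 4)
})
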