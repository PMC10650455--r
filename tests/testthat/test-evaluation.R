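test_that("metrics match the closed forms on the worked example", {
  m <- compute_metrics(list(tp = 2, tn = 6, fp = 1, fn = 1))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  perfect <- compute_metrics(list(tp = 7, tn = 0, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
})

test_that("metrics agree with brute-force recounting of prediction pairs", {
  withr::with_seed(20, {
    for (rep in 1:200) {
      n <- sample(1:60, 1)
      truth <- rbinom(n, 1, 0.5)
      pred <- rbinom(n, 1, 0.5)
      counts <- confusion_counts(truth, pred)
      # independent recount straight from the pairs
      expect_equal(counts$tp, sum(truth & pred))
      expect_equal(counts$tn, sum(!truth & !pred))
      expect_equal(counts$fp, sum(!truth & pred))
      expect_equal(counts$fn, sum(truth & !pred))
      expect_equal(counts$tp + counts$tn + counts$fp + counts$fn, n)
      m <- compute_metrics(counts)
      expect_equal(m$accuracy, mean(truth == pred))
      if (!is.na(m$precision) && !is.na(m$recall) &&
          m$precision + m$recall > 0) {
        expect_equal(m$f1,
                     2 * m$precision * m$recall / (m$precision + m$recall))
      }
    }
  })
})

test_that("undefined metrics are NA, never silently zero", {
  m <- compute_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_true(is.na(m$f1))
  expect_equal(m$accuracy, 1)
  m2 <- compute_metrics(list(tp = 0, tn = 3, fp = 2, fn = 0))
  expect_equal(m2$precision, 0)
  expect_true(is.na(m2$recall))
})

test_that("random split deals each surgeon round-robin across folds", {
  co <- generate_cohort(cohort_spec(seed = 30, trials_per_surgeon = c(18, 18)))
  folded <- random_split(co, n_folds = 6, seed = 1)
  expect_setequal(folded$fold, 1:6)
  # partition: every trial in exactly one fold
  expect_equal(nrow(folded), nrow(co))
  tab <- table(folded$surgeon_id, folded$fold)
  expect_true(all(tab == 3))  # 18 trials / 6 folds
})

test_that("per-surgeon fold counts differ by at most one for any count", {
  for (n_tr in 1:20) {
    co <- generate_cohort(cohort_spec(seed = 31, n_experts = 1, n_novices = 1,
                                      trials_per_surgeon = c(n_tr, n_tr),
                                      length_range = c(30, 40)))
    folded <- random_split(co, n_folds = 6, seed = n_tr)
    tab <- table(factor(folded$fold, levels = 1:6), folded$surgeon_id)
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("LOUO split pairs one expert group with one novice per fold", {
  co <- generate_cohort(cohort_spec(seed = 32))  # 7 experts, 6 novices
  roster <- cohort_roster(co)
  experts <- roster$surgeon_id[roster$skill == "Expert"]
  smallest2 <- experts[order(roster$n_trials[roster$skill == "Expert"])][1:2]
  folded <- louo_split(co, merges = list(smallest2))
  expect_equal(length(unique(folded$fold)), 6L)
  expect_true(check_louo_leakage(folded))
  # the merged experts travel together
  expect_equal(length(unique(folded$fold[folded$surgeon_id %in% smallest2])),
               1L)
  # every fold holds exactly one novice
  for (k in 1:6) {
    nov <- unique(folded$surgeon_id[folded$fold == k &
                                      folded$skill == "Novice"])
    expect_length(nov, 1L)
  }
})

test_that("LOUO with balanced classes needs no merge; unbalanced errors", {
  co <- generate_cohort(cohort_spec(seed = 33, n_experts = 6, n_novices = 6,
                                    trials_per_surgeon = c(3, 4),
                                    length_range = c(40, 60)))
  folded <- louo_split(co)
  expect_equal(length(unique(folded$fold)), 6L)
  for (k in 1:6) {
    expect_length(unique(folded$surgeon_id[folded$fold == k]), 2L)
  }
  co2 <- generate_cohort(cohort_spec(seed = 34, n_experts = 7, n_novices = 6,
                                     trials_per_surgeon = c(2, 3),
                                     length_range = c(40, 60)))
  expect_error(louo_split(co2), "merge")
})

test_that("evaluate_fold tallies confusion counts with Expert positive", {
  co <- tiny_cohort(seed = 40, n_experts = 1, n_novices = 1,
                    trials = c(5, 5), lens = c(40, 80))
  sc <- fit_scaler(co$trace)
  # a stub fit whose model always predicts Expert
  m <- build_model("tcn", init_seed = 1)
  m$params$head.W[] <- 0
  m$params$head.b[] <- 10   # logit 10 -> prob ~ 1
  fit <- structure(list(model = m, scaler = sc), class = "skill_fit")
  ev <- evaluate_fold(fit, co)
  expect_equal(ev$counts$tp, 5)
  expect_equal(ev$counts$fp, 5)
  expect_equal(ev$counts$tn + ev$counts$fn, 0)
  # flipping predictions swaps TP<->FN and TN<->FP
  truth <- encode_skill(co$skill)
  pred <- ev$predictions$.pred
  c1 <- confusion_counts(truth, pred)
  c2 <- confusion_counts(truth, 1 - pred)
  expect_equal(c1$tp, c2$fn)
  expect_equal(c1$tn, c2$fp)
})

test_that("single-class training folds and empty test folds are rejected", {
  co <- tiny_cohort(seed = 41, n_experts = 2, n_novices = 1,
                    trials = c(2, 2), lens = c(40, 60))
  folded <- louo_split(co, merges = list(c("E1", "E2")))
  # holding out the only novice leaves single-class training data
  novice_fold <- unique(folded$fold[folded$skill == "Novice"])
  expect_error(train_one_fold(folded, novice_fold, "tcn"), "single class")
  expect_error(train_one_fold(folded, 99, "tcn"), "empty")
})

test_that("a short training run learns a separable cohort deterministically", {
  co <- tiny_cohort(seed = 42)
  folded <- random_split(co, n_folds = 3, seed = 2)
  cfg <- train_config(epochs = 3, crop_len = 60, seed = 7,
                      learning_rate = 1e-3)
  fit1 <- train_one_fold(folded, 1, "cldnn", cfg)
  fit2 <- train_one_fold(folded, 1, "cldnn", cfg)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$history, fit2$history)
  ev1 <- evaluate_fold(fit1, folded[folded$fold == 1, ])
  ev2 <- evaluate_fold(fit2, folded[folded$fold == 1, ])
  expect_identical(ev1$predictions$.prob, ev2$predictions$.prob)
  # scaler was fitted on training trials only
  sc_full <- fit_scaler(lapply(folded$trace, clip_negatives))
  expect_false(isTRUE(all.equal(fit1$scaler$mean, sc_full$mean)))
})

test_that("expert trials contribute target 1 during training", {
  expect_equal(encode_skill("Expert"), 1)
  co <- tiny_cohort(seed = 43)
  folded <- random_split(co, n_folds = 3, seed = 1)
  fit <- train_one_fold(folded, 1, "tcn",
                        train_config(epochs = 1, crop_len = 60))
  # labels seen by the loss are the 0/1 encoding of the skill column
  expect_s3_class(fit, "skill_fit")
})

test_that("benchmark report aggregates per-fold metrics consistently", {
  co <- tiny_cohort(seed = 44)
  # two epochs can leave a one-class fold, whose precision is NA by design
  bm <- suppressWarnings(
    run_benchmark(co, archs = "cldnn", scheme = "random",
                  cfg = train_config(epochs = 2, crop_len = 60,
                                     learning_rate = 1e-3),
                  n_folds = 3, seed = 5))
  expect_equal(nrow(bm$folds), 3L)
  acc <- bm$folds$accuracy
  expect_equal(bm$summary$mean[bm$summary$metric == "accuracy"], mean(acc),
               tolerance = 1e-12)
  expect_equal(bm$summary$sd[bm$summary$metric == "accuracy"], sd(acc),
               tolerance = 1e-12)
  expect_true(all(bm$folds$tp + bm$folds$tn + bm$folds$fp + bm$folds$fn ==
                    table(bm$folded$fold)[as.character(bm$folds$fold)]))
  # tidiers
  expect_equal(nrow(tidy(bm)), 3L * 4L)
  expect_equal(nrow(glance(bm)), 1L)
  expect_s3_class(autoplot(bm), "ggplot")
  d <- withr::local_tempdir()
  write_report(bm, d)
  expect_true(file.exists(file.path(d, "report.json")))
  expect_true(file.exists(file.path(d, "report.csv")))
})

test_that("augmented training runs end-to-end, including the FFT channels", {
  co <- tiny_cohort(seed = 45)
  folded <- random_split(co, n_folds = 3, seed = 2)
  cfg <- train_config(epochs = 2, crop_len = 60, learning_rate = 1e-3,
                      seed = 3)
  # FFT representation: model is built with 3 input channels and the test
  # trials are stacked the same way at evaluation
  fit <- train_one_fold(folded, 1, "cldnn", cfg,
                        augmentation = augmentation_config("fft"))
  expect_equal(fit$model$in_channels, 3L)
  ev <- evaluate_fold(fit, folded[folded$fold == 1, ])
  expect_equal(ev$counts$tp + ev$counts$tn + ev$counts$fp + ev$counts$fn,
               sum(folded$fold == 1))
  # a gated single-channel augmentation
  fit2 <- train_one_fold(folded, 1, "tcn", cfg,
                         augmentation = augmentation_config("quantize"))
  expect_equal(fit2$model$in_channels, 1L)
  ev2 <- evaluate_fold(fit2, folded[folded$fold == 1, ])
  expect_true(all(ev2$predictions$.prob >= 0 & ev2$predictions$.prob <= 1))
})
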