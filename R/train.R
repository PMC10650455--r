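# Training loop and the cross-validated benchmark driver.

#' Training configuration
#'
#' Benchmark defaults: up to 100 epochs, batch size 32, Adam with a fixed
#' learning rate of 1e-4, 300-step training crops, and 15% of the training
#' trials held out (stratified by class) for minimum-validation-loss model
#' selection.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param crop_len Training crop length in steps.
#' @param val_fraction Fraction of training trials held out for model
#'   selection; 0 disables selection (the final parameters are returned).
#' @param seed Master seed for everything derived in one fold's training run
#'   (crops, augmentation draws, initialization, batching).
#' @param early_stop_loss Optional training-loss floor; training stops once
#'   the epoch training loss falls below it (used for capacity checks).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L,
                         learning_rate = 1e-4, crop_len = 300L,
                         val_fraction = 0.15, seed = 1L,
                         early_stop_loss = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            crop_len >= 1L, val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 crop_len = as.integer(crop_len),
                 val_fraction = val_fraction,
                 seed = as.integer(seed),
                 early_stop_loss = early_stop_loss),
            class = "train_config")
}

# crop/pad + optional augmentation for one trace; returns list(x = T x C
# matrix-like vector or matrix, true_len)
make_training_example <- function(trace, cfg, augmentation) {
  cr <- crop_or_pad(trace, cfg$crop_len)
  true_len <- attr(cr, "true_len")
  attributes(cr) <- NULL
  if (!is.null(augmentation)) cr <- apply_augmentation(cr, augmentation)
  list(x = cr, true_len = true_len)
}

# assemble a list of examples into an (N, T, C) array + lens
stack_examples <- function(examples, crop_len, in_channels) {
  N <- length(examples)
  x <- array(0, c(N, crop_len, in_channels))
  lens <- integer(N)
  for (i in seq_len(N)) {
    ex <- examples[[i]]
    if (is.matrix(ex$x)) x[i, , ] <- t(ex$x) else x[i, , 1L] <- ex$x
    lens[i] <- ex$true_len
  }
  list(x = x, lens = lens)
}

#' Fit a skill model on preprocessed traces
#'
#' Core training loop: every epoch draws a fresh random crop (or zero-pads)
#' per training trial, applies the configured augmentation, and minimizes
#' binary cross-entropy with Adam. When validation traces are supplied, the
#' validation loss (computed in evaluation mode on crops fixed at the start
#' of the run) is monitored every epoch and the parameters with the minimum
#' validation loss are returned.
#'
#' All randomness is consumed from the current RNG stream; callers wanting
#' reproducibility wrap the call in `withr::with_seed()` (as
#' [train_one_fold()] does).
#'
#' @param model A freshly built `skill_model`.
#' @param traces List of preprocessed (clipped, scaled) training traces.
#' @param labels Numeric 0/1 labels (Expert = 1).
#' @param cfg A [train_config()].
#' @param val_traces,val_labels Optional validation split for model
#'   selection.
#' @param augmentation Optional [augmentation_config()].
#' @return List of class `skill_fit_core`: `model` (selected parameters),
#'   `history` (per-epoch losses), `best_epoch`.
#' @keywords internal
#' @export
fit_model <- function(model, traces, labels, cfg,
                      val_traces = NULL, val_labels = NULL,
                      augmentation = NULL) {
  stopifnot(length(traces) == length(labels), all(labels %in% c(0, 1)))
  n <- length(traces)
  opt <- adam_init(model$params)
  has_val <- !is.null(val_traces) && length(val_traces) > 0L
  if (has_val) {
    val_ex <- lapply(val_traces, make_training_example, cfg = cfg,
                     augmentation = if (!is.null(augmentation) &&
                                        augmentation$name == "fft")
                       augmentation else NULL)
    val_batch <- stack_examples(val_ex, cfg$crop_len, model$in_channels)
  }
  best_loss <- Inf
  best_model <- model
  best_epoch <- 0L
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    n_correct <- 0L
    for (b in seq_len(ceiling(n / cfg$batch_size))) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      ex <- lapply(traces[idx], make_training_example, cfg = cfg,
                   augmentation = augmentation)
      batch <- stack_examples(ex, cfg$crop_len, model$in_channels)
      y <- labels[idx]
      fw <- model_forward(model, batch$x, batch$lens, training = TRUE,
                          with_cache = TRUE)
      model <- fw$model  # refreshed normalization running stats
      l <- bce_from_logits(fw$logit, y)
      g <- model_backward(model, fw$cache, l$dlogit)
      st <- adam_step(model$params, g, opt, cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
      epoch_loss <- epoch_loss + l$loss * length(idx)
      n_correct <- n_correct + sum((fw$prob >= 0.5) == (y == 1))
    }
    epoch_loss <- epoch_loss / n
    val_loss <- NA_real_
    if (has_val) {
      vf <- model_forward(model, val_batch$x, val_batch$lens,
                          training = FALSE)
      val_loss <- bce_from_logits(vf$logit, val_labels)$loss
      if (val_loss < best_loss) {
        best_loss <- val_loss
        best_model <- model
        best_epoch <- epoch
      }
    }
    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = epoch_loss,
                                    train_acc = n_correct / n,
                                    val_loss = val_loss)
    if (!is.null(cfg$early_stop_loss) &&
        epoch_loss < cfg$early_stop_loss) break
  }
  if (!has_val) {
    best_model <- model
    best_epoch <- length(Filter(Negate(is.null), hist))
  }
  list(model = best_model, history = dplyr::bind_rows(hist),
       best_epoch = best_epoch)
}

#' Train one cross-validation fold
#'
#' Fits the preprocessing scaler on the training folds only, carves a
#' stratified validation subset for model selection, trains the requested
#' architecture, and returns everything needed to evaluate the held-out
#' fold. Fully reproducible from `cfg$seed`.
#'
#' @param folded Cohort tibble with a `fold` column ([random_split()] /
#'   [louo_split()]).
#' @param test_fold Index of the held-out fold.
#' @param arch Architecture name (see [build_model()]).
#' @param cfg A [train_config()].
#' @param augmentation Optional [augmentation_config()]; the `fft`
#'   configuration switches the model to 3 input channels and is also
#'   applied (deterministically) at evaluation.
#' @return An object of class `skill_fit`: `model`, `scaler`, `arch`,
#'   `config`, `history`, `best_epoch`, `test_fold`.
#' @export
train_one_fold <- function(folded, test_fold, arch, cfg = train_config(),
                           augmentation = NULL) {
  stopifnot("fold" %in% names(folded))
  test_df <- folded[folded$fold == test_fold, ]
  train_df <- folded[folded$fold != test_fold, ]
  if (nrow(test_df) == 0L) stop("test fold ", test_fold, " is empty")
  if (length(unique(train_df$skill)) < 2L) {
    stop("training folds contain a single class; cannot train")
  }
  in_channels <- if (!is.null(augmentation) && augmentation$name == "fft")
    3L else 1L
  withr::with_seed(cfg$seed, {
    y_all <- encode_skill(train_df$skill)
    val_idx <- integer(0)
    if (cfg$val_fraction > 0) {
      for (cls in c(0, 1)) {
        cls_idx <- which(y_all == cls)
        n_val <- max(1L, floor(cfg$val_fraction * length(cls_idx)))
        n_val <- min(n_val, length(cls_idx) - 1L)
        if (n_val > 0L) {
          val_idx <- c(val_idx, cls_idx[sample.int(length(cls_idx), n_val)])
        }
      }
    }
    scaler <- fit_scaler(lapply(train_df$trace, clip_negatives))
    prep <- preprocess_trials(train_df, scaler)
    is_val <- seq_len(nrow(prep)) %in% val_idx
    model <- build_model(arch, in_channels = in_channels,
                         init_seed = sample.int(.Machine$integer.max, 1L))
    fit <- fit_model(model,
                     traces = prep$trace[!is_val],
                     labels = y_all[!is_val],
                     cfg = cfg,
                     val_traces = prep$trace[is_val],
                     val_labels = y_all[is_val],
                     augmentation = augmentation)
    structure(list(model = fit$model, scaler = scaler, arch = arch,
                   config = cfg, history = fit$history,
                   best_epoch = fit$best_epoch, test_fold = test_fold),
              class = "skill_fit")
  })
}

#' @export
print.skill_fit <- function(x, ...) {
  cat(sprintf("<skill_fit> arch=%s test_fold=%d best_epoch=%d\n",
              x$arch, x$test_fold, x$best_epoch))
  invisible(x)
}

#' Predict skill for new trials with a fitted fold model
#'
#' @param object A `skill_fit`.
#' @param cohort Cohort tibble of raw trials.
#' @param threshold Decision threshold (default 0.5).
#' @param ... Unused.
#' @return Tibble with `.prob` (Expert probability) and `.pred_skill`.
#' @export
predict.skill_fit <- function(object, cohort, threshold = 0.5, ...) {
  ev <- evaluate_fold(object, cohort, threshold = threshold)
  dplyr::mutate(ev$predictions,
                .pred_skill = ifelse(.data$.pred == 1L, "Expert", "Novice"))
}

fold_seed <- function(seed, arch_index, fold) {
  as.integer((as.numeric(seed) %% 65011) * 32749 +
               arch_index * 7907 + fold * 104729) %% 2147483647L
}

#' Run the cross-validated skill-classification benchmark
#'
#' Iterates every fold of the chosen cross-validation scheme (each fold held
#' out once), trains each requested architecture, evaluates on the held-out
#' trials at their original temporal resolution, and aggregates accuracy,
#' precision, recall and F1 as mean +/- standard deviation over folds.
#'
#' @param cohort A cohort tibble.
#' @param archs Character vector of architectures to benchmark.
#' @param scheme `"random"` (six-fold, stratified within surgeon) or
#'   `"louo"` (leave-one-user-out; unequal class rosters are auto-merged,
#'   smallest expert groups first).
#' @param cfg A [train_config()].
#' @param augmentation Optional [augmentation_config()] applied to training
#'   crops.
#' @param n_folds Number of folds for the random scheme (default 6).
#' @param seed Seed controlling fold assignment and all per-fold training
#'   seeds; one seed fixes the entire report.
#' @return An object of class `skill_benchmark`: `folds` (per-fold metric
#'   tibble), `summary` (per-arch mean/sd), `predictions`, `fits` (list of
#'   `skill_fit`), `scheme`, `folded` (the fold assignment).
#' @export
run_benchmark <- function(cohort, archs = c("tcn", "cldnn"),
                          scheme = c("random", "louo"),
                          cfg = train_config(), augmentation = NULL,
                          n_folds = 6L, seed = cfg$seed) {
  scheme <- match.arg(scheme)
  folded <- if (scheme == "random") {
    random_split(cohort, n_folds = n_folds, seed = seed)
  } else {
    louo_split(cohort, merges = auto_merges(cohort))
  }
  if (scheme == "louo") check_louo_leakage(folded)
  folds_present <- sort(unique(folded$fold))
  fold_rows <- list()
  pred_rows <- list()
  fits <- list()
  for (ai in seq_along(archs)) {
    arch <- archs[ai]
    for (k in folds_present) {
      cfg_k <- cfg
      cfg_k$seed <- fold_seed(seed, ai, k)
      fit <- train_one_fold(folded, k, arch, cfg_k,
                            augmentation = augmentation)
      ev <- evaluate_fold(fit, folded[folded$fold == k, ])
      m <- compute_metrics(ev$counts)
      fold_rows[[length(fold_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(arch = arch, fold = k,
                       tp = ev$counts$tp, tn = ev$counts$tn,
                       fp = ev$counts$fp, fn = ev$counts$fn), m)
      pred_rows[[length(pred_rows) + 1L]] <-
        dplyr::mutate(ev$predictions, arch = arch, fold = k)
      fits[[paste(arch, k, sep = ".")]] <- fit
    }
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  structure(list(folds = folds_tbl,
                 summary = summarise_benchmark(folds_tbl),
                 predictions = dplyr::bind_rows(pred_rows),
                 fits = fits, scheme = scheme, folded = folded,
                 config = cfg, seed = seed),
            class = "skill_benchmark")
}

# merge smallest same-class groups until expert/novice group counts match
auto_merges <- function(cohort) {
  roster <- cohort_roster(cohort)
  ne <- sum(roster$skill == "Expert")
  nn <- sum(roster$skill == "Novice")
  if (ne == nn) return(NULL)
  big <- if (ne > nn) "Expert" else "Novice"
  excess <- abs(ne - nn)
  cls <- roster[roster$skill == big, ]
  cls <- cls[order(cls$n_trials), ]
  # the (excess + 1) surgeons with the fewest trials travel together
  list(cls$surgeon_id[seq_len(excess + 1L)])
}

summarise_benchmark <- function(folds_tbl) {
  long <- tidyr::pivot_longer(folds_tbl,
                              c("accuracy", "precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  if (anyNA(long$value)) {
    warning("undefined metric value(s) skipped in cross-fold summary")
  }
  long |>
    dplyr::group_by(.data$arch, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_folds = dplyr::n(), .groups = "drop")
}

#' @export
print.skill_benchmark <- function(x, ...) {
  cat(sprintf("<skill_benchmark> scheme=%s folds=%d arch(s): %s\n",
              x$scheme, length(unique(x$folds$fold)),
              paste(unique(x$folds$arch), collapse = ", ")))
  s <- x$summary
  for (a in unique(s$arch)) {
    acc <- s[s$arch == a & s$metric == "accuracy", ]
    f1 <- s[s$arch == a & s$metric == "f1", ]
    cat(sprintf("  %-12s accuracy %.2f%% +/- %.2f%%  F1 %.2f%% +/- %.2f%%\n",
                a, 100 * acc$mean, 100 * acc$sd, 100 * f1$mean,
                100 * f1$sd))
  }
  invisible(x)
}

#' Write benchmark report files
#'
#' Writes `report.json` (per-fold confusion counts and metrics plus the
#' cross-fold summary) and `report.csv` (one row per architecture, metrics
#' formatted as "mean +/- sd" percentages).
#'
#' @param benchmark A `skill_benchmark`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(scheme = benchmark$scheme,
         folds = benchmark$folds,
         summary = benchmark$summary),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  wide <- benchmark$summary |>
    dplyr::mutate(cell = sprintf("%.2f ± %.2f", 100 * .data$mean,
                                 100 * .data$sd)) |>
    dplyr::select("arch", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell") |>
    dplyr::select("arch", "accuracy", "f1", "precision", "recall")
  readr::write_csv(wide, file.path(dir, "report.csv"))
  invisible(dir)
}
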