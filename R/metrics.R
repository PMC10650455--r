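# Confusion counts and the four classification metrics, Expert = positive.

#' Confusion counts from labels and predictions
#'
#' @param truth Numeric/integer 0-1 vector (or Expert/Novice labels).
#' @param pred Numeric/integer 0-1 vector of predictions.
#' @return A `confusion_counts` object: list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  if (is.character(truth)) truth <- encode_skill(truth)
  if (is.character(pred)) pred <- encode_skill(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(0, 1)), all(pred %in% c(0, 1)))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 tn = sum(truth == 0 & pred == 0),
                 fp = sum(truth == 0 & pred == 1),
                 fn = sum(truth == 1 & pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Computes accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN) and F1 = 2TP/(2TP+FP+FN), with Expert as the positive
#' class. A metric whose denominator is zero is undefined and reported as
#' `NA` (never silently 0).
#'
#' @param counts A `confusion_counts` object or a list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return One-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1` (fractions in `[0, 1]` or `NA`).
#' @examples
#' compute_metrics(list(tp = 2, tn = 6, fp = 1, fn = 1))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0), tp + tn + fp + fn >= 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn))
}

#' Evaluate a fitted model on held-out trials
#'
#' Test trials keep their original temporal resolution (no cropping, no
#' padding, no augmentation); a trial is predicted Expert when the model
#' probability is at least `threshold`.
#'
#' @param fit A `skill_fit` from [train_one_fold()] (or a `skill_model` plus
#'   an explicit `scaler`).
#' @param test_cohort Cohort tibble of raw test trials.
#' @param scaler Optional `force_scaler` overriding the one stored in `fit`.
#' @param threshold Decision threshold on the Expert probability
#'   (default 0.5).
#' @return List with `counts` (`confusion_counts`) and `predictions`
#'   (tibble: surgeon_id, trial_index, skill, .prob, .pred).
#' @export
evaluate_fold <- function(fit, test_cohort, scaler = NULL, threshold = 0.5) {
  model <- if (inherits(fit, "skill_fit")) fit$model else fit
  scaler <- scaler %||% if (inherits(fit, "skill_fit")) fit$scaler else NULL
  if (is.null(scaler)) stop("no scaler available; pass `scaler`")
  prep <- preprocess_trials(test_cohort, scaler)
  traces <- prep$trace
  if (model$in_channels == 3L) traces <- lapply(traces, rfft_stack)
  prob <- predict_prob(model, traces)
  pred <- as.integer(prob >= threshold)
  truth <- encode_skill(test_cohort$skill)
  list(counts = confusion_counts(truth, pred),
       predictions = tibble::tibble(
         surgeon_id = test_cohort$surgeon_id,
         trial_index = test_cohort$trial_index,
         skill = test_cohort$skill,
         .prob = prob,
         .pred = pred))
}
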