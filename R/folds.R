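# Cross-validation fold construction: random six-fold (stratified within
# surgeon) and leave-one-user-out (LOUO).

#' Random k-fold split stratified within surgeon
#'
#' For each surgeon independently, shuffles their trials and deals them
#' round-robin across folds (with a random starting fold), so every fold
#' contains a near-equal number of trials from every surgeon: per-surgeon
#' per-fold counts differ by at most 1.
#'
#' @param cohort A cohort tibble.
#' @param n_folds Number of folds (default 6).
#' @param seed RNG seed for the shuffles.
#' @return The cohort with an integer `fold` column (attribute
#'   `scheme = "random"`).
#' @export
random_split <- function(cohort, n_folds = 6L, seed = 1L) {
  validate_cohort(cohort)
  stopifnot(n_folds >= 2L)
  out <- withr::with_seed(seed, {
    fold <- integer(nrow(cohort))
    for (sid in unique(cohort$surgeon_id)) {
      idx <- which(cohort$surgeon_id == sid)
      perm <- idx[sample.int(length(idx))]
      start <- sample.int(n_folds, 1L)
      fold[perm] <- ((start - 1L + seq_along(perm) - 1L) %% n_folds) + 1L
    }
    fold
  })
  cohort$fold <- out
  attr(cohort, "scheme") <- "random"
  attr(cohort, "n_folds") <- as.integer(n_folds)
  cohort
}

#' Leave-one-user-out split
#'
#' Each fold holds out all trials of one expert group and one novice, so test
#' surgeons are never seen during training. When the class rosters are
#' unequal, surgeons can be merged into groups that travel together (e.g.,
#' with 7 experts and 6 novices, merging the two experts with the fewest
#' trials yields 6 folds).
#'
#' @param cohort A cohort tibble.
#' @param pairing Optional list of length-2 character vectors
#'   `c(expert_group_label, novice_id)` overriding the default roster-order
#'   pairing.
#' @param merges Optional list of character vectors of surgeon ids to merge
#'   into one group (same-class surgeons only).
#' @return The cohort with a `fold` column (attribute `scheme = "louo"`).
#' @export
louo_split <- function(cohort, pairing = NULL, merges = NULL) {
  validate_cohort(cohort)
  roster <- cohort_roster(cohort)
  group_of <- stats::setNames(roster$surgeon_id, roster$surgeon_id)
  if (!is.null(merges)) {
    for (grp in merges) {
      unknown <- setdiff(grp, roster$surgeon_id)
      if (length(unknown)) stop("merge names unknown surgeon: ", unknown[1])
      cls <- unique(roster$skill[roster$surgeon_id %in% grp])
      if (length(cls) > 1L) stop("cannot merge surgeons of different classes")
      group_of[grp] <- paste(sort(grp), collapse = "+")
    }
  }
  roster$group <- group_of[roster$surgeon_id]
  expert_groups <- unique(roster$group[roster$skill == "Expert"])
  novices <- unique(roster$group[roster$skill == "Novice"])
  if (length(expert_groups) != length(novices)) {
    stop(sprintf(paste0(
      "cannot pair %d expert group(s) with %d novice(s); ",
      "merge same-class surgeons via `merges` so the counts match"),
      length(expert_groups), length(novices)))
  }
  if (is.null(pairing)) {
    pairing <- Map(c, expert_groups, novices)
  }
  fold_of_group <- character(0)
  for (k in seq_along(pairing)) {
    fold_of_group[pairing[[k]]] <- k
  }
  unassigned <- setdiff(unique(roster$group), names(fold_of_group))
  if (length(unassigned)) stop("pairing leaves group unassigned: ",
                               unassigned[1])
  cohort$fold <- as.integer(fold_of_group[group_of[cohort$surgeon_id]])
  attr(cohort, "scheme") <- "louo"
  attr(cohort, "n_folds") <- length(pairing)
  cohort
}

#' Check a fold assignment for surgeon leakage
#'
#' For a LOUO assignment, verifies that no surgeon contributes trials to both
#' the training and the test side of any fold.
#'
#' @param folded Cohort with a `fold` column.
#' @return `TRUE` invisibly if no fold shares a surgeon between train and
#'   test; otherwise an error.
#' @export
check_louo_leakage <- function(folded) {
  stopifnot("fold" %in% names(folded))
  for (k in sort(unique(folded$fold))) {
    test_s <- unique(folded$surgeon_id[folded$fold == k])
    train_s <- unique(folded$surgeon_id[folded$fold != k])
    shared <- intersect(test_s, train_s)
    if (length(shared)) {
      stop("surgeon ", shared[1], " appears in both train and test of fold ",
           k)
    }
  }
  invisible(TRUE)
}
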