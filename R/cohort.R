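# Cohort container and disk I/O. A cohort is a tibble with one row per trial:
# surgeon_id (character), skill ("Expert"/"Novice"), trial_index (integer),
# trace (list of numeric force vectors). On disk: a JSON manifest pointing at
# one two-column CSV per trial.

skill_levels <- c("Novice", "Expert")

#' Assemble a cohort tibble from its components
#'
#' @param surgeon_id Character vector of surgeon identifiers.
#' @param skill Character vector, `"Expert"` or `"Novice"`.
#' @param trial_index Integer trial number within surgeon (from 1).
#' @param trace List of numeric force traces.
#' @return A validated cohort tibble.
#' @export
new_cohort <- function(surgeon_id, skill, trial_index, trace) {
  cohort <- tibble::tibble(
    surgeon_id = as.character(surgeon_id),
    skill = as.character(skill),
    trial_index = as.integer(trial_index),
    trace = trace)
  validate_cohort(cohort)
  cohort
}

#' Validate a cohort tibble
#'
#' Checks column presence and types, legal skill labels, per-surgeon label
#' consistency, uniqueness of (surgeon, trial) keys, and that every trace is
#' a finite numeric vector.
#'
#' @param cohort A cohort tibble.
#' @return The cohort, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort) {
  required <- c("surgeon_id", "skill", "trial_index", "trace")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0L) return(invisible(cohort))
  bad <- setdiff(unique(cohort$skill), skill_levels)
  if (length(bad)) {
    stop("unknown skill label(s): ", paste(bad, collapse = ", "),
         " (must be Expert or Novice)")
  }
  key <- paste(cohort$surgeon_id, cohort$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicate (surgeon_id, trial_index): ", key[duplicated(key)][1])
  }
  per <- tapply(cohort$skill, cohort$surgeon_id,
                function(s) length(unique(s)))
  if (any(per > 1L)) {
    stop("surgeon ", names(per)[per > 1L][1],
         " has inconsistent skill labels across trials")
  }
  ok <- vapply(cohort$trace,
               function(tr) is.numeric(tr) && length(tr) >= 1L &&
                 all(is.finite(tr)),
               logical(1))
  if (!all(ok)) stop("trace in row ", which(!ok)[1], " is not finite numeric")
  invisible(cohort)
}

#' Per-surgeon roster of a cohort
#'
#' @param cohort A cohort tibble.
#' @return Tibble with one row per surgeon: `surgeon_id`, `skill`,
#'   `n_trials`.
#' @export
cohort_roster <- function(cohort) {
  validate_cohort(cohort)
  cohort |>
    dplyr::group_by(.data$surgeon_id, .data$skill) |>
    dplyr::summarise(n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$surgeon_id)
}

#' Encode skill labels as the training target
#'
#' Expert trials are encoded as 1 (the positive class), Novice as 0.
#'
#' @param skill Character vector of labels.
#' @return Numeric 0/1 vector.
#' @export
encode_skill <- function(skill) {
  bad <- setdiff(unique(skill), skill_levels)
  if (length(bad)) stop("unknown skill label(s): ", paste(bad, collapse = ", "))
  as.numeric(skill == "Expert")
}

#' Write a cohort to disk
#'
#' Writes one `t,force_n` CSV per trial plus a JSON manifest
#' (`manifest.json`) listing `surgeon_id`, `skill`, `trial_index` and the
#' relative `trace_path` of every trial.
#'
#' @param cohort A cohort tibble.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  validate_cohort(cohort)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  trace_path <- sprintf("%s_trial%03d.csv",
                        gsub("[^A-Za-z0-9_-]", "_", cohort$surgeon_id),
                        cohort$trial_index)
  for (i in seq_len(nrow(cohort))) {
    tr <- cohort$trace[[i]]
    readr::write_csv(
      # %.17g guarantees a lossless double round trip through text
      tibble::tibble(t = seq_along(tr) - 1L,
                     force_n = sprintf("%.17g", tr)),
      file.path(path, trace_path[i]))
  }
  manifest <- data.frame(
    surgeon_id = cohort$surgeon_id,
    skill = cohort$skill,
    trial_index = cohort$trial_index,
    trace_path = trace_path,
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Inverse of [write_trials()]: reads `manifest.json` and the per-trial CSVs
#' it references. `read_trials(write_trials(x, p))` reproduces `x` to full
#' float precision.
#'
#' @param path Directory containing `manifest.json`.
#' @return A cohort tibble.
#' @export
read_trials <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json found in ", path)
  manifest <- jsonlite::fromJSON(mf)
  if (length(manifest) == 0L || NROW(manifest) == 0L) {
    return(new_cohort(character(), character(), integer(), list()))
  }
  required <- c("surgeon_id", "skill", "trial_index", "trace_path")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) {
    stop("manifest is missing field(s): ", paste(missing, collapse = ", "))
  }
  traces <- lapply(manifest$trace_path, function(p) {
    # force_n is read as text and parsed with strtod for an exact round trip
    df <- readr::read_csv(file.path(path, p), col_types = "ic",
                          progress = FALSE)
    if (!all(c("t", "force_n") %in% names(df))) {
      stop("trace file ", p, " is missing column(s): ",
           paste(setdiff(c("t", "force_n"), names(df)), collapse = ", "))
    }
    as.numeric(df$force_n)
  })
  new_cohort(manifest$surgeon_id, manifest$skill, manifest$trial_index,
             traces)
}
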