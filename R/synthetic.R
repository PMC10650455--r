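# Seeded synthetic expert/novice force-trace generator. Emulates the
# qualitative morphology of glove-sensor force recordings: a resting baseline
# with intermittent grasp/dissection bursts, high-frequency tremor, and
# skill-dependent smoothness, clipped to the 0-10 N sensor range.

#' Skill-level generative profile
#'
#' Parameters of the per-class trace generator. Novices exert higher and more
#' variable forces with sharper peaks; experts produce smoother, lower-force
#' traces.
#'
#' @param base_force Mean resting force (newtons).
#' @param burst_rate Expected force bursts per 100 steps.
#' @param burst_amp_mean,burst_amp_sd Normal distribution of burst peak
#'   amplitudes (newtons).
#' @param smoothness Half-width (steps) of the centered moving average applied
#'   to the assembled signal; larger = smoother.
#' @param tremor_sd Standard deviation (newtons) of i.i.d. high-frequency
#'   jitter.
#' @return An object of class `skill_profile`.
#' @export
skill_profile <- function(base_force, burst_rate, burst_amp_mean,
                          burst_amp_sd, smoothness, tremor_sd) {
  vals <- c(base_force, burst_rate, burst_amp_mean, burst_amp_sd,
            smoothness, tremor_sd)
  stopifnot(all(is.finite(vals)), all(vals >= 0))
  structure(list(base_force = base_force, burst_rate = burst_rate,
                 burst_amp_mean = burst_amp_mean, burst_amp_sd = burst_amp_sd,
                 smoothness = smoothness, tremor_sd = tremor_sd),
            class = "skill_profile")
}

#' Default expert and novice generative profiles
#'
#' Deterministic constants encoding the qualitative expert/novice contrast:
#' novices produce higher mean force, larger and more variable bursts, more
#' tremor, and less smoothing (sharp peaks and sudden turning points).
#'
#' @return Named list with elements `expert` and `novice`.
#' @export
default_profiles <- function() {
  list(
    expert = skill_profile(base_force = 0.8, burst_rate = 3,
                           burst_amp_mean = 2.0, burst_amp_sd = 0.5,
                           smoothness = 4, tremor_sd = 0.15),
    novice = skill_profile(base_force = 1.5, burst_rate = 6,
                           burst_amp_mean = 4.5, burst_amp_sd = 1.5,
                           smoothness = 1, tremor_sd = 0.45))
}

# truncated centered moving average of half-width s (window shrinks at edges,
# so constants are preserved exactly)
moving_average <- function(x, s) {
  s <- as.integer(round(s))
  if (s <= 0L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - s)
  hi <- pmin(n, i + s)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Generate one synthetic force trial
#'
#' Assembles baseline + triangular force bursts (Poisson onsets, Normal peak
#' amplitudes, Uniform(5, 25)-step widths) + Gaussian tremor, smooths with a
#' centered moving average, and clips to the 0-10 N sensor range.
#'
#' @param profile A [skill_profile()].
#' @param length Trial length in steps.
#' @param seed Optional seed; when `NULL`, draws from the current RNG stream.
#' @return Numeric force trace of the requested length, values in `[0, 10]`.
#' @export
generate_trial <- function(profile, length, seed = NULL) {
  stopifnot(inherits(profile, "skill_profile"), length >= 1L)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trial(profile, length)))
  }
  n <- as.integer(length)
  x <- rep(profile$base_force, n)
  n_bursts <- stats::rpois(1L, profile$burst_rate * n / 100)
  if (n_bursts > 0L) {
    onset <- stats::runif(n_bursts, 1, n)
    peak <- pmax(0, stats::rnorm(n_bursts, profile$burst_amp_mean,
                                 profile$burst_amp_sd))
    width <- stats::runif(n_bursts, 5, 25)
    for (b in seq_len(n_bursts)) {
      half <- width[b] / 2
      lo <- max(1L, floor(onset[b] - half))
      hi <- min(n, ceiling(onset[b] + half))
      k <- lo:hi
      x[k] <- x[k] + peak[b] * pmax(0, 1 - abs(k - onset[b]) / half)
    }
  }
  if (profile$tremor_sd > 0) x <- x + stats::rnorm(n, 0, profile$tremor_sd)
  x <- moving_average(x, profile$smoothness)
  pmin(pmax(x, 0), 10)
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the benchmark cohort shape: 13 surgeons (7 experts, 6
#' novices), 16-20 retained trials each (at most 20 repetitions per surgeon,
#' minus faulty recordings), trial lengths 100-600 steps.
#'
#' @param n_experts,n_novices Surgeon counts per class.
#' @param trials_per_surgeon Length-2 integer range of trials per surgeon.
#' @param length_range Length-2 integer range of trial lengths (steps).
#' @param seed RNG seed making the cohort fully reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_experts = 7L, n_novices = 6L,
                        trials_per_surgeon = c(16L, 20L),
                        length_range = c(100L, 600L), seed = 1L) {
  stopifnot(n_experts >= 1L, n_novices >= 1L,
            length(trials_per_surgeon) == 2L, all(trials_per_surgeon >= 1L),
            length(length_range) == 2L, all(length_range >= 1L))
  structure(list(n_experts = as.integer(n_experts),
                 n_novices = as.integer(n_novices),
                 trials_per_surgeon = as.integer(trials_per_surgeon),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic expert/novice cohort
#'
#' Draws a full cohort from the class profiles. Each surgeon receives a
#' multiplicative log-normal random effect on their burst amplitude (drawn
#' once per surgeon), so leave-one-user-out evaluation must generalize across
#' genuinely different individuals, not just across trials.
#'
#' @param spec A [cohort_spec()].
#' @param profiles Named list with `expert` and `novice` [skill_profile()]s;
#'   defaults to [default_profiles()].
#' @return A cohort tibble (one row per trial).
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' cohort_roster(cohort)
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            profiles = default_profiles()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    rows <- list()
    roster <- tibble::tibble(
      surgeon_id = c(sprintf("E%d", seq_len(spec$n_experts)),
                     sprintf("N%d", seq_len(spec$n_novices))),
      skill = rep(c("Expert", "Novice"),
                  c(spec$n_experts, spec$n_novices)))
    for (i in seq_len(nrow(roster))) {
      prof <- if (roster$skill[i] == "Expert") profiles$expert else
        profiles$novice
      surg_prof <- prof
      surg_prof$burst_amp_mean <-
        prof$burst_amp_mean * exp(stats::rnorm(1L, 0, 0.15))
      # index-based draws: safe when the ranges collapse to a single value
      kr <- spec$trials_per_surgeon[1]:spec$trials_per_surgeon[2]
      k <- kr[sample.int(length(kr), 1L)]
      lr <- spec$length_range[1]:spec$length_range[2]
      lens <- lr[sample.int(length(lr), k, replace = TRUE)]
      traces <- lapply(lens, function(l) generate_trial(surg_prof, l))
      rows[[i]] <- tibble::tibble(
        surgeon_id = roster$surgeon_id[i],
        skill = roster$skill[i],
        trial_index = seq_len(k),
        trace = traces)
    }
    cohort <- dplyr::bind_rows(rows)
    validate_cohort(cohort)
    cohort
  })
}
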