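# broom-style tidiers and autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold benchmark results
#'
#' @param x A `skill_benchmark`.
#' @param ... Unused.
#' @return Long tibble: one row per architecture, fold and metric.
#' @export
tidy.skill_benchmark <- function(x, ...) {
  tidyr::pivot_longer(x$folds, c("accuracy", "precision", "recall", "f1"),
                      names_to = "metric", values_to = "value")
}

#' One-row-per-architecture benchmark summary
#'
#' @param x A `skill_benchmark`.
#' @param ... Unused.
#' @return Tibble with `<metric>_mean` / `<metric>_sd` columns per
#'   architecture plus the scheme and fold count.
#' @export
glance.skill_benchmark <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}") |>
    dplyr::mutate(scheme = x$scheme, .after = "arch")
}

#' Per-epoch training history of a fitted fold
#'
#' @param x A `skill_fit`.
#' @param ... Unused.
#' @return Tibble with epoch, training loss/accuracy and validation loss.
#' @export
tidy.skill_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted fold
#'
#' @param x A `skill_fit`.
#' @param ... Unused.
#' @return Tibble with architecture, parameter count, selected epoch and the
#'   minimum validation loss.
#' @export
glance.skill_fit <- function(x, ...) {
  tibble::tibble(arch = x$arch,
                 n_params = count_params(x$model),
                 best_epoch = x$best_epoch,
                 val_loss = if (nrow(x$history) && x$best_epoch >= 1L)
                   x$history$val_loss[x$best_epoch] else NA_real_,
                 test_fold = x$test_fold)
}

#' Plot cross-fold benchmark metrics
#'
#' Per-fold values (points) with the cross-fold mean and +/- one standard
#' deviation (error bars) for each architecture and metric.
#'
#' @param object A `skill_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skill_benchmark <- function(object, ...) {
  long <- tidy.skill_benchmark(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arch, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, position = ggplot2::position_jitter(
      width = 0.08, height = 0, seed = 1)) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "#B2182B",
                          size = 2.5) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1), geom = "errorbar",
                          width = 0.2, colour = "#B2182B") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = sprintf("%s cross-validation", object$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot a handful of cohort force traces
#'
#' @param cohort A cohort tibble.
#' @param n_per_class Traces drawn per skill class (first trials in roster
#'   order).
#' @return A ggplot object.
#' @export
plot_cohort_traces <- function(cohort, n_per_class = 3L) {
  validate_cohort(cohort)
  pick <- cohort |>
    dplyr::group_by(.data$skill) |>
    dplyr::slice_head(n = n_per_class) |>
    dplyr::ungroup()
  long <- pick |>
    dplyr::mutate(id = paste0(.data$surgeon_id, " #", .data$trial_index)) |>
    dplyr::mutate(df = purrr::map(.data$trace, function(tr) {
      tibble::tibble(step = seq_along(tr), force = tr)
    })) |>
    dplyr::select("id", "skill", "df") |>
    tidyr::unnest("df")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$force)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~skill + id, scales = "free_x") +
    ggplot2::labs(x = "time step", y = "force (N)") +
    ggplot2::theme_minimal()
}
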