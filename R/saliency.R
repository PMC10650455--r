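# Temporal saliency: collapse the final pre-head feature map to a per-step
# attention intensity in [0, 1] and overlay it on the force plot.

#' Compute a temporal saliency track
#'
#' Implements the attention-overlay procedure for the TCN and CLDNN models:
#' extract the final feature map before the linear head (TCN: the fourth
#' block's output, 16 x T; CLDNN: the last LSTM layer's sequence output,
#' 64 x floor(T/4)), average over the feature dimension, min-max normalize to
#' `[0, 1]`, and linearly interpolate back to the trial's original temporal
#' resolution. For the TCN the temporal resolution is preserved throughout
#' the network, so the interpolation is the identity.
#'
#' @param fit A `skill_fit` (preferred; carries the fold scaler) or a bare
#'   `skill_model` with `preprocessed = TRUE` input.
#' @param trace Numeric force trace.
#' @param preprocessed Set `TRUE` when `trace` is already clipped and
#'   scaled; otherwise the fit's scaler is applied first.
#' @param reduce `"mean"` (arithmetic mean of raw activations, the default)
#'   or `"abs_mean"` (mean of absolute activations).
#' @return A tibble of class `saliency_track` with columns `step`, `force`
#'   (the input trace) and `intensity` in `[0, 1]`; attributes
#'   `source_feature`, `t_prime` and `f_dim` describe the collapsed feature
#'   map. A constant feature map yields all-zero intensities.
#' @export
compute_saliency <- function(fit, trace, preprocessed = FALSE,
                             reduce = c("mean", "abs_mean")) {
  reduce <- match.arg(reduce)
  model <- if (inherits(fit, "skill_fit")) fit$model else fit
  if (!model$arch %in% c("tcn", "cldnn")) {
    stop("saliency is defined for the tcn and cldnn architectures, not ",
         model$arch)
  }
  x <- trace
  if (!preprocessed) {
    scaler <- if (inherits(fit, "skill_fit")) fit$scaler else NULL
    if (is.null(scaler)) {
      stop("raw traces need a fitted scaler; pass a skill_fit or set ",
           "preprocessed = TRUE")
    }
    x <- apply_scaler(clip_negatives(trace), scaler)
  }
  input <- if (model$in_channels == 3L) rfft_stack(x) else x
  fw <- model_forward(model, trace_to_input(input, model$in_channels),
                      with_features = TRUE)
  if (model$arch == "tcn") {
    feat <- fw$features$F4              # channels x T
    raw <- if (reduce == "mean") colMeans(feat) else colMeans(abs(feat))
    source_feature <- "F4"
    f_dim <- nrow(feat)
  } else {
    feat <- fw$features$f6              # floor(T/4) x channels
    raw <- if (reduce == "mean") rowMeans(feat) else rowMeans(abs(feat))
    source_feature <- "f6"
    f_dim <- ncol(feat)
  }
  intensity <- normalize01(raw)
  Tt <- length(trace)
  if (length(intensity) != Tt) {
    intensity <- stats::approx(
      x = seq(1, Tt, length.out = length(intensity)),
      y = intensity, xout = seq_len(Tt))$y
  }
  out <- tibble::tibble(step = seq_len(Tt), force = as.numeric(trace),
                        intensity = intensity)
  class(out) <- c("saliency_track", class(out))
  attr(out, "source_feature") <- source_feature
  attr(out, "t_prime") <- length(raw)
  attr(out, "f_dim") <- f_dim
  out
}

# min-max normalization to [0, 1]; a constant vector maps to all zeros
# ("no attention anywhere")
normalize01 <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo <= 0) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Plot a saliency overlay
#'
#' Line plot of force versus time step, colored segment-by-segment by
#' attention intensity on a cold-to-warm scale (blue = low, red = high).
#'
#' @param object A `saliency_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saliency_track <- function(object, ...) {
  seg <- tibble::tibble(
    x = object$step[-nrow(object)],
    xend = object$step[-1L],
    y = object$force[-nrow(object)],
    yend = object$force[-1L],
    intensity = (object$intensity[-nrow(object)] +
                   object$intensity[-1L]) / 2)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$intensity),
      linewidth = 0.7) +
    ggplot2::scale_colour_gradient(low = "#2166AC", high = "#B2182B",
                                   limits = c(0, 1), name = "attention") +
    ggplot2::labs(x = "time step", y = "force (N)") +
    ggplot2::theme_minimal()
}

#' Render a saliency overlay to an image file
#'
#' Deterministic: identical inputs produce byte-identical files.
#'
#' @param track A `saliency_track` from [compute_saliency()].
#' @param path Output PNG path.
#' @param width,height,dpi Image geometry passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_overlay <- function(track, path, width = 8, height = 3, dpi = 120) {
  p <- autoplot.saliency_track(track)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = dpi,
                  device = grDevices::png, units = "in")
  invisible(path)
}
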