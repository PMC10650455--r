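# The six training-time augmentations. All operators are pure functions of
# (input, parameters, RNG state): pass `seed` for a self-contained draw or
# leave it NULL to consume the caller's RNG stream (as the training loop
# does). Probability-gated operators apply themselves with `apply_prob` and
# otherwise return the input unchanged.

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

gate_applies <- function(apply_prob) {
  stopifnot(apply_prob >= 0, apply_prob <= 1)
  apply_prob > 0 && stats::runif(1L) < apply_prob
}

#' Stack a trace with its real-FFT spectrum as a 3-channel input
#'
#' Computes the one-dimensional discrete Fourier transform of the
#' (real-valued) force sequence, keeps the `floor(T/2) + 1` non-redundant
#' coefficients, zero-pads their real and imaginary parts to length T, and
#' stacks them under the raw sequence. The result feeds 3-input-channel
#' models; the operator is deterministic (no probability gate) and is applied
#' at training and evaluation time alike.
#'
#' @param trace Numeric force trace of length `T >= 2`.
#' @return A `3 x T` numeric matrix: row 1 the input sequence, rows 2-3 the
#'   zero-padded real and imaginary spectrum.
#' @export
rfft_stack <- function(trace) {
  Tt <- length(trace)
  if (Tt < 2L) stop("rfft_stack requires at least 2 samples")
  sp <- stats::fft(trace)[seq_len(Tt %/% 2L + 1L)]
  re <- c(Re(sp), rep(0, Tt - length(sp)))
  im <- c(Im(sp), rep(0, Tt - length(sp)))
  rbind(force = trace, re = re, im = im)
}

#' Quantize a trace to a small level set
#'
#' With probability `apply_prob`, replaces every sample by the nearest of
#' `n_levels` equally spaced values spanning the trace's own range (ties go
#' to the lower level). Constant traces are returned unchanged.
#'
#' @param trace Numeric force trace.
#' @param n_levels Number of quantization levels (default 10).
#' @param apply_prob Application probability (default 0.5).
#' @param seed Optional seed.
#' @return Numeric vector of the same length.
#' @export
augment_quantize <- function(trace, n_levels = 10L, apply_prob = 0.5,
                             seed = NULL) {
  stopifnot(n_levels >= 2L)
  with_opt_seed(seed, {
    lo <- min(trace)
    hi <- max(trace)
    if (!gate_applies(apply_prob) || hi <= lo) {
      trace  # gated off, or degenerate single level
    } else {
      levels <- seq(lo, hi, length.out = n_levels)
      mids <- (levels[-1L] + levels[-n_levels]) / 2
      idx <- findInterval(trace, mids, left.open = TRUE) + 1L
      levels[idx]
    }
  })
}

#' Multiplicative drift augmentation
#'
#' With probability `apply_prob`, picks `n_points` interior anchor steps,
#' assigns each a multiplier drawn uniformly from `1 + drift_range` (values
#' amplified by an extra 10-50% of their original magnitude by default),
#' anchors both endpoints at multiplier 1, interpolates a smooth per-step
#' multiplier curve through the anchors with a natural cubic spline, and
#' multiplies the trace by it.
#'
#' @param trace Numeric force trace of length `>= n_points + 2`.
#' @param n_points Number of interior drift anchors (default 5).
#' @param drift_range Length-2 numeric; anchor multipliers are
#'   `1 + Uniform(drift_range[1], drift_range[2])` (default `c(0.1, 0.5)`).
#' @param apply_prob Application probability (default 0.5).
#' @param seed Optional seed.
#' @return Numeric vector of the same length.
#' @export
augment_drift <- function(trace, n_points = 5L, drift_range = c(0.1, 0.5),
                          apply_prob = 0.5, seed = NULL) {
  Tt <- length(trace)
  if (Tt < n_points + 2L) {
    stop(sprintf("drift needs at least %d samples, got %d", n_points + 2L, Tt))
  }
  with_opt_seed(seed, {
    if (!gate_applies(apply_prob)) {
      trace
    } else {
      interior <- 2:(Tt - 1L)
      anchors <- sort(interior[sample.int(length(interior), n_points)])
      mult <- 1 + stats::runif(n_points, drift_range[1], drift_range[2])
      curve <- stats::spline(x = c(1L, anchors, Tt), y = c(1, mult, 1),
                             xout = seq_len(Tt), method = "natural")$y
      trace * curve
    }
  })
}

#' Time-warp augmentation (local speed doubling)
#'
#' With probability `apply_prob`, selects `n_ranges` disjoint contiguous
#' ranges of `floor(T/20)` steps each, keeps every second sample inside them
#' (doubling the local speed), and linearly resamples the shortened sequence
#' back to the original length so the output shape is unchanged.
#'
#' @param trace Numeric force trace of length `>= 20 * n_ranges`.
#' @param n_ranges Number of warped ranges (default 5).
#' @param apply_prob Application probability (default 0.5).
#' @param seed Optional seed.
#' @return Numeric vector of the same length.
#' @export
augment_time_warp <- function(trace, n_ranges = 5L, apply_prob = 0.5,
                              seed = NULL) {
  Tt <- length(trace)
  if (Tt < 20L * n_ranges) {
    stop(sprintf("time warp needs at least %d samples, got %d",
                 20L * n_ranges, Tt))
  }
  with_opt_seed(seed, {
    if (!gate_applies(apply_prob)) {
      trace
    } else {
      L <- Tt %/% 20L
      # disjoint placement: sorted uniform offsets into the free space
      free <- Tt - n_ranges * L
      offs <- sort(sample.int(free + 1L, n_ranges, replace = TRUE) - 1L)
      starts <- offs + (seq_len(n_ranges) - 1L) * L + 1L
      keep <- rep(TRUE, Tt)
      for (s in starts) {
        rng <- s:(s + L - 1L)
        keep[rng] <- (seq_along(rng) %% 2L) == 1L  # every second sample
      }
      short <- trace[keep]
      stats::approx(x = seq_along(short), y = short,
                    xout = seq(1, length(short), length.out = Tt))$y
    }
  })
}

#' Additive Gaussian-noise augmentation
#'
#' Adds i.i.d. zero-mean Gaussian noise (default standard deviation 0.1) to
#' every sample. Always applied (no probability gate).
#'
#' @param trace Numeric force trace.
#' @param sd Noise standard deviation (default 0.1).
#' @param seed Optional seed.
#' @return Numeric vector of the same length.
#' @export
augment_gaussian_noise <- function(trace, sd = 0.1, seed = NULL) {
  stopifnot(sd >= 0)
  with_opt_seed(seed, trace + stats::rnorm(length(trace), 0, sd))
}

#' Temporal jittering (segment shuffling)
#'
#' Partitions a fixed-length training crop into `n_segments` consecutive
#' blocks of `segment_len` steps and permutes the block order uniformly at
#' random, preserving the sample multiset.
#'
#' @param trace Numeric trace of length exactly `n_segments * segment_len`
#'   (the 300-step training crops by default).
#' @param n_segments Number of blocks (default 30).
#' @param segment_len Block length in steps (default 10).
#' @param seed Optional seed.
#' @return Numeric vector of the same length.
#' @export
augment_temporal_jitter <- function(trace, n_segments = 30L,
                                    segment_len = 10L, seed = NULL) {
  Tt <- length(trace)
  if (Tt != n_segments * segment_len) {
    stop(sprintf("temporal jitter needs length %d (= %d x %d), got %d",
                 n_segments * segment_len, n_segments, segment_len, Tt))
  }
  with_opt_seed(seed, {
    perm <- sample.int(n_segments)
    idx <- as.vector(vapply(perm, function(s) {
      ((s - 1L) * segment_len + 1L):(s * segment_len)
    }, integer(segment_len)))
    trace[idx]
  })
}

#' Augmentation configuration
#'
#' Bundles an augmentation name with its parameters for use in training
#' ([train_one_fold()], [run_benchmark()]). Defaults reproduce the benchmark
#' settings of each operator.
#'
#' @param name One of `"fft"`, `"quantize"`, `"drift"`, `"timewarp"`,
#'   `"gaussian_noise"`, `"temporal_jitter"`.
#' @param apply_prob Probability gate for the gated operators; ignored by
#'   `fft` (deterministic) and `gaussian_noise`/`temporal_jitter` (always
#'   applied).
#' @param params Named list of operator-specific overrides.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(name = c("fft", "quantize", "drift",
                                         "timewarp", "gaussian_noise",
                                         "temporal_jitter"),
                                apply_prob = 0.5, params = list()) {
  name <- match.arg(name)
  stopifnot(apply_prob >= 0, apply_prob <= 1)
  structure(list(name = name, apply_prob = apply_prob, params = params),
            class = "augmentation_config")
}

#' Apply a configured augmentation to one trace
#'
#' @param trace Numeric trace (a fixed-length training crop).
#' @param config An [augmentation_config()].
#' @param seed Optional seed; `NULL` consumes the current RNG stream.
#' @return The augmented trace: a numeric vector, or a `3 x T` matrix for
#'   the `fft` representation.
#' @export
apply_augmentation <- function(trace, config, seed = NULL) {
  stopifnot(inherits(config, "augmentation_config"))
  p <- config$params
  switch(config$name,
    fft = rfft_stack(trace),
    quantize = augment_quantize(trace,
                                n_levels = p$n_levels %||% 10L,
                                apply_prob = config$apply_prob, seed = seed),
    drift = augment_drift(trace,
                          n_points = p$n_points %||% 5L,
                          drift_range = p$drift_range %||% c(0.1, 0.5),
                          apply_prob = config$apply_prob, seed = seed),
    timewarp = augment_time_warp(trace,
                                 n_ranges = p$n_ranges %||% 5L,
                                 apply_prob = config$apply_prob, seed = seed),
    gaussian_noise = augment_gaussian_noise(trace, sd = p$sd %||% 0.1,
                                            seed = seed),
    temporal_jitter = augment_temporal_jitter(
      trace,
      n_segments = p$n_segments %||% 30L,
      segment_len = p$segment_len %||% 10L, seed = seed))
}
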