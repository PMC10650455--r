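# Force-trace preprocessing: negative clipping, standard scaling, and
# fixed-length random cropping / zero padding. A force trace is a plain
# numeric vector in newtons; a cohort is a tibble with a `trace` list-column.

#' Replace negative force samples with zero
#'
#' Piezoresistive sensors occasionally report small negative forces during
#' unloading; these are physically meaningless and are clipped to zero before
#' any other preprocessing.
#'
#' @param trace Numeric vector of force samples (newtons); must be finite.
#' @return Numeric vector of the same length with all samples `>= 0`.
#' @examples
#' clip_negatives(c(-0.3, 0, 2))
#' @export
clip_negatives <- function(trace) {
  check_finite_trace(trace)
  pmax(trace, 0)
}

check_finite_trace <- function(trace) {
  if (!is.numeric(trace)) stop("force trace must be numeric")
  bad <- which(!is.finite(trace))
  if (length(bad)) {
    stop(sprintf("non-finite force sample at index %d", bad[1]))
  }
  invisible(trace)
}

#' Fit a standard scaler on pooled training samples
#'
#' Pools every sample of every training trace and computes the mean and
#' (population) standard deviation, the statistics used to standardize both
#' training and test trials. Fitting on training folds only avoids test-set
#' leakage.
#'
#' @param traces A list of numeric force traces, or a cohort tibble with a
#'   `trace` list-column.
#' @return An object of class `force_scaler` with elements `mean` and `sd`.
#' @examples
#' fit_scaler(list(c(0, 2)))
#' @export
fit_scaler <- function(traces) {
  traces <- as_trace_list(traces)
  if (!length(traces)) stop("need at least one trace to fit a scaler")
  pooled <- unlist(traces, use.names = FALSE)
  m <- mean(pooled)
  s <- sqrt(mean((pooled - m)^2))
  if (s <= 0 || !is.finite(s)) {
    stop("pooled force samples have zero variance; cannot fit scaler")
  }
  structure(list(mean = m, sd = s), class = "force_scaler")
}

#' @export
print.force_scaler <- function(x, ...) {
  cat(sprintf("<force_scaler> mean=%.4f N sd=%.4f N\n", x$mean, x$sd))
  invisible(x)
}

#' Standardize a force trace
#'
#' @param trace Numeric force trace.
#' @param scaler A `force_scaler` from [fit_scaler()].
#' @return `(trace - mean) / sd`, same length.
#' @export
apply_scaler <- function(trace, scaler) {
  stopifnot(inherits(scaler, "force_scaler"), scaler$sd > 0)
  (trace - scaler$mean) / scaler$sd
}

#' Crop or zero-pad a trace to a fixed training length
#'
#' Trials longer than `target_len` yield a random contiguous window (start
#' index uniform over all admissible positions, drawn from the current RNG
#' stream); shorter trials are padded with trailing zeros. Training uses
#' 300-step windows; at test time trials keep their original length.
#'
#' @param trace Numeric force trace.
#' @param target_len Target length in steps (default 300).
#' @return Numeric vector of length `target_len`, with attribute
#'   `true_len` = `min(length(trace), target_len)` giving the number of
#'   non-padded samples.
#' @export
crop_or_pad <- function(trace, target_len = 300L) {
  stopifnot(target_len >= 1L)
  Tt <- length(trace)
  if (Tt > target_len) {
    start <- sample.int(Tt - target_len + 1L, 1L)
    out <- trace[start:(start + target_len - 1L)]
    true_len <- target_len
  } else if (Tt < target_len) {
    out <- c(trace, rep(0, target_len - Tt))
    true_len <- Tt
  } else {
    out <- trace
    true_len <- Tt
  }
  attr(out, "true_len") <- as.integer(true_len)
  out
}

#' Clip and (optionally) standardize every trace of a cohort
#'
#' @param cohort A cohort tibble (see [generate_cohort()] / [read_trials()]).
#' @param scaler Optional `force_scaler`; when supplied, traces are
#'   standardized after clipping.
#' @return The cohort with the `trace` column preprocessed.
#' @export
preprocess_trials <- function(cohort, scaler = NULL) {
  validate_cohort(cohort)
  tr <- lapply(cohort$trace, clip_negatives)
  if (!is.null(scaler)) tr <- lapply(tr, apply_scaler, scaler = scaler)
  cohort$trace <- tr
  cohort
}

as_trace_list <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("trace" %in% names(x))
    x$trace
  } else if (is.list(x)) {
    x
  } else if (is.numeric(x)) {
    list(x)
  } else {
    stop("expected a list of traces or a cohort tibble")
  }
}
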