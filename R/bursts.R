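# Beta-burst detection from the smoothed Hilbert amplitude envelope.
# Bursts: envelope strictly above its 75th percentile for >= 100 ms.
# Non-burst epochs: envelope strictly below its 50th percentile for >= 100 ms.
# Samples between the two thresholds are transitional and left unlabeled.

# analytic signal via the FFT construction (zero out negative frequencies,
# double positive ones); x must be real
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# centered moving mean with shrinking windows at the edges
moving_mean <- function(a, w) {
  if (w <= 1L) return(a)
  n <- length(a)
  left <- w %/% 2L
  right <- w - 1L - left
  cs <- cumsum(c(0, a))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smoothed amplitude envelope of a beta signal
#'
#' Magnitude of the analytic (Hilbert) signal, smoothed with a centered
#' moving average of `smooth_ms` (windows shrink at the signal edges).
#'
#' @param beta a `beta_signal` (or numeric vector together with `fs`).
#' @param smooth_ms smoothing window in milliseconds (default 50).
#' @param fs sampling rate, only needed when `beta` is a plain vector.
#' @return an `envelope`: list with `a` (non-negative amplitudes, same length
#'   as the input), `fs`, `smooth_ms`, `source_label`.
#' @export
compute_envelope <- function(beta, smooth_ms = 50, fs = NULL) {
  if (inherits(beta, "beta_signal")) {
    x <- beta$x; fs <- beta$fs; lab <- beta$source_label
  } else {
    x <- as.numeric(beta); lab <- NULL
    if (is.null(fs)) stop("'fs' required when 'beta' is a plain vector")
  }
  if (!length(x)) stop("empty signal")
  a <- Mod(analytic_signal(x))
  w <- max(1L, round(smooth_ms * fs / 1000))
  structure(list(a = moving_mean(a, w), fs = fs, smooth_ms = smooth_ms,
                 source_label = lab),
            class = "envelope")
}

#' Detect burst and non-burst epochs from an envelope
#'
#' Thresholds are percentiles of the whole (trimmed) envelope, computed with
#' linear interpolation between order statistics. Bursts are maximal runs of
#' samples strictly above the burst threshold; non-burst epochs are maximal
#' runs strictly below the non-burst threshold; both are kept only when at
#' least `min_dur_ms` long. A constant envelope yields equal thresholds and
#' empty epoch lists (not an error).
#'
#' @param env an `envelope`.
#' @param burst_pct percentile defining the burst threshold (default 75).
#' @param nonburst_pct percentile defining the non-burst threshold (default 50).
#' @param min_dur_ms minimum epoch duration in ms (default 100).
#' @return an `epoch_set`: `bursts` and `nonbursts` interval matrices
#'   (0-based, half-open, trimmed-signal coordinates), `thresholds`,
#'   `fs`, `n`, `source_label`.
#' @export
detect_epochs <- function(env, burst_pct = 75, nonburst_pct = 50,
                          min_dur_ms = 100) {
  stopifnot(inherits(env, "envelope"))
  if (!length(env$a)) stop("empty envelope")
  if (burst_pct <= nonburst_pct) stop("burst_pct must exceed nonburst_pct")
  thr_b <- stats::quantile(env$a, burst_pct / 100, names = FALSE, type = 7)
  thr_n <- stats::quantile(env$a, nonburst_pct / 100, names = FALSE, type = 7)
  min_dur <- max(1L, round(min_dur_ms * env$fs / 1000))
  structure(list(
    bursts = logical_runs(env$a > thr_b, min_dur),
    nonbursts = logical_runs(env$a < thr_n, min_dur),
    thresholds = c(burst = thr_b, nonburst = thr_n),
    min_dur = min_dur, fs = env$fs, n = length(env$a),
    source_label = env$source_label),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set%s> %d bursts, %d non-burst epochs over %d samples (fs = %g)\n",
    if (is.null(x$source_label)) "" else paste0(" ", x$source_label),
    nrow(x$bursts), nrow(x$nonbursts), x$n, x$fs))
  cat(sprintf("  thresholds: burst > %.4g, non-burst < %.4g; min duration %d samples\n",
              x$thresholds["burst"], x$thresholds["nonburst"], x$min_dur))
  invisible(x)
}

#' Flag epoch sets with too few bursts
#'
#' Pairs whose STN channel shows fewer than 2 bursts cannot enter the
#' burst-adjacent analysis; channels with no bursts at all are excluded from
#' every burst analysis.
#'
#' @param epoch_sets list of `epoch_set` objects.
#' @return the same list with logical attributes `eligible_any` (>= 1 burst)
#'   and `eligible_adjacent` (>= 2 bursts) set on each element.
#' @export
exclude_sparse_pairs <- function(epoch_sets) {
  lapply(epoch_sets, function(es) {
    nb <- nrow(es$bursts)
    es$eligible_any <- nb >= 1L
    es$eligible_adjacent <- nb >= 2L
    es
  })
}
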