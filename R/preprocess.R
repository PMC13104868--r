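# Filtering chain: 1 Hz high-pass -> beta band-pass -> edge/head trimming.
# All filters are zero-phase (forward-backward) Butterworth IIR filters of
# overall order 4, applied with steady-state initial conditions so that
# start-up transients are negligible after the standard 2 s edge trim.

# forward-backward filter with constant-signal steady-state initialisation
# at both ends (the same idea scipy/MATLAB filtfilt use to suppress edge
# transients; here via explicit init.x/init.y on signal::filter)
zerophase_filter <- function(b, a, x) {
  k <- max(length(a), length(b)) - 1L
  h1 <- sum(b) / sum(a)  # DC gain, equilibrium for a constant input
  fwd <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1L], k),
                              init.y = rep(z[1L] * h1, k)))
  }
  rev(fwd(rev(fwd(x))))
}

#' Zero-phase beta band-pass filter
#'
#' Band-pass filters one channel in the beta range with a zero-phase
#' (forward-backward) Butterworth IIR filter of overall order `order`
#' (`order/2` per section, doubled in effective attenuation by the two
#' passes).
#'
#' @param channel numeric vector of raw samples.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, pass band in Hz; default `c(13, 30)`.
#' @param order overall filter order (even); default 4.
#' @param source_label optional channel name carried into the result.
#' @return a `beta_signal`: list with `x` (filtered samples), `fs`, `band`,
#'   `source_label`.
#' @export
bandpass_beta <- function(channel, fs, band = c(13, 30), order = 4L,
                          source_label = NULL) {
  check_finite(channel, "channel")
  if (order < 2L || order %% 2L != 0L) stop("'order' must be a positive even integer")
  if (length(channel) <= 6L * order)
    stop("signal too short for stable filtering (need > ", 6L * order, " samples)")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band edges must satisfy 0 < lo < hi < fs/2 (Nyquist = ", fs / 2, " Hz)")
  flt <- signal::butter(order %/% 2L, band * 2 / fs, type = "pass")
  structure(list(x = zerophase_filter(flt$b, flt$a, channel), fs = fs,
                 band = band, source_label = source_label),
            class = "beta_signal")
}

#' Zero-phase 1 Hz high-pass filter
#'
#' Removes drift and DC with a zero-phase fourth-order Butterworth high-pass
#' at 1 Hz.
#'
#' @inheritParams bandpass_beta
#' @param cutoff high-pass corner in Hz (default 1).
#' @return numeric vector, same length as input.
#' @export
highpass_1hz <- function(channel, fs, cutoff = 1, order = 4L) {
  check_finite(channel, "channel")
  if (length(channel) <= 6L * order)
    stop("signal too short for stable filtering (need > ", 6L * order, " samples)")
  if (cutoff <= 0 || cutoff >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  flt <- signal::butter(order, cutoff * 2 / fs, type = "high")
  zerophase_filter(flt$b, flt$a, channel)
}

#' Trim filter edges and recording head
#'
#' Discards the first `head_discard_s` seconds of the recording (start-up /
#' electrode settling) and `edge_trim_s` seconds from each end of the
#' filtered signal (filter edge effects). All downstream sample coordinates
#' are relative to the trimmed origin.
#'
#' @param x numeric vector (a filtered channel).
#' @param fs sampling rate in Hz.
#' @param head_discard_s seconds dropped once from the start (default 60).
#' @param edge_trim_s seconds dropped from both ends (default 2).
#' @return the trimmed vector, length `length(x) - floor(head_discard_s*fs) -
#'   2*floor(edge_trim_s*fs)`.
#' @export
trim_edges <- function(x, fs, head_discard_s = 60, edge_trim_s = 2) {
  n_head <- floor(head_discard_s * fs)
  n_edge <- floor(edge_trim_s * fs)
  n_min <- n_head + 2L * n_edge + 1L
  if (length(x) < n_min)
    stop(sprintf(
      "recording too short: %d samples; need at least %d (%.3f s at fs = %g)",
      length(x), n_min, n_min / fs, fs))
  x[(n_head + n_edge + 1L):(length(x) - n_edge)]
}

#' Preprocess a multichannel recording into beta-band signals
#'
#' Applies the fixed chain high-pass (1 Hz) -> beta band-pass -> trim to every
#' channel. The head discard is applied once on the shared recording timeline;
#' the edge trim is applied per filtered signal.
#'
#' @param rec a `recording` (see [as_recording()]).
#' @param band beta band in Hz.
#' @param order overall IIR order per filter.
#' @param head_discard_s,edge_trim_s see [trim_edges()].
#' @return a `beta_set`: named list of `beta_signal` objects (one per
#'   channel) plus `fs`, `roles`, `n` (trimmed length).
#' @export
preprocess_recording <- function(rec, band = c(13, 30), order = 4L,
                                 head_discard_s = 60, edge_trim_s = 2) {
  stopifnot(inherits(rec, "recording"))
  signals <- lapply(seq_along(rec$labels), function(j) {
    hp <- highpass_1hz(rec$samples[, j], rec$fs, order = order)
    bp <- bandpass_beta(hp, rec$fs, band = band, order = order,
                        source_label = rec$labels[j])
    bp$x <- trim_edges(bp$x, rec$fs, head_discard_s, edge_trim_s)
    bp
  })
  names(signals) <- rec$labels
  structure(list(signals = signals, fs = rec$fs, band = band,
                 labels = rec$labels, roles = rec$roles,
                 n = length(signals[[1]]$x)),
            class = "beta_set")
}
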