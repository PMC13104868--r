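# Synthetic STN/cortex signal pairs with known ground truth.
#
# STN channel: 1/f-shaped Gaussian background plus a narrow-band beta carrier
# whose amplitude envelope is multiplied by burst_gain inside bursts sampled
# from a homogeneous Poisson process (truncated-normal durations, merged when
# overlapping). Cortical channel: independent 1/f background plus a beta
# component whose instantaneous phase is a mixture of (STN beta phase +
# phase_lag_rad) and an independent beta phase; the locked weight is applied
# inside bursts only, everywhere, or nowhere according to coupling_mode.
# The phase-mixture construction makes coherence/dwPLI targets controllable
# independently of amplitude.

#' Configuration for the synthetic LFP/ECoG generator
#'
#' Defaults describe the regime the pipeline targets: 1 kHz sampling, a
#' 13-30 Hz carrier centred on 20 Hz, bursts of ~300 ms at ~0.8/s occupying
#' roughly a quarter of the recording, a threefold envelope gain inside
#' bursts, and strong burst-locked phase coupling at a quarter-cycle lag.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (default 1000; must exceed 60 Hz).
#' @param beta_freq carrier centre frequency in Hz, inside `[13, 30]`.
#' @param carrier_bw_hz carrier bandwidth in Hz (default 6): the carrier is
#'   white noise band-passed to `beta_freq +/- carrier_bw_hz/2`.
#' @param burst_rate Poisson burst onset rate, bursts/second.
#' @param burst_dur_mean_ms,burst_dur_sd_ms truncated-normal burst duration
#'   parameters in ms (truncated at 120 ms).
#' @param burst_gain envelope multiplier inside bursts (>= 1).
#' @param coupling_mode `"burst_locked"`, `"tonic"` or `"none"`.
#' @param coupling_strength fraction of cortical beta phase inherited from
#'   the STN carrier inside the coupling region, in `[0, 1]`.
#' @param phase_lag_rad phase lag of the inherited component, radians.
#' @param noise_exponent 1/f slope of the background (power ~ f^-exponent).
#' @param noise_rms RMS of the broadband background (default 1).
#' @param beta_amp baseline RMS of the beta carrier outside bursts
#'   (default 0.5).
#' @param seed integer seed; the pair is fully reproducible from it.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(duration_s = 60, fs = 1000, beta_freq = 20,
                         carrier_bw_hz = 6, burst_rate = 0.8,
                         burst_dur_mean_ms = 300, burst_dur_sd_ms = 100,
                         burst_gain = 3,
                         coupling_mode = c("burst_locked", "tonic", "none"),
                         coupling_strength = 0.8, phase_lag_rad = pi / 4,
                         noise_exponent = 2, noise_rms = 1, beta_amp = 0.5,
                         seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  cfg <- list(duration_s = duration_s, fs = fs, beta_freq = beta_freq,
              carrier_bw_hz = carrier_bw_hz, burst_rate = burst_rate,
              burst_dur_mean_ms = burst_dur_mean_ms,
              burst_dur_sd_ms = burst_dur_sd_ms, burst_gain = burst_gain,
              coupling_mode = coupling_mode,
              coupling_strength = coupling_strength,
              phase_lag_rad = phase_lag_rad,
              noise_exponent = noise_exponent, noise_rms = noise_rms,
              beta_amp = beta_amp, seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "coupling_mode")])
  if (!all(is.finite(num))) stop("all synth_config parameters must be finite")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs <= 60) stop("fs must exceed 60 Hz (2 x 30 Hz)")
  if (beta_freq < 13 || beta_freq > 30) stop("beta_freq must lie in [13, 30]")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  if (burst_gain < 1) stop("burst_gain must be >= 1")
  if (burst_rate < 0) stop("burst_rate must be non-negative")
  structure(cfg, class = "synth_config")
}

# 1/f^(exponent/2) amplitude-shaped Gaussian noise, flattened below 1 Hz,
# normalised to target RMS
one_over_f_noise <- function(n, fs, exponent, rms) {
  z <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * fs / n
  shape <- pmax(f, 1)^(-exponent / 2)
  shape[1L] <- 0
  x <- Re(stats::fft(z * shape, inverse = TRUE) / n)
  x / stats::sd(x) * rms
}

# narrow-band unit-RMS carrier: band-passed white noise
narrowband_carrier <- function(n, fs, f0, bw) {
  lo <- max(f0 - bw / 2, 0.5)
  hi <- min(f0 + bw / 2, fs / 2 - 0.5)
  flt <- signal::butter(2, c(lo, hi) * 2 / fs, type = "pass")
  x <- zerophase_filter(flt$b, flt$a, stats::rnorm(n + 2000L))[1001:(1000L + n)]
  x / stats::sd(x)
}

# Poisson burst intervals (samples, 0-based half-open), overlaps merged
sample_burst_intervals <- function(cfg, n) {
  n_events <- stats::rpois(1L, cfg$burst_rate * cfg$duration_s)
  if (n_events == 0L) return(new_intervals())
  onsets <- sort(stats::runif(n_events, 0, cfg$duration_s))
  durs <- numeric(n_events)
  for (i in seq_len(n_events)) {
    repeat {
      d <- stats::rnorm(1L, cfg$burst_dur_mean_ms, cfg$burst_dur_sd_ms)
      if (d >= 120) break
    }
    durs[i] <- d
  }
  start <- floor(onsets * cfg$fs)
  end <- pmin(start + round(durs * cfg$fs / 1000), n)
  keep <- end > start & start < n
  if (!any(keep)) return(new_intervals())
  merge_intervals(new_intervals(start[keep], end[keep]))
}

#' Generate a synthetic STN/cortical recording pair with ground truth
#'
#' @param cfg a [synth_config()].
#' @return list with `recording` (2 channels, labels `STN_1` / `ECOG_1`) and
#'   `truth` (a `synth_truth`: `true_bursts` interval matrix in raw sample
#'   coordinates, `coupling_mode`, `phase_lag_rad`). Same seed, same bits.
#' @export
synth_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$burst_dur_mean_ms < 100)
    warning("burst_dur_mean_ms < 100 ms: most bursts would be removed by the ",
            "downstream minimum-duration filter")
  n <- round(cfg$duration_s * cfg$fs)
  with_seed(cfg$seed, {
    bursts <- sample_burst_intervals(cfg, n)
    # smooth 0/1 burst profile (20 ms ramps) shared by envelope gain and
    # coupling weight
    ind <- as.numeric(interval_mask(bursts, n))
    ind_s <- moving_mean(ind, max(1L, round(0.020 * cfg$fs)))
    b <- narrowband_carrier(n, cfg$fs, cfg$beta_freq, cfg$carrier_bw_hz)
    bq <- Im(analytic_signal(b))  # quadrature: quarter-cycle advanced copy
    locked <- cos(cfg$phase_lag_rad) * b + sin(cfg$phase_lag_rad) * bq
    indep <- narrowband_carrier(n, cfg$fs, cfg$beta_freq, cfg$carrier_bw_hz)
    w <- switch(cfg$coupling_mode,
                none = rep(0, n),
                tonic = rep(cfg$coupling_strength, n),
                burst_locked = cfg$coupling_strength * ind_s)
    gain <- 1 + (cfg$burst_gain - 1) * ind_s
    stn <- cfg$beta_amp * gain * b +
      one_over_f_noise(n, cfg$fs, cfg$noise_exponent, cfg$noise_rms)
    ctx <- cfg$beta_amp * (w * locked + (1 - w) * indep) +
      one_over_f_noise(n, cfg$fs, cfg$noise_exponent, cfg$noise_rms)
    rec <- as_recording(cbind(stn, ctx), cfg$fs,
                        labels = c("STN_1", "ECOG_1"),
                        roles = c("stn", "cortical"))
    truth <- structure(list(true_bursts = bursts,
                            coupling_mode = cfg$coupling_mode,
                            phase_lag_rad = cfg$phase_lag_rad,
                            n_samples = n),
                       class = "synth_truth")
    list(recording = rec, truth = truth)
  })
}

#' Map ground-truth burst intervals onto the trimmed timeline
#'
#' Shifts raw-coordinate truth intervals by the preprocessing head discard
#' and edge trim, clipping to the trimmed signal.
#'
#' @param truth a `synth_truth`.
#' @param fs sampling rate in Hz.
#' @param n_trimmed trimmed signal length in samples.
#' @param head_discard_s,edge_trim_s the trim settings used.
#' @return interval matrix in trimmed coordinates.
#' @export
truth_to_trimmed <- function(truth, fs, n_trimmed, head_discard_s = 60,
                             edge_trim_s = 2) {
  off <- floor(head_discard_s * fs) + floor(edge_trim_s * fs)
  iv <- truth$true_bursts
  if (!nrow(iv)) return(new_intervals())
  start <- pmax(iv[, "start"] - off, 0L)
  end <- pmin(iv[, "end"] - off, n_trimmed)
  keep <- end > start
  new_intervals(start[keep], end[keep])
}
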