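# Peri-burst time-resolved coupling: short sliding windows centred on burst
# onset, stepped across a symmetric span, with the across-burst collection of
# windows at each offset serving as the averaging dimension of the coherence
# and dwPLI estimators. A 15 ms window cannot hold Welch sub-windows, so each
# window contributes a single Hamming-tapered, zero-padded DFT.

#' Sample matched non-burst windows away from all bursts
#'
#' Uniformly samples window start positions such that the window lies at
#' least `exclusion_ms` away from every burst interval. Deterministic under
#' `seed`.
#'
#' @param epochs an `epoch_set` (supplies bursts, fs and signal length).
#' @param n_windows number of windows to draw.
#' @param window_ms window length in ms.
#' @param exclusion_ms minimum distance from any burst in ms (default 50).
#' @param seed integer seed.
#' @return interval matrix of sampled windows.
#' @export
matched_nonburst_windows <- function(epochs, n_windows, window_ms,
                                     exclusion_ms = 50, seed = 1L) {
  fs <- epochs$fs
  w <- max(2L, round(window_ms * fs / 1000))
  excl <- round(exclusion_ms * fs / 1000)
  n <- epochs$n
  eligible <- rep(TRUE, n - w + 1L)
  b <- epochs$bursts
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      lo <- max(b[i, "start"] - excl - w + 1L, 0L) + 1L
      hi <- min(b[i, "end"] + excl, n - w + 1L)
      if (hi >= lo) eligible[lo:hi] <- FALSE
    }
  }
  cand <- which(eligible) - 1L  # 0-based starts
  if (!length(cand))
    stop("no eligible non-burst window positions (bursts + exclusion cover the signal)")
  starts <- with_seed(seed, {
    if (length(cand) >= n_windows) sort(sample(cand, n_windows))
    else sort(sample(cand, n_windows, replace = TRUE))
  })
  new_intervals(starts, starts + w)
}

#' Peri-burst sliding-window coupling trace
#'
#' For every offset in `[-span_ms, span_ms]` (step `step_ms`), a window of
#' `window_ms` centred at (burst onset + offset) is extracted from each
#' qualifying burst; the across-burst window collection gives one pooled
#' coherence and dwPLI value per offset, band-averaged over beta. Bursts
#' whose peri-onset context leaves the recording are dropped (and counted).
#' A matched non-burst baseline is built from windows sampled at least
#' `exclusion_ms` from any burst; `n_baseline_draws` replicate draws give the
#' baseline mean and SD.
#'
#' @param stn,ctx `beta_signal`s on the trimmed timeline.
#' @param epochs `epoch_set` for the STN channel.
#' @param window_ms sliding window length in ms (default 15).
#' @param step_ms step between window centres in ms (default 5).
#' @param span_ms half-width of the peri-onset interval in ms (default 50).
#' @param band beta band in Hz.
#' @param nfft zero-padded DFT length (default 256) defining the frequency
#'   grid of the short windows.
#' @param exclusion_ms baseline exclusion zone around bursts (default 50).
#' @param n_baseline_draws replicate baseline draws (default 20).
#' @param seed integer seed for baseline sampling.
#' @return a `peri_burst_trace`: `offsets_ms`, `coh_trace`, `dwpli_trace`,
#'   `baseline_coh`, `baseline_dwpli` (+ `_sd`), `n_bursts_used`,
#'   `n_dropped`.
#' @export
peri_burst_trace <- function(stn, ctx, epochs, window_ms = 15, step_ms = 5,
                             span_ms = 50, band = c(13, 30), nfft = 256L,
                             exclusion_ms = 50, n_baseline_draws = 20L,
                             seed = 1L) {
  fs <- stn$fs
  w <- max(2L, round(window_ms * fs / 1000))
  half <- w %/% 2L
  step <- max(1L, round(step_ms * fs / 1000))
  span <- round(span_ms * fs / 1000)
  offsets <- seq.int(-span, span, by = step)
  n <- length(stn$x)
  onsets <- epochs$bursts[, "start"]
  ok <- (onsets - span - half) >= 0L & (onsets + span - half + w) <= n
  n_dropped <- sum(!ok)
  onsets <- onsets[ok]
  if (length(onsets) < 2L)
    stop("need at least 2 bursts with full peri-onset context (",
         length(onsets), " available)")
  band_idx <- select_band_indices(w, fs, band, nfft = nfft)
  pooled_band <- function(segs) {
    sp <- coupling_spectrum(
      cross_spectra(stn$x, ctx$x, segs, fs, w, overlap = 0, nfft = nfft),
      band_idx)
    c(coh = sp$coh_band, dwpli = sp$dwpli_band)
  }
  trace <- vapply(offsets, function(off) {
    starts <- onsets + off - half
    pooled_band(new_intervals(starts, starts + w))
  }, c(coh = 0, dwpli = 0))
  base <- vapply(seq_len(n_baseline_draws), function(d) {
    wins <- matched_nonburst_windows(epochs, length(onsets),
                                     window_ms, exclusion_ms,
                                     seed = derive_seed(seed, "baseline", d))
    pooled_band(wins)
  }, c(coh = 0, dwpli = 0))
  structure(list(
    offsets_ms = offsets / fs * 1000,
    coh_trace = trace["coh", ], dwpli_trace = trace["dwpli", ],
    baseline_coh = mean(base["coh", ]), baseline_dwpli = mean(base["dwpli", ]),
    baseline_coh_sd = stats::sd(base["coh", ]),
    baseline_dwpli_sd = stats::sd(base["dwpli", ]),
    window_ms = window_ms, step_ms = step_ms, span_ms = span_ms,
    n_bursts_used = length(onsets), n_dropped = n_dropped),
    class = "peri_burst_trace")
}

#' @export
print.peri_burst_trace <- function(x, ...) {
  cat(sprintf("<peri_burst_trace> %d offsets (%g..%g ms), %d bursts (%d dropped)\n",
              length(x$offsets_ms), min(x$offsets_ms), max(x$offsets_ms),
              x$n_bursts_used, x$n_dropped))
  cat(sprintf("  coherence: baseline %.4f (sd %.4f), trace range [%.4f, %.4f]\n",
              x$baseline_coh, x$baseline_coh_sd, min(x$coh_trace),
              max(x$coh_trace)))
  invisible(x)
}

#' Plot a peri-burst coupling trace
#'
#' Both metrics against offset from burst onset, with the matched non-burst
#' baseline band (mean +/- 2 SD) shaded.
#'
#' @param x a `peri_burst_trace`.
#' @param metric `"coh"` or `"dwpli"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.peri_burst_trace <- function(x, metric = c("coh", "dwpli"), ...) {
  metric <- match.arg(metric)
  tr <- if (metric == "coh") x$coh_trace else x$dwpli_trace
  b <- if (metric == "coh") x$baseline_coh else x$baseline_dwpli
  bs <- if (metric == "coh") x$baseline_coh_sd else x$baseline_dwpli_sd
  ylim <- range(tr, b - 2 * bs, b + 2 * bs)
  graphics::plot(x$offsets_ms, tr, type = "o", pch = 16,
                 xlab = "offset from burst onset (ms)",
                 ylab = if (metric == "coh") "beta coherence" else "beta dwPLI",
                 ylim = ylim, ...)
  graphics::polygon(c(x$offsets_ms, rev(x$offsets_ms)),
                    c(rep(b - 2 * bs, length(x$offsets_ms)),
                      rep(b + 2 * bs, length(x$offsets_ms))),
                    col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::abline(h = b, lty = 2)
  graphics::abline(v = 0, col = "red", lty = 3)
  invisible(x)
}
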