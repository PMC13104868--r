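# Per-pair burst vs non-burst coupling: build the burst and (capped,
# randomly sampled) non-burst segment sets, estimate coherence and dwPLI on
# pooled Welch sub-windows, band-average over beta with a shared set of
# frequency bins, and report the burst - non-burst differences.

#' Randomly sample non-burst segments up to a cap
#'
#' To avoid bias from unequal segment counts, at most `cap` non-burst
#' segments per contact pair enter the coupling estimate. Sampling is uniform
#' without replacement and deterministic under `seed`; the selected segments
#' keep their original temporal order.
#'
#' @param nonbursts interval matrix of non-burst epochs.
#' @param cap maximum number of segments (default 100).
#' @param seed integer seed for the sampling stream.
#' @return interval matrix with `min(cap, n)` rows.
#' @export
sample_nonburst_segments <- function(nonbursts, cap = 100L, seed = 1L) {
  n <- nrow(nonbursts)
  if (n <= cap) return(nonbursts)
  keep <- with_seed(seed, sort(sample.int(n, cap)))
  nonbursts[keep, , drop = FALSE]
}

#' Burst vs non-burst coupling for one STN-cortical contact pair
#'
#' Cortical samples are taken at the identical (STN-defined) epoch sample
#' indices. The Welch sub-window length is `min(window_len_max, shortest
#' segment)` so every epoch contributes at least one sub-window, and the
#' beta-band frequency indices implied by that window are shared by the
#' burst, non-burst and (downstream) surrogate estimates.
#'
#' @param stn,ctx `beta_signal` objects on the same trimmed timeline.
#' @param epochs `epoch_set` detected on the STN channel.
#' @param band beta band in Hz.
#' @param window_len_max upper bound on the Welch sub-window (default 256).
#' @param overlap Welch overlap fraction (default 0.5).
#' @param nonburst_cap cap on sampled non-burst segments (default 100).
#' @param seed seed for non-burst sampling.
#' @return a `pair_coupling` object: `burst` and `nonburst`
#'   `coupling_spectrum`s, scalar differences `diff_coh`, `diff_dwpli`
#'   (burst - non-burst), segment bookkeeping, and the shared Welch settings.
#' @export
pair_coupling <- function(stn, ctx, epochs, band = c(13, 30),
                          window_len_max = 256L, overlap = 0.5,
                          nonburst_cap = 100L, seed = 1L) {
  stopifnot(inherits(stn, "beta_signal"), inherits(ctx, "beta_signal"))
  if (length(stn$x) != length(ctx$x))
    stop("STN and cortical signals must share one trimmed timeline")
  if (!nrow(epochs$bursts)) stop("no bursts detected for this pair")
  nb <- sample_nonburst_segments(epochs$nonbursts, nonburst_cap, seed)
  if (!nrow(nb)) stop("no non-burst segments available for this pair")
  wl <- min(window_len_max,
            min(interval_lengths(epochs$bursts)),
            min(interval_lengths(nb)))
  band_idx <- select_band_indices(wl, stn$fs, band)
  cs_b <- cross_spectra(stn$x, ctx$x, epochs$bursts, stn$fs, wl, overlap)
  cs_n <- cross_spectra(stn$x, ctx$x, nb, stn$fs, wl, overlap)
  burst <- coupling_spectrum(cs_b, band_idx)
  nonburst <- coupling_spectrum(cs_n, band_idx)
  structure(list(
    stn_label = stn$source_label, ctx_label = ctx$source_label,
    burst = burst, nonburst = nonburst,
    diff_coh = burst$coh_band - nonburst$coh_band,
    diff_dwpli = burst$dwpli_band - nonburst$dwpli_band,
    n_bursts = nrow(epochs$bursts), n_nonburst_sampled = nrow(nb),
    segments = list(burst = epochs$bursts, nonburst = nb),
    window_len = wl, overlap = overlap, band = band, band_idx = band_idx,
    fs = stn$fs),
    class = "pair_coupling")
}

#' @export
print.pair_coupling <- function(x, ...) {
  cat(sprintf("<pair_coupling> %s ~ %s  (%d bursts, %d non-burst segments, window %d)\n",
              x$stn_label %||% "STN", x$ctx_label %||% "CTX",
              x$n_bursts, x$n_nonburst_sampled, x$window_len))
  cat(sprintf("  coherence: burst %.4f  non-burst %.4f  diff %+.4f\n",
              x$burst$coh_band, x$nonburst$coh_band, x$diff_coh))
  cat(sprintf("  dwPLI:     burst %.4f  non-burst %.4f  diff %+.4f\n",
              x$burst$dwpli_band, x$nonburst$dwpli_band, x$diff_dwpli))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate a list of pair couplings
#'
#' @param pcs list of `pair_coupling` objects.
#' @return data.frame, one row per pair, with the band-averaged values and
#'   their differences.
#' @export
pair_coupling_table <- function(pcs) {
  do.call(rbind, lapply(pcs, function(p) {
    data.frame(stn_label = p$stn_label %||% NA_character_,
               ctx_label = p$ctx_label %||% NA_character_,
               coh_burst = p$burst$coh_band,
               coh_nonburst = p$nonburst$coh_band,
               coh_diff = p$diff_coh,
               dwpli_burst = p$burst$dwpli_band,
               dwpli_nonburst = p$nonburst$dwpli_band,
               dwpli_diff = p$diff_dwpli,
               n_bursts = p$n_bursts,
               n_nonburst_sampled = p$n_nonburst_sampled,
               stringsAsFactors = FALSE)
  }))
}
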