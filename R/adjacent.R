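# Burst-adjacent analysis: each burst is matched with equal-length windows
# carved from the immediately preceding and following non-burst intervals,
# and coupling is pooled per role (burst / pre / post) across bursts.

#' Match each burst with equal-length pre and post non-burst windows
#'
#' For a burst of length L, the pre window is the last L samples of the
#' nearest earlier non-burst interval at least L long, the post window the
#' first L samples of the nearest later such interval; shorter intervening
#' intervals are skipped rather than shrunk, keeping durations exactly
#' matched. A triplet is valid only when both sides have a qualifying
#' neighbour. (Requiring the *immediately* adjacent interval to be long
#' enough would systematically discard long bursts, biasing the retained
#' set toward short ones; see the methods vignette.)
#'
#' @param epochs an `epoch_set` with at least 2 bursts.
#' @return data.frame with one row per burst: `burst_start`, `burst_end`,
#'   `pre_start`, `pre_end`, `post_start`, `post_end` (NA when missing),
#'   `valid`.
#' @export
build_adjacent_triplets <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  b <- epochs$bursts
  nb <- epochs$nonbursts
  if (nrow(b) < 2L)
    stop("burst-adjacent analysis needs at least 2 bursts (pair should be excluded)")
  out <- data.frame(burst_start = b[, "start"], burst_end = b[, "end"],
                    pre_start = NA_integer_, pre_end = NA_integer_,
                    post_start = NA_integer_, post_end = NA_integer_,
                    valid = FALSE)
  len_nb <- interval_lengths(nb)
  for (i in seq_len(nrow(b))) {
    L <- b[i, "end"] - b[i, "start"]
    earlier <- which(nb[, "end"] <= b[i, "start"] & len_nb >= L)
    later <- which(nb[, "start"] >= b[i, "end"] & len_nb >= L)
    ok_pre <- ok_post <- FALSE
    if (length(earlier)) {
      j <- earlier[length(earlier)]  # nearest earlier long-enough interval
      out$pre_start[i] <- nb[j, "end"] - L
      out$pre_end[i] <- nb[j, "end"]
      ok_pre <- TRUE
    }
    if (length(later)) {
      j <- later[1L]  # nearest later long-enough interval
      out$post_start[i] <- nb[j, "start"]
      out$post_end[i] <- nb[j, "start"] + L
      ok_post <- TRUE
    }
    out$valid[i] <- ok_pre && ok_post
  }
  out
}

#' Burst vs pre-burst vs post-burst coupling for one pair
#'
#' Pools Welch sub-windows per role across all valid triplets and
#' band-averages coherence and dwPLI with a shared set of frequency bins.
#'
#' @param stn,ctx `beta_signal`s on the trimmed timeline.
#' @param triplets output of [build_adjacent_triplets()].
#' @param band beta band in Hz.
#' @param window_len_max,overlap Welch settings as in [pair_coupling()].
#' @return an `adjacent_coupling`: per-role `coh` and `dwpli` band averages,
#'   `n_valid`, `n_invalid`, and the burst-minus-pre / burst-minus-post
#'   differences.
#' @export
adjacent_coupling <- function(stn, ctx, triplets, band = c(13, 30),
                              window_len_max = 256L, overlap = 0.5) {
  tv <- triplets[triplets$valid, , drop = FALSE]
  if (nrow(tv) < 2L)
    stop("need at least 2 valid burst/pre/post triplets (", nrow(tv), " found)")
  segs <- list(
    burst = new_intervals(tv$burst_start, tv$burst_end),
    pre = new_intervals(tv$pre_start, tv$pre_end),
    post = new_intervals(tv$post_start, tv$post_end))
  wl <- min(window_len_max, min(unlist(lapply(segs, interval_lengths))))
  band_idx <- select_band_indices(wl, stn$fs, band)
  spec <- lapply(segs, function(sg) {
    coupling_spectrum(cross_spectra(stn$x, ctx$x, sg, stn$fs, wl, overlap),
                      band_idx)
  })
  structure(list(
    coh = vapply(spec, `[[`, 0, "coh_band"),
    dwpli = vapply(spec, `[[`, 0, "dwpli_band"),
    diff_coh_pre = spec$burst$coh_band - spec$pre$coh_band,
    diff_coh_post = spec$burst$coh_band - spec$post$coh_band,
    diff_dwpli_pre = spec$burst$dwpli_band - spec$pre$dwpli_band,
    diff_dwpli_post = spec$burst$dwpli_band - spec$post$dwpli_band,
    n_valid = nrow(tv), n_invalid = sum(!triplets$valid),
    window_len = wl, band_idx = band_idx),
    class = "adjacent_coupling")
}

#' @export
print.adjacent_coupling <- function(x, ...) {
  cat(sprintf("<adjacent_coupling> %d valid triplets (%d invalid), window %d\n",
              x$n_valid, x$n_invalid, x$window_len))
  cat(sprintf("  coherence burst/pre/post: %.4f / %.4f / %.4f\n",
              x$coh["burst"], x$coh["pre"], x$coh["post"]))
  cat(sprintf("  dwPLI     burst/pre/post: %.4f / %.4f / %.4f\n",
              x$dwpli["burst"], x$dwpli["pre"], x$dwpli["post"]))
  invisible(x)
}
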