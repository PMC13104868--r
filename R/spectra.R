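# Welch cross-spectral engine shared by coherence, dwPLI, surrogate tests and
# the peri-burst sliding windows. Segments (bursts, sampled non-burst epochs,
# peri-event windows) are cut into Hamming-tapered, mean-removed sub-windows
# with 50% overlap; sub-windows are pooled across segments so that short
# epochs still contribute to a common estimate on one frequency grid.

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# sub-window start positions (0-based) for half-open segments
sub_starts <- function(segs, window_len, step) {
  if (!nrow(segs)) return(list(starts = integer(0), skipped = 0L))
  out <- vector("list", nrow(segs))
  skipped <- 0L
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, "start"]; e <- segs[i, "end"]
    if (e - s < window_len) { skipped <- skipped + 1L; next }
    out[[i]] <- seq.int(s, e - window_len, by = step)
  }
  list(starts = as.integer(unlist(out)), skipped = skipped)
}

# tapered, mean-removed, optionally circularly-shifted sub-window DFTs;
# returns an (nfreq x K) complex matrix of one-sided spectra
gather_fft <- function(sig, idx0, taper, nfft, shift = 0L) {
  n <- length(sig)
  wl <- nrow(idx0)
  if (shift != 0L) {
    z <- sig[((idx0 - shift) %% n) + 1L]
  } else {
    z <- sig[idx0 + 1L]
  }
  dim(z) <- dim(idx0)
  z <- (z - rep(colMeans(z), each = wl)) * taper
  if (nfft > wl) z <- rbind(z, matrix(0, nfft - wl, ncol(z)))
  nf <- nfft %/% 2L + 1L
  stats::mvfft(z)[seq_len(nf), , drop = FALSE]
}

#' Pooled Welch cross- and auto-spectra over a segment collection
#'
#' Computes per-sub-window one-sided cross spectra `Sxy = X conj(Y)` and auto
#' spectra `Sxx`, `Syy` for two channels over a list of equal-role segments,
#' pooling sub-windows from every segment on a common frequency grid.
#' Segments shorter than `window_len` are skipped (their count is returned).
#'
#' @param x,y numeric vectors, equal length (e.g. trimmed STN and cortical
#'   beta signals).
#' @param segs interval matrix (0-based half-open sample intervals).
#' @param fs sampling rate in Hz.
#' @param window_len Welch sub-window length in samples.
#' @param overlap fractional overlap of consecutive sub-windows in `[0, 1)`;
#'   default 0.5.
#' @param shift circular shift (samples) applied to `x` only, used by the
#'   surrogate machinery; default 0.
#' @param nfft DFT length (>= `window_len`; zero-padded when larger).
#' @return a `cross_spectra` object: `freqs`, complex matrix `Sxy`
#'   (nfreq x K), real matrices `Sxx`, `Syy`, `n_sub` (K), `n_skipped`,
#'   `window_len`, `nfft`, `fs`.
#' @export
cross_spectra <- function(x, y, segs, fs, window_len, overlap = 0.5,
                          shift = 0L, nfft = window_len) {
  stopifnot(length(x) == length(y), window_len >= 2L, nfft >= window_len)
  if (overlap < 0 || overlap >= 1) stop("'overlap' must lie in [0, 1)")
  step <- max(1L, window_len - floor(window_len * overlap))
  ss <- sub_starts(segs, window_len, step)
  if (!length(ss$starts))
    stop("zero usable segments: every segment is shorter than window_len = ",
         window_len)
  idx0 <- outer(0:(window_len - 1L), ss$starts, `+`)
  taper <- hamming_window(window_len)
  X <- gather_fft(x, idx0, taper, nfft, shift = shift)
  Y <- gather_fft(y, idx0, taper, nfft, shift = 0L)
  nf <- nrow(X)
  structure(list(
    freqs = (0:(nf - 1L)) * fs / nfft,
    Sxy = X * Conj(Y),
    Sxx = Mod(X)^2, Syy = Mod(Y)^2,
    n_sub = ncol(X), n_skipped = ss$skipped,
    window_len = window_len, nfft = nfft, fs = fs),
    class = "cross_spectra")
}

#' Magnitude-squared coherence from pooled spectra
#'
#' `C(f) = |sum Sxy|^2 / (sum Sxx * sum Syy)` over pooled sub-windows.
#' With a single sub-window the estimator is identically 1; the result is
#' then flagged degenerate with a warning.
#'
#' @param cs a `cross_spectra` object.
#' @return list with `freqs`, `coh` in `[0, 1]`, `n_sub`, `degenerate`.
#' @export
msc <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  degenerate <- cs$n_sub < 2L
  if (degenerate)
    warning("coherence from a single sub-window is identically 1; flagged degenerate")
  sxy <- rowSums(cs$Sxy)
  denom <- rowSums(cs$Sxx) * rowSums(cs$Syy)
  coh <- ifelse(denom > 0, Mod(sxy)^2 / denom, 0)
  list(freqs = cs$freqs, coh = pmin(coh, 1), n_sub = cs$n_sub,
       degenerate = degenerate)
}

#' Debiased weighted phase lag index from pooled spectra
#'
#' Debiased squared WPLI computed from the imaginary part of the per-sub-window
#' cross spectrum. With `I_j = Im(Sxy_j)` over `n` sub-windows:
#' `dwPLI(f) = ((sum I_j)^2 - sum I_j^2) / ((sum |I_j|)^2 - sum I_j^2)`.
#' The estimator is insensitive to zero-lag (purely real) coupling and to
#' amplitude scaling, and can be slightly negative under the null because of
#' the debiasing. Frequencies where the denominator is exactly zero (all
#' imaginary parts zero, e.g. strictly zero-lag coupling) are defined as 0 and
#' flagged.
#'
#' @param cs a `cross_spectra` object with at least 2 pooled sub-windows.
#' @return list with `freqs`, `dwpli` (<= 1, possibly slightly negative),
#'   `n_sub`, `zero_denom` (logical per frequency).
#' @export
dwpli <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (cs$n_sub < 2L)
    stop("dwPLI is undefined for a single sub-window (need >= 2)")
  im <- Im(cs$Sxy)
  s1 <- rowSums(im)
  s2 <- rowSums(im^2)
  sa <- rowSums(abs(im))
  num <- s1^2 - s2
  den <- sa^2 - s2
  zero <- den == 0
  d <- numeric(length(den))
  d[!zero] <- num[!zero] / den[!zero]
  list(freqs = cs$freqs, dwpli = d, n_sub = cs$n_sub, zero_denom = zero)
}

#' Beta-band frequency indices on a Welch grid
#'
#' Indices of the one-sided frequency grid `k * fs / nfft` falling inside the
#' beta band. The indices are defined once per contact pair (from the grid
#' implied by the pair's Welch window) and reused verbatim for burst,
#' non-burst and surrogate estimates so that band averages are comparable.
#'
#' @param window_len Welch sub-window length in samples.
#' @param fs sampling rate in Hz.
#' @param band length-2 band edges in Hz (default `c(13, 30)`, inclusive).
#' @param nfft DFT length (default `window_len`).
#' @return integer indices into the frequency grid.
#' @export
select_band_indices <- function(window_len, fs, band = c(13, 30),
                                nfft = window_len) {
  nf <- nfft %/% 2L + 1L
  freqs <- (0:(nf - 1L)) * fs / nfft
  idx <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  if (!length(idx)) {
    wl_min <- window_len
    while (wl_min <= fs) {
      wl_min <- wl_min + 1L
      fr <- (0:(wl_min %/% 2L)) * fs / wl_min
      if (any(fr >= band[1] & fr <= band[2])) break
    }
    stop(sprintf(
      "no frequency bin inside [%g, %g] Hz on the grid of window_len = %d (step %.3f Hz); need window_len >= %d",
      band[1], band[2], window_len, fs / nfft, wl_min))
  }
  idx
}

# band-averaged coherence + dwPLI summary for one condition
coupling_spectrum <- function(cs, band_idx) {
  m <- msc(cs)
  d <- dwpli(cs)
  structure(list(
    freqs = cs$freqs, coh = m$coh, dwpli = d$dwpli, band_idx = band_idx,
    coh_band = mean(m$coh[band_idx]), dwpli_band = mean(d$dwpli[band_idx]),
    n_sub = cs$n_sub, degenerate = m$degenerate,
    zero_denom_band = any(d$zero_denom[band_idx])),
    class = "coupling_spectrum")
}
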