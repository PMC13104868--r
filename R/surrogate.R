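# Circular time-shift surrogate testing. The STN beta signal is rotated
# relative to the cortical signal by a random offset (uniform between 0.5 and
# 5 s), which preserves both marginal spectra while destroying the temporal
# alignment between the channels; coupling recomputed with identical epoch
# boundaries, Welch settings, band bins and non-burst subset gives one draw
# from the null. The rotation is applied to the cortical channel so that the
# STN signal keeps its alignment with its own envelope-defined epochs: the
# observed and surrogate statistics then share the same STN amplitude
# structure within each condition, which is what makes the empirical
# p-values calibrated (see the methods vignette).

#' Circularly shift a vector
#'
#' `out[i] = x[(i - shift) mod n]`: the content of `x` is rotated forward in
#' time by `shift` samples, wrapping at the ends.
#'
#' @param x numeric vector.
#' @param shift_samples integer in `[0, length(x))`.
#' @return shifted vector, same length.
#' @export
circular_shift <- function(x, shift_samples) {
  n <- length(x)
  s <- as.integer(shift_samples)
  if (s < 0L || s >= n) stop("shift_samples must lie in [0, length(x))")
  if (s == 0L) return(x)
  c(x[(n - s + 1L):n], x[1L:(n - s)])
}

#' Surrogate null distributions for one pair and condition
#'
#' Generates `n_surrogates` circular rotations of the STN beta signal
#' relative to the cortical signal (uniform in `shift_range_s`, rounded to
#' whole samples; applied to the cortical channel so STN envelope/epoch
#' alignment is preserved), recomputes the band-averaged coherence and dwPLI
#' of the given condition with exactly the segment boundaries, Welch window,
#' frequency bins and sampled non-burst subset stored in `pc`, and returns
#' empirical p-values `p = #(null >= observed) / n_surrogates` for both
#' metrics. A p of 0 is reported as `< 1/n_surrogates` in printed summaries.
#' The RNG stream is derived deterministically from
#' `(seed, pair id, condition)`.
#'
#' @param pc a `pair_coupling` for this pair (holds segments and settings).
#' @param stn,ctx the `beta_signal`s the pair was computed from.
#' @param condition `"burst"` or `"nonburst"`.
#' @param n_surrogates number of surrogate datasets (default 200).
#' @param shift_range_s shift range in seconds (default `c(0.5, 5)`).
#' @param seed master seed (default 1).
#' @return list with one `surrogate_null` per metric (`coh`, `dwpli`); each
#'   has `metric`, `condition`, `null_values`, `observed`, `p_emp`,
#'   `n_surrogates`, `shift_range_s`, `seed`.
#' @export
surrogate_test <- function(pc, stn, ctx, condition = c("nonburst", "burst"),
                           n_surrogates = 200L, shift_range_s = c(0.5, 5),
                           seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(pc, "pair_coupling"))
  n <- length(stn$x)
  fs <- pc$fs
  if (shift_range_s[2] * fs >= n)
    stop("upper shift bound (", shift_range_s[2], " s) must be shorter than the signal")
  segs <- pc$segments[[condition]]
  wl <- pc$window_len
  step <- max(1L, wl - floor(wl * pc$overlap))
  ss <- sub_starts(segs, wl, step)
  idx0 <- outer(0:(wl - 1L), ss$starts, `+`)
  taper <- hamming_window(wl)
  bi <- pc$band_idx
  # STN spectra do not depend on the rotation: compute once
  Xb <- gather_fft(stn$x, idx0, taper, wl)[bi, , drop = FALSE]
  sxx <- rowSums(Mod(Xb)^2)
  pair_id <- paste(pc$stn_label %||% "stn", pc$ctx_label %||% "ctx", sep = "~")
  sub_seed <- derive_seed(seed, pair_id, condition)
  shifts <- with_seed(sub_seed,
    as.integer(round(stats::runif(n_surrogates, shift_range_s[1],
                                  shift_range_s[2]) * fs)))
  null_coh <- null_dw <- numeric(n_surrogates)
  for (k in seq_len(n_surrogates)) {
    Yb <- gather_fft(ctx$x, idx0, taper, wl, shift = shifts[k])[bi, , drop = FALSE]
    sxy <- Xb * Conj(Yb)
    coh <- Mod(rowSums(sxy))^2 / (sxx * rowSums(Mod(Yb)^2))
    im <- Im(sxy)
    s1 <- rowSums(im); s2 <- rowSums(im^2); sa <- rowSums(abs(im))
    den <- sa^2 - s2
    dw <- ifelse(den == 0, 0, (s1^2 - s2) / den)
    null_coh[k] <- mean(coh)
    null_dw[k] <- mean(dw)
  }
  obs <- c(coh = pc[[condition]]$coh_band, dwpli = pc[[condition]]$dwpli_band)
  mk <- function(metric, null_values, observed) {
    structure(list(metric = metric, condition = condition,
                   null_values = null_values, observed = observed,
                   p_emp = mean(null_values >= observed),
                   n_surrogates = n_surrogates,
                   shift_range_s = shift_range_s, seed = seed,
                   shifts = shifts),
              class = "surrogate_null")
  }
  list(coh = mk("coh", null_coh, obs["coh"]),
       dwpli = mk("dwpli", null_dw, obs["dwpli"]))
}

#' Surrogate null for a single metric
#'
#' Convenience wrapper around [surrogate_test()] returning only the requested
#' metric's `surrogate_null`.
#'
#' @inheritParams surrogate_test
#' @param metric `"coh"` or `"dwpli"`.
#' @export
surrogate_null <- function(pc, stn, ctx, condition = c("nonburst", "burst"),
                           metric = c("coh", "dwpli"), n_surrogates = 200L,
                           shift_range_s = c(0.5, 5), seed = 1L) {
  metric <- match.arg(metric)
  surrogate_test(pc, stn, ctx, condition, n_surrogates, shift_range_s,
                 seed)[[metric]]
}

#' @export
print.surrogate_null <- function(x, ...) {
  ptxt <- if (x$p_emp == 0) sprintf("< %.4g", 1 / x$n_surrogates)
          else sprintf("= %.4g", x$p_emp)
  cat(sprintf("<surrogate_null> %s, %s: observed %.4f vs %d surrogates (p %s)\n",
              x$metric, x$condition, x$observed, x$n_surrogates, ptxt))
  invisible(x)
}

#' Empirical CDF of surrogate-test p-values
#'
#' Standard right-continuous ECDF over `[0, 1]`.
#'
#' @param p numeric vector of p-values (at least one).
#' @return a `stats::ecdf` step function.
#' @export
null_ecdf <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  stats::ecdf(p)
}
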