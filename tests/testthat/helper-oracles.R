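# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's vectorised code paths: explicit DFT
# sums, sample-by-sample run scans, and enumeration-based tests.

# wrap a plain vector as a beta_signal
make_beta <- function(x, fs = 1000, label = "X") {
  structure(list(x = as.numeric(x), fs = fs, band = c(13, 30),
                 source_label = label),
            class = "beta_signal")
}

make_envelope <- function(a, fs = 1000, label = "STN_1") {
  structure(list(a = as.numeric(a), fs = fs, smooth_ms = 50,
                 source_label = label),
            class = "envelope")
}

make_epochs <- function(bursts, nonbursts, fs = 1000, n = NULL,
                        label = "STN_1") {
  structure(list(bursts = bursts, nonbursts = nonbursts,
                 thresholds = c(burst = NA_real_, nonburst = NA_real_),
                 min_dur = 1L, fs = fs,
                 n = if (is.null(n)) max(bursts[, 2], nonbursts[, 2]) else n,
                 source_label = label),
            class = "epoch_set")
}

iv <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# naive single-sub-window DFT: explicit exponential sums, one bin at a time
naive_dft <- function(z, nfft) {
  n <- length(z)
  nf <- nfft %/% 2 + 1
  out <- complex(nf)
  for (k in 0:(nf - 1)) {
    s <- 0 + 0i
    for (t in 0:(n - 1)) s <- s + z[t + 1] * exp(-2i * pi * k * t / nfft)
    out[k + 1] <- s
  }
  out
}

# brute-force Welch cross/auto spectra, coherence and dwPLI for a list of
# (x, y) segment pairs; loops everywhere, no pooling shortcuts
naive_welch_coupling <- function(x, y, segs, fs, wl, overlap = 0.5,
                                 nfft = wl) {
  step <- max(1, wl - floor(wl * overlap))
  h <- if (wl == 1) 1 else 0.54 - 0.46 * cos(2 * pi * (0:(wl - 1)) / (wl - 1))
  Sxy <- list(); Sxx <- list(); Syy <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1]; e <- segs[i, 2]
    if (e - s < wl) next
    st <- s
    while (st + wl <= e) {
      xs <- x[(st + 1):(st + wl)]; ys <- y[(st + 1):(st + wl)]
      xs <- (xs - mean(xs)) * h; ys <- (ys - mean(ys)) * h
      X <- naive_dft(c(xs, rep(0, nfft - wl)), nfft)
      Y <- naive_dft(c(ys, rep(0, nfft - wl)), nfft)
      Sxy[[length(Sxy) + 1]] <- X * Conj(Y)
      Sxx[[length(Sxx) + 1]] <- Mod(X)^2
      Syy[[length(Syy) + 1]] <- Mod(Y)^2
      st <- st + step
    }
  }
  K <- length(Sxy)
  nf <- nfft %/% 2 + 1
  coh <- dw <- numeric(nf)
  for (f in seq_len(nf)) {
    sxy <- 0 + 0i; sxx <- 0; syy <- 0
    I <- numeric(K)
    for (j in seq_len(K)) {
      sxy <- sxy + Sxy[[j]][f]
      sxx <- sxx + Sxx[[j]][f]
      syy <- syy + Syy[[j]][f]
      I[j] <- Im(Sxy[[j]][f])
    }
    coh[f] <- Mod(sxy)^2 / (sxx * syy)
    # at DC/Nyquist the DFT is analytically real; kill the ~1e-16 imaginary
    # residue the explicit exponential sum leaves there
    if (sum(abs(I)) < 1e-9 * sqrt(sxx * syy)) I[] <- 0
    den <- sum(abs(I))^2 - sum(I^2)
    dw[f] <- if (den == 0) 0 else (sum(I)^2 - sum(I^2)) / den
  }
  list(coh = coh, dwpli = dw, n_sub = K)
}

# sample-by-sample labeling then run extraction (burst detector oracle)
naive_detect <- function(a, fs, burst_pct = 75, nonburst_pct = 50,
                         min_dur_ms = 100) {
  thr_b <- as.numeric(stats::quantile(a, burst_pct / 100, type = 7))
  thr_n <- as.numeric(stats::quantile(a, nonburst_pct / 100, type = 7))
  min_dur <- max(1, round(min_dur_ms * fs / 1000))
  scan <- function(lab) {
    runs <- list()
    i <- 1
    while (i <= length(lab)) {
      if (lab[i]) {
        j <- i
        while (j <= length(lab) && lab[j]) j <- j + 1
        if (j - i >= min_dur) runs[[length(runs) + 1]] <- c(i - 1, j - 1)
        i <- j
      } else i <- i + 1
    }
    if (!length(runs)) return(iv())
    do.call(rbind, lapply(runs, function(r) iv(r[1], r[2])))
  }
  list(bursts = scan(a > thr_b), nonbursts = scan(a < thr_n))
}

# exact two-sided Wilcoxon signed-rank p by enumeration of all sign flips
# (no ties, no zeros)
enum_wilcoxon_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(p, 1)
}

# synthetic pair generation + analysis used by cohort-level checks
quick_pair <- function(seed, mode = "burst_locked", duration_s = 30, ...) {
  analyze_synth_pair(synth_config(duration_s = duration_s,
                                  coupling_mode = mode, seed = seed, ...))
}
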