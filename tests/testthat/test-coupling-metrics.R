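# Welch cross-spectra, coherence, dwPLI, band selection, segment sampling.

fs <- 1000

test_that("self cross-spectrum is real and equals the auto-spectrum", {
  set.seed(1)
  x <- rnorm(2000)
  cs <- cross_spectra(x, x, iv(0, 2000), fs, 256L)
  expect_lt(max(abs(Im(cs$Sxy))), 1e-8 * max(cs$Sxx))
  expect_equal(Re(cs$Sxy), cs$Sxx, tolerance = 1e-12)
})

test_that("a quarter-cycle delay shows up as a pi/2 cross-spectral phase", {
  t <- (0:2047) / fs
  x <- sin(2 * pi * 20 * t)
  y <- sin(2 * pi * 20 * (t - 1 / 80))  # quarter cycle of 20 Hz
  cs <- cross_spectra(x, y, iv(0, 2048), fs, 256L)
  bin20 <- which.min(abs(cs$freqs - 20))
  ph <- Arg(rowSums(cs$Sxy))[bin20]
  expect_lt(abs(abs(ph) - pi / 2), 0.05)
})

test_that("coherence of independent noise shrinks like 1/K", {
  set.seed(7)
  mean_coh <- function(n_seg) {
    x <- rnorm(n_seg * 128); y <- rnorm(n_seg * 128)
    cs <- cross_spectra(x, y, iv(0, n_seg * 128), fs, 128L, overlap = 0)
    mean(msc(cs)$coh[-1])  # drop DC
  }
  c100 <- mean(replicate(5, mean_coh(100)))
  c20 <- mean(replicate(5, mean_coh(20)))
  expect_lt(c100, 0.1)
  expect_lt(c100, c20)      # decreasing with sub-window count
  expect_lt(abs(c100 - 1 / 100), 0.01)  # E[C] ~ 1/K under independence
})

test_that("coherence is 1 for a scaled copy and ~0.5 at unit SNR", {
  set.seed(8)
  x <- rnorm(6400)
  cs <- cross_spectra(x, 3.2 * x, iv(0, 6400), fs, 256L)
  expect_equal(max(msc(cs)$coh), 1, tolerance = 1e-10)
  expect_gt(min(msc(cs)$coh), 0.999)

  # y = x + independent noise of equal power -> C = SNR/(1+SNR) = 0.5
  coh_mid <- replicate(200, {
    x <- rnorm(1280)
    y <- x + rnorm(1280)
    mean(msc(cross_spectra(x, y, iv(0, 1280), fs, 128L))$coh[10:50])
  })
  expect_lt(abs(mean(coh_mid) - 0.5), 0.03)
})

test_that("single sub-window coherence is flagged degenerate", {
  x <- rnorm(256)
  cs <- cross_spectra(x, x, iv(0, 256), fs, 256L)
  expect_identical(cs$n_sub, 1L)
  expect_warning(m <- msc(cs), "degenerate")
  expect_true(m$degenerate)
  expect_error(dwpli(cs), "single sub-window")
})

test_that("dwPLI evaluates the debiased formula exactly on fixed Im values", {
  fake_cs <- function(I) {
    structure(list(freqs = 0, Sxy = matrix(complex(imaginary = I), 1),
                   Sxx = matrix(1, 1, length(I)),
                   Syy = matrix(1, 1, length(I)),
                   n_sub = length(I), n_skipped = 0L,
                   window_len = 4L, nfft = 4L, fs = fs),
              class = "cross_spectra")
  }
  expect_equal(dwpli(fake_cs(c(2, 2, 2)))$dwpli, 1)          # (36-12)/(36-12)
  expect_equal(dwpli(fake_cs(c(1, -1)))$dwpli, -1)           # (0-2)/(4-2)
  d0 <- dwpli(fake_cs(c(0, 0, 0)))
  expect_equal(d0$dwpli, 0)
  expect_true(d0$zero_denom)
})

test_that("zero-lag (real-valued) coupling gives dwPLI 0 with a flag", {
  set.seed(9)
  x <- rnorm(2048)
  cs <- cross_spectra(x, 2 * x, iv(0, 2048), fs, 256L)
  d <- dwpli(cs)
  expect_true(all(d$dwpli == 0))
  expect_true(all(d$zero_denom))
})

test_that("msc and dwPLI match the brute-force oracle on random segment sets", {
  set.seed(21)
  for (rep in 1:12) {
    n <- 1200
    x <- rnorm(n); y <- rnorm(n)
    n_seg <- sample(2:4, 1)
    starts <- sort(sample(0:(n - 200), n_seg))
    segs <- iv(rbind(starts, starts + sample(80:180, n_seg, replace = TRUE)))
    wl <- sample(c(32L, 64L), 1)
    cs <- cross_spectra(x, y, segs, fs, wl)
    or <- naive_welch_coupling(x, y, segs, fs, wl)
    expect_equal(cs$n_sub, or$n_sub)
    expect_lt(max(abs(msc(cs)$coh - or$coh)), 1e-10)
    expect_lt(max(abs(dwpli(cs)$dwpli - or$dwpli)), 1e-10)
  }
})

test_that("coherence is invariant to per-channel scaling", {
  set.seed(22)
  x <- rnorm(2000); y <- rnorm(2000) + 0.3 * x
  segs <- iv(0, 1000, 1100, 1900)
  c1 <- msc(cross_spectra(x, y, segs, fs, 128L))$coh
  c2 <- msc(cross_spectra(-7.3 * x, 0.002 * y, segs, fs, 128L))$coh
  expect_lt(max(abs(c1 - c2)), 1e-12)
})

test_that("dwPLI is symmetric under lag sign flip", {
  set.seed(23)
  b <- as.numeric(stats::filter(rnorm(4096), rep(1, 8), sides = 2))
  b[is.na(b)] <- 0
  bq <- Im(burstcoupling:::analytic_signal(b))
  for (phi in c(pi / 4, pi / 2)) {
    yp <- cos(phi) * b + sin(phi) * bq
    ym <- cos(phi) * b - sin(phi) * bq
    segs <- iv(200, 2000, 2200, 3800)
    dp <- dwpli(cross_spectra(b, yp, segs, fs, 128L))$dwpli
    dm <- dwpli(cross_spectra(b, ym, segs, fs, 128L))$dwpli
    expect_lt(max(abs(dp - dm)), 1e-12)
  }
})

test_that("dwPLI is debiased: near-zero mean over independent pairs", {
  # debiasing removes the j = j' terms, so the null mean is ~0 when the
  # pooled sub-windows are independent (overlap 0); overlapping windows
  # share data and retain a small positive residual, which the surrogate
  # null absorbs because it is built from identically overlapping windows
  set.seed(24)
  vals <- replicate(1000, {
    x <- rnorm(1280); y <- rnorm(1280)
    cs <- cross_spectra(x, y, iv(0, 1280), fs, 128L, overlap = 0)
    mean(dwpli(cs)$dwpli[select_band_indices(128L, fs)])
  })
  expect_gte(mean(vals), -0.02)
  expect_lte(mean(vals), 0.02)
})

test_that("band indices follow the fs/window_len grid arithmetic", {
  idx <- select_band_indices(256L, fs)
  expect_equal((idx - 1) * fs / 256, c(15.625, 19.53125, 23.4375, 27.34375))
  # step 15.625 Hz leaves a single bin (15.625) inside [13, 30]
  idx64 <- select_band_indices(64L, fs)
  expect_equal((idx64 - 1) * fs / 64, 15.625)
  expect_error(select_band_indices(16L, fs), "window_len")
})

test_that("non-burst segment sampling respects the cap deterministically", {
  segs <- iv(rbind(seq(0, 2490, by = 10), seq(5, 2495, by = 10)))
  expect_identical(sample_nonburst_segments(segs[1:40, ], 100), segs[1:40, ])
  s1 <- sample_nonburst_segments(segs, 100, seed = 5)
  s2 <- sample_nonburst_segments(segs, 100, seed = 5)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 100L)
  expect_true(all(diff(s1[, "start"]) > 0))  # original order kept
  expect_false(identical(s1, sample_nonburst_segments(segs, 100, seed = 6)))
})

test_that("pair coupling recovers the burst/non-burst dissociation", {
  for (seed in 1:3) {
    r <- quick_pair(seed)
    expect_gt(r$pc$diff_coh, 0)
    expect_gt(r$pc$diff_dwpli, 0)
    expect_equal(r$pc$diff_coh,
                 r$pc$burst$coh_band - r$pc$nonburst$coh_band)
  }
  r <- quick_pair(4, mode = "none")
  es_empty <- make_epochs(iv(), r$epochs$nonbursts, n = r$epochs$n)
  expect_error(pair_coupling(r$stn, r$ctx, es_empty), "no bursts")
})
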