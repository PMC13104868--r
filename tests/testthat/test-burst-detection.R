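# Envelope computation and percentile-threshold burst detection.

fs <- 1000

test_that("envelope of a unit tone is ~1 and of silence is 0", {
  t <- (0:(5 * fs - 1)) / fs
  env <- compute_envelope(make_beta(sin(2 * pi * 20 * t)))
  core <- (fs + 1):(4 * fs)
  expect_lt(max(abs(env$a[core] - 1)), 0.02)
  expect_identical(compute_envelope(make_beta(numeric(1000)))$a, numeric(1000))
})

test_that("envelope tracks a slow amplitude modulation", {
  t <- (0:(10 * fs - 1)) / fs
  mod_true <- 1 + 0.5 * sin(2 * pi * 1 * t)
  env <- compute_envelope(make_beta(sin(2 * pi * 20 * t) * mod_true))
  core <- (fs + 1):(9 * fs)
  rms_err <- sqrt(mean((env$a[core] - mod_true[core])^2)) /
    sqrt(mean(mod_true[core]^2))
  expect_lt(rms_err, 0.05)
})

test_that("strict thresholds label a three-level envelope correctly", {
  # 5 low, 4 mid, 3 high samples: q75 = 3.75, q50 = 3 -> strict comparisons
  # label only the high run as burst and only the low run as non-burst
  a <- c(rep(1, 5), rep(3, 4), rep(6, 3))
  es <- detect_epochs(make_envelope(a, fs = 10), min_dur_ms = 100)
  expect_identical(es$bursts, iv(9, 12))
  expect_identical(es$nonbursts, iv(0, 5))
  expect_equal(unname(es$thresholds),
               unname(quantile(a, c(0.75, 0.5), type = 7)))
})

test_that("an envelope with percentile-straddling plateaus yields no epochs", {
  # 7 zeros / 5 nines: thresholds land exactly on the plateau values (9, 0),
  # so strict inequalities leave every sample unlabeled
  a <- c(0, 0, 0, 9, 9, 9, 9, 9, 0, 0, 0, 0)
  es <- detect_epochs(make_envelope(a, fs = 10), min_dur_ms = 100)
  expect_identical(nrow(es$bursts), 0L)
  expect_identical(nrow(es$nonbursts), 0L)
})

test_that("minimum-duration filter can remove every run", {
  a <- rep(c(0, 9), 50)
  es <- detect_epochs(make_envelope(a, fs = 1000), min_dur_ms = 100)
  expect_identical(nrow(es$bursts), 0L)
  expect_identical(nrow(es$nonbursts), 0L)
})

test_that("a strictly increasing envelope gives one top-quartile burst", {
  a <- 1:1000
  es <- detect_epochs(make_envelope(a, fs = 1000), min_dur_ms = 100)
  # oracle: q75 = 750.25 on the ramp, so samples 751..1000 (0-based 750..999)
  expect_identical(es$bursts, iv(750, 1000))
  expect_identical(es$nonbursts, iv(0, 500))
  expect_equal(nrow(es$bursts), 1L)
  expect_lt(abs(sum(interval_lengths(es$bursts)) - 250), 2)
})

test_that("detector equals the brute-force oracle on random envelopes", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(20:500, 1)
    a <- if (rep %% 3 == 0) round(runif(n), 1) else runif(n)  # some ties
    md <- sample(c(10, 50, 100), 1)
    es <- detect_epochs(make_envelope(a, fs = 100), min_dur_ms = md)
    or <- naive_detect(a, 100, min_dur_ms = md)
    expect_identical(unname(es$bursts), unname(or$bursts))
    expect_identical(unname(es$nonbursts), unname(or$nonbursts))
  }
})

test_that("fraction above the burst threshold matches the percentile", {
  set.seed(4)
  for (rep in 1:20) {
    a <- rexp(sample(500:5000, 1))
    es <- detect_epochs(make_envelope(a, fs = 1000), min_dur_ms = 1)
    frac <- mean(a > es$thresholds["burst"])
    expect_gte(frac, 0.20)
    # discreteness: at most one extra sample can sit above the threshold
    expect_lte(frac, 0.25 + 2 / length(a))
  }
})

test_that("a constant envelope yields empty epoch lists without error", {
  es <- detect_epochs(make_envelope(rep(2, 1000)))
  expect_identical(nrow(es$bursts), 0L)
  expect_identical(nrow(es$nonbursts), 0L)
  expect_equal(unname(es$thresholds["burst"]), unname(es$thresholds["nonburst"]))
})

test_that("detected bursts overlap ground truth at high gain and low noise", {
  # percentile thresholding pins detected occupancy at 25% of samples while
  # the Poisson process leaves true occupancy fluctuating around ~21%, and
  # smoothing/filtering smear every burst edge; 0.45 is the floor the
  # detector robustly clears under these favourable conditions
  jac <- vapply(1:3, function(seed) {
    r <- quick_pair(seed, duration_s = 30, noise_rms = 0.3)
    tr <- truth_to_trimmed(r$truth, 1000, r$epochs$n, 0, 2)
    m_true <- burstcoupling:::interval_mask(tr, r$epochs$n)
    m_det <- burstcoupling:::interval_mask(r$epochs$bursts, r$epochs$n)
    sum(m_true & m_det) / sum(m_true | m_det)
  }, 0)
  expect_gte(min(jac), 0.45)
  expect_gte(stats::median(jac), 0.5)
})

test_that("sparse pairs are flagged for exclusion", {
  es2 <- make_epochs(iv(0, 200, 300, 500), iv(600, 900))
  es1 <- make_epochs(iv(0, 200), iv(600, 900))
  es0 <- make_epochs(iv(), iv(600, 900), n = 900)
  out <- exclude_sparse_pairs(list(a = es2, b = es1, c = es0))
  expect_true(out$a$eligible_adjacent && out$a$eligible_any)
  expect_false(out$b$eligible_adjacent)
  expect_true(out$b$eligible_any)
  expect_false(out$c$eligible_any)
})
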