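# Synthetic LFP/ECoG generator: reproducibility, burst placement, coupling
# construction, fixture round trips.

test_that("same seed gives bit-identical output; different seeds differ", {
  cfg <- synth_config(duration_s = 5, seed = 42)
  a <- synth_pair(cfg)
  b <- synth_pair(cfg)
  expect_identical(a, b)
  c <- synth_pair(synth_config(duration_s = 5, seed = 43))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("true burst intervals are sorted, non-overlapping, in range", {
  for (seed in 1:20) {
    sp <- synth_pair(synth_config(duration_s = 20, seed = seed))
    b <- sp$truth$true_bursts
    if (nrow(b) < 2L) next
    expect_true(all(diff(b[, "start"]) > 0))
    # gaps of at least 1 sample between consecutive bursts
    expect_true(all(b[-1, "start"] - b[-nrow(b), "end"] >= 1))
    expect_true(all(b[, "start"] >= 0))
    expect_true(all(b[, "end"] <= sp$truth$n_samples))
  }
})

test_that("burst count is consistent with the Poisson onset process", {
  cfg <- synth_config(duration_s = 120, fs = 1000, burst_rate = 0.5, seed = 7)
  sp <- synth_pair(cfg)
  # oracle: direct count of the generator's interval list against the
  # Poisson(rate * duration) 99% interval (merging only reduces the count)
  lam <- 0.5 * 120
  expect_gte(nrow(sp$truth$true_bursts), qpois(0.005, lam))
  expect_lte(nrow(sp$truth$true_bursts), qpois(0.995, lam))
})

test_that("tonic full-strength quarter-cycle coupling shifts cortical beta by pi/2", {
  cfg <- synth_config(duration_s = 10, coupling_mode = "tonic",
                      coupling_strength = 1, phase_lag_rad = pi / 2,
                      burst_gain = 1, noise_rms = 0, seed = 5)
  sp <- synth_pair(cfg)
  stn <- sp$recording$samples[, 1]
  ctx <- sp$recording$samples[, 2]
  core <- 2001:8000  # away from edges
  ph <- function(z) Arg(burstcoupling:::analytic_signal(z))
  dphi <- (ph(stn) - ph(ctx))[core] %% (2 * pi)
  # circular mean of the phase difference
  mu <- Arg(mean(exp(1i * dphi))) %% (2 * pi)
  expect_lt(abs(mu - pi / 2), 0.05)
})

test_that("generator rejects bad parameters and warns on sub-100ms bursts", {
  expect_error(synth_config(duration_s = -1), "duration_s")
  expect_error(synth_config(duration_s = 10, fs = 50), "fs")
  expect_error(synth_config(duration_s = 10, coupling_strength = 1.5),
               "coupling_strength")
  expect_error(synth_config(duration_s = 10, burst_gain = 0.5), "burst_gain")
  expect_error(synth_config(duration_s = Inf), "finite")
  expect_warning(synth_pair(synth_config(duration_s = 5,
                                         burst_dur_mean_ms = 80, seed = 1)),
                 "100 ms")
})

test_that("tsv fixtures round-trip exactly, EDF within one quantization step", {
  sp <- synth_pair(synth_config(duration_s = 3, seed = 9))
  td <- withr::local_tempdir()
  tsv <- file.path(td, "pair.tsv")
  write_recording(sp$recording, tsv, "tsv")
  back <- read_recording(tsv)
  expect_identical(back$samples, sp$recording$samples)
  expect_identical(back$fs, sp$recording$fs)
  expect_identical(unname(back$roles), unname(sp$recording$roles))

  edf <- file.path(td, "pair.edf")
  write_recording(sp$recording, edf, "edf")
  backe <- read_recording(edf)
  expect_equal(backe$labels, sp$recording$labels)
  expect_equal(backe$fs, sp$recording$fs)
  expect_equal(nrow(backe$samples), nrow(sp$recording$samples))
  for (j in 1:2) {
    rng <- diff(range(sp$recording$samples[, j]))
    qstep <- rng / (32767 - (-32768))
    expect_lte(max(abs(backe$samples[, j] - sp$recording$samples[, j])), qstep)
  }
})

test_that("empty recordings are refused by the writers", {
  expect_error(as_recording(matrix(numeric(0), 0, 2), 1000,
                            c("STN_1", "ECOG_1"), c("stn", "cortical")),
               "no samples")
  expect_error(write_recording(list(), tempfile()))
})

test_that("unsupported fixture format is an error", {
  sp <- synth_pair(synth_config(duration_s = 2, seed = 1))
  expect_error(write_recording(sp$recording, tempfile(), "mat"))
})
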