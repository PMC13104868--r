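# Burst-adjacent triplets and peri-burst sliding-window traces.

test_that("triplets carve matched-length pre/post windows from neighbours", {
  es <- make_epochs(iv(100, 150, 400, 420), iv(0, 90, 160, 300), n = 500)
  tr <- build_adjacent_triplets(es)
  expect_identical(tr$pre_start[1], 40L)
  expect_identical(tr$pre_end[1], 90L)
  expect_identical(tr$post_start[1], 160L)
  expect_identical(tr$post_end[1], 210L)
  expect_true(tr$valid[1])
  # second burst has no later non-burst interval -> invalid
  expect_false(tr$valid[2])
})

test_that("a too-short nearest neighbour invalidates the triplet", {
  es <- make_epochs(iv(100, 180), iv(60, 90, 200, 400), n = 500)
  es$bursts <- rbind(es$bursts, iv(450, 460))  # keep >= 2 bursts
  tr <- build_adjacent_triplets(es)
  expect_false(tr$valid[1])  # nearest earlier interval is 30 < 80 samples
  expect_error(build_adjacent_triplets(make_epochs(iv(0, 10), iv(20, 400),
                                                   n = 400)),
               "at least 2 bursts")
})

test_that("triplet invariants hold on synthetic epoch sets", {
  for (seed in 1:5) {
    r <- quick_pair(seed, duration_s = 25)
    tr <- build_adjacent_triplets(r$epochs)
    tv <- tr[tr$valid, ]
    nb_mask <- burstcoupling:::interval_mask(r$epochs$nonbursts, r$epochs$n)
    for (i in seq_len(nrow(tv))) {
      L <- tv$burst_end[i] - tv$burst_start[i]
      expect_identical(tv$pre_end[i] - tv$pre_start[i], L)
      expect_identical(tv$post_end[i] - tv$post_start[i], L)
      expect_lte(tv$pre_end[i], tv$burst_start[i])
      expect_gte(tv$post_start[i], tv$burst_end[i])
      expect_true(all(nb_mask[(tv$pre_start[i] + 1):tv$pre_end[i]]))
      expect_true(all(nb_mask[(tv$post_start[i] + 1):tv$post_end[i]]))
    }
  }
})

test_that("burst coupling exceeds matched pre and post windows", {
  for (seed in 1:4) {
    r <- quick_pair(seed)
    ac <- adjacent_coupling(r$stn, r$ctx,
                            build_adjacent_triplets(r$epochs))
    expect_gt(ac$diff_coh_pre, 0)
    expect_gt(ac$diff_coh_post, 0)
    expect_gt(ac$diff_dwpli_pre, 0)
    expect_gt(ac$diff_dwpli_post, 0)
  }
})

test_that("the peri-burst grid has (2 span / step) + 1 offsets", {
  r <- quick_pair(2)
  tr <- peri_burst_trace(r$stn, r$ctx, r$epochs)
  expect_length(tr$offsets_ms, 21L)
  expect_equal(tr$offsets_ms, seq(-50, 50, by = 5))
})

test_that("burst-locked coupling rises after onset but not 50 ms before", {
  # 15 ms windows make single-pair traces noisy; as in the group analysis,
  # the trace is interpreted averaged across contact pairs
  trs <- lapply(1:3, function(seed) {
    r <- quick_pair(seed)
    peri_burst_trace(r$stn, r$ctx, r$epochs, seed = derive_seed(seed, "pb"))
  })
  trace <- rowMeans(vapply(trs, `[[`, numeric(21), "coh_trace"))
  base <- mean(vapply(trs, `[[`, 0, "baseline_coh"))
  base_sd <- mean(vapply(trs, `[[`, 0, "baseline_coh_sd"))
  offsets <- trs[[1]]$offsets_ms
  inside <- offsets >= 20
  expect_gt(mean(trace[inside]), base + 2 * base_sd)
  expect_lte(trace[1], base + 2 * base_sd)  # -50 ms: no elevation
})

test_that("without coupling the trace stays inside the baseline band", {
  r <- quick_pair(11, mode = "none")
  tr <- peri_burst_trace(r$stn, r$ctx, r$epochs, seed = 1)
  for (m in c("coh", "dwpli")) {
    trace <- if (m == "coh") tr$coh_trace else tr$dwpli_trace
    mu <- if (m == "coh") tr$baseline_coh else tr$baseline_dwpli
    sdv <- if (m == "coh") tr$baseline_coh_sd else tr$baseline_dwpli_sd
    # allow at most the expected handful of 2 SD excursions over 21 windows
    expect_lte(sum(trace > mu + 2 * sdv | trace < mu - 2 * sdv), 3L)
  }
})

test_that("matched non-burst windows avoid the exclusion zone", {
  es <- make_epochs(iv(1000, 1200), iv(0, 1000, 1200, 3000), n = 3000)
  w <- matched_nonburst_windows(es, 50, window_ms = 15, exclusion_ms = 50,
                                seed = 4)
  expect_identical(nrow(w), 50L)
  # oracle: eligible starts exclude [950 - 15, 1250)
  expect_true(all(w[, "end"] <= 950 | w[, "start"] >= 1250))
  expect_identical(w, matched_nonburst_windows(es, 50, 15, 50, seed = 4))
  # bursts + exclusion covering everything -> error
  es2 <- make_epochs(iv(0, 2980), iv(2980, 3000), n = 3000)
  expect_error(matched_nonburst_windows(es2, 5, 15, 50), "eligible")
})
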