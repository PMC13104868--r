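# End-to-end orchestration: preprocessing -> burst detection -> coupling ->
# surrogate tests -> burst-adjacent and peri-burst analyses -> statistics,
# with every stage output written to a run directory as TSV.

#' Pipeline run configuration
#'
#' Hosts every analysis constant in one validated object. Either `input`
#' (path to a TSV/EDF recording) or `synth` (a [synth_config()]) must be
#' given.
#'
#' @param input optional recording path.
#' @param synth optional `synth_config` used to generate the recording.
#' @param band beta band in Hz.
#' @param burst_pct,nonburst_pct envelope percentiles for epoch detection.
#' @param min_dur_ms minimum epoch duration (ms).
#' @param smooth_ms envelope smoothing window (ms).
#' @param head_discard_s,edge_trim_s trim settings (see [trim_edges()]).
#'   When the recording comes from the synthetic generator the head discard
#'   defaults to 0 s: there is no start-up transient to drop.
#' @param window_len_max,overlap Welch settings.
#' @param nonburst_cap cap on sampled non-burst segments.
#' @param n_surrogates,shift_range_s surrogate settings.
#' @param peri_window_ms,peri_step_ms,peri_span_ms peri-burst settings.
#' @param alpha significance level for contact summaries.
#' @param dump_nulls write full surrogate null vectors to `nulls.tsv`.
#' @param seed master seed for every stochastic step.
#' @return a `run_config`.
#' @export
run_config <- function(input = NULL, synth = NULL, band = c(13, 30),
                       burst_pct = 75, nonburst_pct = 50, min_dur_ms = 100,
                       smooth_ms = 50,
                       head_discard_s = if (is.null(synth)) 60 else 0,
                       edge_trim_s = 2, window_len_max = 256L, overlap = 0.5,
                       nonburst_cap = 100L, n_surrogates = 200L,
                       shift_range_s = c(0.5, 5), peri_window_ms = 15,
                       peri_step_ms = 5, peri_span_ms = 50, alpha = 0.05,
                       dump_nulls = FALSE, seed = 1L) {
  if (is.null(input) && is.null(synth))
    stop("run_config needs either 'input' or 'synth'")
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  cfg <- as.list(environment())
  stopifnot(band[1] > 0, band[1] < band[2], burst_pct > nonburst_pct,
            min_dur_ms > 0, alpha > 0, alpha < 1,
            shift_range_s[1] > 0, shift_range_s[1] < shift_range_s[2])
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are errors, protecting against silently ignored typos in
#' threshold names.
#'
#' @param path YAML file whose keys match the [run_config()] arguments
#'   (`synth` as a nested block of [synth_config()] arguments).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$synth)) {
    sk <- setdiff(names(y$synth), names(formals(synth_config)))
    if (length(sk)) stop("unknown synth keys: ", paste(sk, collapse = ", "))
    y$synth <- do.call(synth_config, y$synth)
  }
  do.call(run_config, y)
}

run_manifest <- function() {
  c("config.yaml", "log.txt", "pairs.tsv", "contacts.tsv", "triplets.tsv",
    "trace.tsv", "report.md")
}

#' Run the full burst-coupling pipeline
#'
#' Executes preprocessing, burst detection per STN channel, burst/non-burst
#' coupling, surrogate testing (both conditions, both metrics), the
#' burst-adjacent triplet analysis and the peri-burst sliding-window analysis
#' for every STN x cortical contact pair, then the cohort-level statistics.
#' All stage outputs, a config snapshot, a log with per-pair exclusion
#' reasons and a Markdown report are written to `out_dir`. Deterministic
#' under a fixed config seed.
#'
#' @param cfg a `run_config`.
#' @param out_dir run directory (created if needed).
#' @return a `coupling_run`: `dir`, `pairs` (data.frame), `contacts`,
#'   `stats`, `adjacent`, `traces`, `epochs`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logf <- function(...) writeLines(sprintf(...), log_con)
  t0 <- proc.time()["elapsed"]
  stage <- function(name) logf("[%7.2fs] %s", proc.time()["elapsed"] - t0, name)

  snap <- cfg
  snap$synth <- if (!is.null(cfg$synth)) unclass(cfg$synth)
  yaml::write_yaml(lapply(unclass(snap), function(v) if (is.null(v)) NULL else v),
                   file.path(out_dir, "config.yaml"))

  stage("load recording")
  rec <- if (!is.null(cfg$input)) read_recording(cfg$input)
         else synth_pair(cfg$synth)$recording
  logf("  %d samples x %d channels at %g Hz", nrow(rec$samples),
       ncol(rec$samples), rec$fs)

  stage("preprocess")
  bs <- preprocess_recording(rec, band = cfg$band,
                             head_discard_s = cfg$head_discard_s,
                             edge_trim_s = cfg$edge_trim_s)
  stn_labels <- names(which(bs$roles == "stn"))
  ctx_labels <- names(which(bs$roles == "cortical"))
  if (!length(stn_labels) || !length(ctx_labels))
    stop("pipeline stage 'preprocess': need at least one STN and one cortical channel")

  stage("burst detection")
  epochs <- lapply(stn_labels, function(l) {
    es <- detect_epochs(compute_envelope(bs$signals[[l]], cfg$smooth_ms),
                        cfg$burst_pct, cfg$nonburst_pct, cfg$min_dur_ms)
    write_epochs(es, file.path(out_dir, sprintf("epochs_%s.tsv", l)))
    es
  })
  names(epochs) <- stn_labels
  epochs <- exclude_sparse_pairs(epochs)
  for (l in stn_labels)
    logf("  %s: %d bursts, %d non-burst epochs%s", l, nrow(epochs[[l]]$bursts),
         nrow(epochs[[l]]$nonbursts),
         if (!epochs[[l]]$eligible_adjacent)
           " [excluded from burst-adjacent analysis: < 2 bursts]" else "")

  stage("coupling + surrogates")
  pair_rows <- list(); adj_rows <- list(); trace_rows <- list()
  null_rows <- list()
  for (sl in stn_labels) {
    es <- epochs[[sl]]
    if (!es$eligible_any) {
      logf("  %s: excluded from all burst analyses (0 bursts)", sl)
      next
    }
    triplets <- if (es$eligible_adjacent) build_adjacent_triplets(es)
    for (cl in ctx_labels) {
      stn <- bs$signals[[sl]]; ctx <- bs$signals[[cl]]
      pc <- pair_coupling(stn, ctx, es, band = cfg$band,
                          window_len_max = cfg$window_len_max,
                          overlap = cfg$overlap,
                          nonburst_cap = cfg$nonburst_cap,
                          seed = derive_seed(cfg$seed, sl, cl, "nbsample"))
      sur <- lapply(c(burst = "burst", nonburst = "nonburst"), function(cond)
        surrogate_test(pc, stn, ctx, cond, cfg$n_surrogates,
                       cfg$shift_range_s, cfg$seed))
      row <- pair_coupling_table(list(pc))
      row$p_coh_burst <- sur$burst$coh$p_emp
      row$p_dwpli_burst <- sur$burst$dwpli$p_emp
      row$p_coh_nonburst <- sur$nonburst$coh$p_emp
      row$p_dwpli_nonburst <- sur$nonburst$dwpli$p_emp
      row$surr_mean_coh_nonburst <- mean(sur$nonburst$coh$null_values)
      row$surr_mean_dwpli_nonburst <- mean(sur$nonburst$dwpli$null_values)
      pair_rows[[paste(sl, cl)]] <- row
      if (isTRUE(cfg$dump_nulls)) {
        null_rows[[paste(sl, cl)]] <- data.frame(
          stn_label = sl, ctx_label = cl,
          condition = rep(c("burst", "nonburst"), each = cfg$n_surrogates),
          surrogate = rep(seq_len(cfg$n_surrogates), 2L),
          coh = c(sur$burst$coh$null_values, sur$nonburst$coh$null_values),
          dwpli = c(sur$burst$dwpli$null_values, sur$nonburst$dwpli$null_values))
      }
      if (!is.null(triplets)) {
        ac <- tryCatch(
          adjacent_coupling(stn, ctx, triplets, band = cfg$band,
                            window_len_max = cfg$window_len_max,
                            overlap = cfg$overlap),
          error = function(e) { logf("  %s~%s: adjacent skipped (%s)",
                                     sl, cl, conditionMessage(e)); NULL })
        if (!is.null(ac))
          adj_rows[[paste(sl, cl)]] <- data.frame(
            stn_label = sl, ctx_label = cl,
            coh_burst = ac$coh["burst"], coh_pre = ac$coh["pre"],
            coh_post = ac$coh["post"],
            dwpli_burst = ac$dwpli["burst"], dwpli_pre = ac$dwpli["pre"],
            dwpli_post = ac$dwpli["post"],
            n_valid = ac$n_valid, n_invalid = ac$n_invalid)
      }
      tr <- tryCatch(
        peri_burst_trace(stn, ctx, es, cfg$peri_window_ms, cfg$peri_step_ms,
                         cfg$peri_span_ms, band = cfg$band,
                         seed = derive_seed(cfg$seed, sl, cl, "peribase")),
        error = function(e) { logf("  %s~%s: peri-burst skipped (%s)",
                                   sl, cl, conditionMessage(e)); NULL })
      if (!is.null(tr))
        trace_rows[[paste(sl, cl)]] <- data.frame(
          stn_label = sl, ctx_label = cl, offset_ms = tr$offsets_ms,
          coh = tr$coh_trace, dwpli = tr$dwpli_trace,
          baseline_coh = tr$baseline_coh, baseline_coh_sd = tr$baseline_coh_sd,
          baseline_dwpli = tr$baseline_dwpli,
          baseline_dwpli_sd = tr$baseline_dwpli_sd)
    }
  }
  if (!length(pair_rows))
    stop("pipeline stage 'coupling': no analyzable STN-cortical pairs")
  pairs <- do.call(rbind, pair_rows); rownames(pairs) <- NULL
  adjacent <- if (length(adj_rows)) {
    a <- do.call(rbind, adj_rows); rownames(a) <- NULL; a
  } else data.frame()
  traces <- if (length(trace_rows)) {
    a <- do.call(rbind, trace_rows); rownames(a) <- NULL; a
  } else data.frame()

  stage("statistics")
  contacts <- contact_summary(pairs, cfg$alpha)
  wtsv <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wtsv(pairs, "pairs.tsv")
  wtsv(contacts, "contacts.tsv")
  wtsv(adjacent, "triplets.tsv")
  wtsv(traces, "trace.tsv")
  if (length(null_rows)) wtsv(do.call(rbind, null_rows), "nulls.tsv")

  stage("report")
  report(out_dir)
  stage("done")

  structure(list(dir = out_dir, pairs = pairs, contacts = contacts,
                 adjacent = adjacent, traces = traces, epochs = epochs,
                 config = cfg),
            class = "coupling_run")
}

#' @export
print.coupling_run <- function(x, ...) {
  cat(sprintf("<coupling_run> %s: %d pairs, %d cortical contacts\n",
              x$dir, nrow(x$pairs), nrow(x$contacts)))
  if (nrow(x$pairs) >= 2L) {
    pc <- paired_compare(x$pairs$coh_burst, x$pairs$coh_nonburst)
    pd <- paired_compare(x$pairs$dwpli_burst, x$pairs$dwpli_nonburst)
    cat(sprintf("  burst - non-burst coherence: mean %+.4f (dz %.2f)\n",
                pc$mean_diff, pc$cohens_dz))
    cat(sprintf("  burst - non-burst dwPLI:     mean %+.4f (dz %.2f)\n",
                pd$mean_diff, pd$cohens_dz))
  }
  invisible(x)
}

#' Validate a run directory against the pipeline manifest
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return TRUE invisibly; errors name every missing output.
#' @export
validate_run <- function(run_dir) {
  want <- run_manifest()
  have <- list.files(run_dir)
  miss <- setdiff(want, have)
  if (!any(grepl("^epochs_.*\\.tsv$", have)))
    miss <- c(miss, "epochs_<label>.tsv")
  if (length(miss))
    stop("run directory ", run_dir, " is missing: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Generate, preprocess and analyze one synthetic pair
#'
#' Convenience wrapper used heavily in validation: generates a pair from
#' `scfg`, runs the filter/trim chain (head discard 0 s by default: the
#' generator has no start-up transient), detects epochs and computes
#' burst/non-burst coupling.
#'
#' @param scfg a [synth_config()].
#' @param head_discard_s,edge_trim_s trim settings.
#' @param ... further arguments to [pair_coupling()].
#' @return list with `stn`, `ctx` (`beta_signal`s), `epochs`, `pc`
#'   (`pair_coupling`), `truth`.
#' @export
analyze_synth_pair <- function(scfg, head_discard_s = 0, edge_trim_s = 2, ...) {
  sp <- synth_pair(scfg)
  bs <- preprocess_recording(sp$recording, head_discard_s = head_discard_s,
                             edge_trim_s = edge_trim_s)
  stn <- bs$signals[["STN_1"]]
  ctx <- bs$signals[["ECOG_1"]]
  epochs <- detect_epochs(compute_envelope(stn))
  pc <- pair_coupling(stn, ctx, epochs, seed = derive_seed(scfg$seed, "nb"), ...)
  list(stn = stn, ctx = ctx, epochs = epochs, pc = pc, truth = sp$truth)
}
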