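# Paired statistics, effect sizes, correlations and contact-level summaries.

#' Paired comparison of two coupling conditions
#'
#' Two-sided Wilcoxon signed-rank test (exact for <= 25 non-zero differences
#' without ties, otherwise normal approximation with tie correction;
#' zero differences are dropped), two-sided paired t-test, and the paired
#' effect size `dz = mean(a - b) / sd(a - b)` (sample SD, n - 1).
#'
#' @param a,b numeric vectors of per-pair values, equal length >= 2.
#' @return a `paired_result`: `n`, `wilcoxon_p`, `ttest_p`, `cohens_dz`,
#'   `mean_diff`, `degenerate` (TRUE when all differences are zero, leaving
#'   the tests undefined).
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  sdd <- stats::sd(d)
  degenerate <- all(d == 0)
  if (degenerate) {
    res <- list(wilcoxon_p = NA_real_, ttest_p = NA_real_,
                cohens_dz = NA_real_)
  } else {
    n_nz <- sum(d != 0)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = n_nz <= 25L,
                         correct = TRUE))
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(wilcoxon_p = wt$p.value, ttest_p = tt$p.value,
                cohens_dz = if (sdd > 0) mean(d) / sdd else NA_real_)
  }
  structure(c(list(n = length(a), mean_diff = mean(d), sd_diff = sdd,
                   degenerate = degenerate), res),
            class = "paired_result")
}

#' @export
print.paired_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<paired_result> all differences zero (tests undefined), n =", x$n, "\n")
  } else {
    cat(sprintf(
      "<paired_result> n = %d, mean diff = %+.4g, dz = %.3f, Wilcoxon p = %.3g, t p = %.3g\n",
      x$n, x$mean_diff, x$cohens_dz, x$wilcoxon_p, x$ttest_p))
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value via the t approximation.
#' Constant input leaves the coefficient undefined and is flagged.
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @return list with `rho`, `p`, `n`, `degenerate`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Per-cortical-contact summary of surrogate significance and coupling
#'
#' For every cortical contact: the fraction of its STN pairs whose burst /
#' non-burst coupling exceeds surrogate expectations (`p < alpha`,
#' uncorrected) per metric, the condition means, and the fraction of pairs
#' significant in neither condition ("none").
#'
#' @param pair_table data.frame with columns `ctx_label`, `coh_burst`,
#'   `coh_nonburst`, `dwpli_burst`, `dwpli_nonburst`, `p_coh_burst`,
#'   `p_coh_nonburst`, `p_dwpli_burst`, `p_dwpli_nonburst`.
#' @param alpha significance level (default 0.05).
#' @return data.frame, one row per cortical contact.
#' @export
contact_summary <- function(pair_table, alpha = 0.05) {
  need <- c("ctx_label", "coh_burst", "coh_nonburst", "dwpli_burst",
            "dwpli_nonburst", "p_coh_burst", "p_coh_nonburst",
            "p_dwpli_burst", "p_dwpli_nonburst")
  miss <- setdiff(need, names(pair_table))
  if (length(miss)) stop("pair_table lacks columns: ", paste(miss, collapse = ", "))
  rows <- lapply(split(pair_table, pair_table$ctx_label), function(g) {
    data.frame(
      cortical_contact = g$ctx_label[1L],
      n_pairs = nrow(g),
      frac_burst_exceeding_coh = mean(g$p_coh_burst < alpha),
      frac_nonburst_exceeding_coh = mean(g$p_coh_nonburst < alpha),
      frac_burst_exceeding_dwpli = mean(g$p_dwpli_burst < alpha),
      frac_nonburst_exceeding_dwpli = mean(g$p_dwpli_nonburst < alpha),
      frac_none_coh = mean(g$p_coh_burst >= alpha & g$p_coh_nonburst >= alpha),
      frac_none_dwpli = mean(g$p_dwpli_burst >= alpha & g$p_dwpli_nonburst >= alpha),
      mean_coh_burst = mean(g$coh_burst),
      mean_coh_nonburst = mean(g$coh_nonburst),
      mean_dwpli_burst = mean(g$dwpli_burst),
      mean_dwpli_nonburst = mean(g$dwpli_nonburst),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
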