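# Shared helpers: seeded evaluation, deterministic sub-stream derivation,
# and half-open interval arithmetic used throughout the pipeline.
# Intervals are integer matrices with columns (start, end), 0-based,
# half-open [start, end), in samples of the trimmed signal.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so seeded helpers never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a deterministic RNG sub-stream seed
#'
#' Hashes a master seed together with string keys (pair id, condition, ...)
#' into a 31-bit integer, so every surrogate test and sampling step gets its
#' own reproducible stream independent of execution order.
#'
#' @param seed master integer seed.
#' @param ... further keys (coerced to character).
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

# -- intervals ---------------------------------------------------------------

new_intervals <- function(start = integer(0), end = integer(0)) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (nrow(m) && any(m[, "end"] <= m[, "start"]))
    stop("intervals must have end > start")
  m
}

interval_lengths <- function(iv) {
  if (!nrow(iv)) return(integer(0))
  iv[, "end"] - iv[, "start"]
}

# merge sorted-or-unsorted intervals; any touching/overlapping pair is fused,
# and a gap of 0 samples counts as touching (keeps inter-interval gaps >= 1)
merge_intervals <- function(iv) {
  if (nrow(iv) < 2L) return(iv)
  iv <- iv[order(iv[, "start"]), , drop = FALSE]
  out <- list(iv[1L, ])
  for (i in 2L:nrow(iv)) {
    last <- out[[length(out)]]
    cur <- iv[i, ]
    if (cur["start"] <= last["end"]) {
      last["end"] <- max(last["end"], cur["end"])
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- cur
    }
  }
  do.call(rbind, out)
}

# maximal runs of TRUE in a logical vector, as 0-based half-open intervals,
# keeping only runs of at least min_len samples
logical_runs <- function(flag, min_len = 1L) {
  if (!length(flag)) return(new_intervals())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  new_intervals(starts[keep], ends[keep])
}

# TRUE for samples covered by any interval, over a signal of length n
interval_mask <- function(iv, n) {
  mask <- logical(n)
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      lo <- max(iv[i, "start"], 0L) + 1L
      hi <- min(iv[i, "end"], n)
      if (hi >= lo) mask[lo:hi] <- TRUE
    }
  }
  mask
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stop(sprintf("'%s' must be finite", name))
  invisible(x)
}
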