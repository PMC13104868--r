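# Recording container plus TSV (+ YAML sidecar) readers and writers.
# EDF support lives in edf.R.

#' Construct a multichannel recording
#'
#' @param samples numeric matrix, samples x channels (physical units, uV).
#' @param fs sampling rate in Hz.
#' @param labels unique channel names.
#' @param roles per-channel role, `"stn"` or `"cortical"`.
#' @return a validated `recording`.
#' @export
as_recording <- function(samples, fs, labels, roles) {
  samples <- as.matrix(samples)
  if (!nrow(samples)) stop("recording has no samples")
  if (fs <= 0) stop("fs must be positive")
  if (length(labels) != ncol(samples)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  roles <- match.arg(roles, c("stn", "cortical"), several.ok = TRUE)
  if (length(roles) != ncol(samples)) stop("one role per channel required")
  colnames(samples) <- labels
  structure(list(samples = unname(samples), fs = fs, labels = labels,
                 roles = stats::setNames(roles, labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples x %d channels at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("  channels:", paste(sprintf("%s[%s]", x$labels, x$roles),
                           collapse = ", "), "\n")
  invisible(x)
}

# infer roles from conventional label prefixes (STN_*, ECOG_*)
roles_from_labels <- function(labels) {
  r <- ifelse(grepl("^STN", labels, ignore.case = TRUE), "stn",
              ifelse(grepl("^ECOG|^ECoG", labels, ignore.case = TRUE),
                     "cortical", NA))
  if (anyNA(r))
    stop("cannot infer channel roles from labels: ",
         paste(labels[is.na(r)], collapse = ", "),
         " (provide a sidecar with roles)")
  r
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a recording to disk
#'
#' `tsv`: tab-separated sample x channel matrix with a header row of labels,
#' plus a YAML sidecar `<path>.yaml` holding `fs` and per-channel roles
#' (lossless round trip). `edf`: 16-bit EDF (see [write_edf()]).
#'
#' @param rec a `recording`.
#' @param path output file path.
#' @param format `"tsv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("tsv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "recording"))
  if (!nrow(rec$samples)) stop("refusing to write an empty recording")
  if (format == "tsv") {
    # %.17g guarantees doubles survive the text round trip bit-exactly
    m <- matrix(sprintf("%.17g", rec$samples), nrow(rec$samples))
    colnames(m) <- rec$labels
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    yaml::write_yaml(list(fs = rec$fs, roles = as.list(rec$roles)),
                     sidecar_path(path))
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Formats: `tsv` (matrix + YAML sidecar) or `edf`. When the sidecar or
#' header lacks a sampling rate it defaults to 1000 Hz with a warning; roles
#' come from the sidecar when present, otherwise from label prefixes.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"edf"`; guessed from the extension when `NULL`.
#' @return a `recording`.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  format <- match.arg(format, c("tsv", "edf"))
  if (format == "edf") return(read_edf(path))
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  labels <- colnames(m)
  side <- sidecar_path(path)
  fs <- NULL; roles <- NULL
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    fs <- meta$fs
    if (!is.null(meta$roles)) {
      roles <- unlist(meta$roles)[labels]
      if (anyNA(roles))
        stop("sidecar roles do not cover all channels in ", path)
    }
  }
  if (is.null(fs)) {
    warning("sampling rate unavailable for ", path, "; defaulting to 1000 Hz")
    fs <- 1000
  }
  if (is.null(roles)) roles <- roles_from_labels(labels)
  as_recording(m, fs, labels, unname(roles))
}

#' Write an epoch set as a BED-like TSV
#'
#' Columns `source_label`, `start_sample`, `end_sample`, `label`
#' (burst/nonburst); thresholds recorded in `#` header comments.
#'
#' @param epochs an `epoch_set`.
#' @param path output path.
#' @export
write_epochs <- function(epochs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# burst_threshold=%.10g nonburst_threshold=%.10g min_dur_samples=%d",
                     epochs$thresholds["burst"], epochs$thresholds["nonburst"],
                     epochs$min_dur), con)
  df <- rbind(
    if (nrow(epochs$bursts))
      data.frame(source_label = epochs$source_label %||% "STN",
                 start_sample = epochs$bursts[, "start"],
                 end_sample = epochs$bursts[, "end"], label = "burst"),
    if (nrow(epochs$nonbursts))
      data.frame(source_label = epochs$source_label %||% "STN",
                 start_sample = epochs$nonbursts[, "start"],
                 end_sample = epochs$nonbursts[, "end"], label = "nonburst"))
  utils::write.table(df[order(df$start_sample), ], con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
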