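# Minimal EDF (European Data Format) writer/reader: 16-bit integer samples,
# 1-second data records, ASCII headers. Covers exactly what the pipeline
# needs (continuous multichannel recordings with labels and a sampling
# rate); no annotations, no discontinuous EDF+.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording as EDF
#'
#' Samples are scaled per channel to the full 16-bit digital range, so the
#' round-trip error is at most one quantization step of the stored physical
#' range. Uses 1 s data records; the final record is zero-padded and the true
#' sample count is stored in the reserved header field so [read_edf()] can
#' trim it back.
#'
#' @param rec a `recording`; `fs` must be a whole number.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (!nrow(rec$samples)) stop("refusing to write an empty recording")
  if (rec$fs != round(rec$fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(rec$fs)
  n <- nrow(rec$samples); p <- ncol(rec$samples)
  n_rec <- ceiling(n / fs)
  pmin_ <- apply(rec$samples, 2, min)
  pmax_ <- apply(rec$samples, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2026 synthetic", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + p), 8),
    edf_pad(sprintf("n_samples=%d", n), 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(p, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$labels, 16)
  field(rep("", p), 80)                      # transducer
  field(rep("uV", p), 8)                     # physical dimension
  field(sprintf("%.8g", pmin_), 8)
  field(sprintf("%.8g", pmax_), 8)
  field(rep(dmin, p), 8)
  field(rep(dmax, p), 8)
  field(rep("", p), 80)                      # prefiltering
  field(rep(fs, p), 8)                       # samples per record
  field(rep("", p), 32)                      # reserved
  dig <- matrix(0L, n_rec * fs, p)
  for (j in seq_len(p)) {
    d <- round((rec$samples[, j] - pmin_[j]) / (pmax_[j] - pmin_[j]) *
                 (dmax - dmin) + dmin)
    dig[seq_len(n), j] <- as.integer(d)
    dig[dig[, j] > dmax, j] <- dmax
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(p))
      writeBin(dig[rows, j], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file.
#' @return a `recording` (roles inferred from channel label prefixes).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                     # version
  rd(80); rd(80); rd(8); rd(8)              # ids, date, time
  rd(8)                                     # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  p <- as.integer(rd(4))
  if (is.na(p) || p < 1L) stop("malformed EDF header: bad signal count")
  rdn <- function(width) vapply(seq_len(p), function(i) rd(width), "")
  labels <- rdn(16)
  rdn(80)
  rdn(8)
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (any(is.na(c(pmin_, pmax_, dmin, dmax, spr))))
    stop("malformed EDF header: non-numeric signal fields")
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single sampling rate across channels")
  fs <- spr[1L] / rec_dur
  samples <- matrix(0, n_rec * spr[1L], p)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(p)) {
      d <- readBin(con, "integer", n = spr[j], size = 2L, endian = "little")
      samples[((r - 1L) * spr[j] + 1L):(r * spr[j]), j] <-
        (d - dmin[j]) / (dmax[j] - dmin[j]) * (pmax_[j] - pmin_[j]) + pmin_[j]
    }
  }
  m <- regmatches(reserved, regexec("n_samples=([0-9]+)", reserved))[[1L]]
  if (length(m) == 2L) {
    n_true <- as.integer(m[2L])
    if (n_true <= nrow(samples)) samples <- samples[seq_len(n_true), , drop = FALSE]
  }
  as_recording(samples, fs, labels, roles_from_labels(labels))
}
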