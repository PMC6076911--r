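#' EEG recording container
#'
#' A multichannel recording: a channels-by-samples numeric matrix, its
#' sampling rate, per-channel labels, and a free-text description of the
#' current reference.
#'
#' @param data numeric matrix, channels in rows, samples in columns (µV)
#' @param rate sampling rate (Hz), positive
#' @param labels per-channel names; default `"1".."n"` (ordinal electrode
#'   numbers)
#' @param reference description of the reference used, default `"online"`
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, rate, labels = NULL, reference = "online") {
  data <- as.matrix(data)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("eeg_recording: rate must be a positive number", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("eeg_recording: one label per channel required", call. = FALSE)
  if (!all(is.finite(data)))
    stop("eeg_recording: non-finite sample values", call. = FALSE)
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              x$reference))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

check_finite <- function(rec, stage) {
  if (!all(is.finite(rec$data)))
    stop(stage, ": produced non-finite sample values", call. = FALSE)
  rec
}

#' Read / write recordings as headered delimited text
#'
#' Plain-text format: comment header lines `# rate: <Hz>` and
#' `# reference: <text>`, then a tab-separated table with one column per
#' channel (channel labels as header) and one row per sample.
#'
#' @param rec an [eeg_recording()]
#' @param path file path
#' @return `read_recording_txt` returns an [eeg_recording()]
#' @export
write_recording_txt <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate: %.10g", rec$rate),
               paste0("# reference: ", rec$reference)), con)
  utils::write.table(t(rec$data), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_recording_txt
#' @export
read_recording_txt <- function(path) {
  hdr <- readLines(path, n = 2L)
  rate <- as.numeric(sub("^# rate:\\s*", "", hdr[1]))
  if (!is.finite(rate))
    stop("read_recording_txt: missing '# rate:' header", call. = FALSE)
  reference <- sub("^# reference:\\s*", "", hdr[2])
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                           check.names = FALSE)
  eeg_recording(t(as.matrix(tab)), rate = rate, labels = colnames(tab),
                reference = reference)
}

#' Read / write recordings in EDF
#'
#' Minimal European Data Format support: a single continuous recording,
#' 16-bit samples, identical sampling rate on all channels, one-second data
#' records (the final partial second is zero-padded on write and trimmed on
#' read using the stored sample count).  Amplitudes are clipped to the
#' channel's physical min/max, which are set from the data on write.
#'
#' @param rec an [eeg_recording()]
#' @param path file path
#' @return `read_recording_edf` returns an [eeg_recording()]
#' @export
write_recording_edf <- function(rec, path) {
  ns <- n_channels(rec)
  fs <- rec$rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_recording_edf: integer sampling rate required", call. = FALSE)
  fs <- as.integer(round(fs))
  n_rec <- as.integer(ceiling(n_samples(rec) / fs))
  pad <- n_rec * fs - n_samples(rec)
  x <- cbind(rec$data, matrix(0, ns, pad))
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  fixed <- function(s, w) formatC(substr(s, 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fixed("0", 8), fixed("X X X X", 80), fixed("Startdate X", 80),
    fixed("01.01.00", 8), fixed("00.00.00", 8),
    fixed(as.character(256L * (ns + 1L)), 8),
    fixed(sprintf("dcmrank nsamp=%d", n_samples(rec)), 44),
    fixed(as.character(n_rec), 8), fixed("1", 8), fixed(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w)
    writeChar(paste(vapply(as.character(vals), fixed, "", w = w),
                    collapse = ""), con, eos = NULL)
  field(rec$labels, 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)                     # physical dimension
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)                      # reserved
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] - pmin_[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  fs <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(fs)) != 1)
    stop("read_recording_edf: mixed sampling rates unsupported", call. = FALSE)
  spr <- fs[1]
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  out <- matrix(0, ns, n_rec * spr)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr, size = 2, endian = "little",
                     signed = TRUE)
      out[ch, ((r - 1L) * spr + 1L):(r * spr)] <-
        pmin_[ch] + (dig - dmin_[ch]) * scale[ch]
    }
  }
  nsamp <- suppressWarnings(
    as.integer(sub(".*nsamp=([0-9]+).*", "\\1", reserved)))
  if (is.finite(nsamp) && nsamp >= 1 && nsamp <= ncol(out))
    out <- out[, seq_len(nsamp), drop = FALSE]
  eeg_recording(out, rate = spr / dur, labels = labels, reference = "online")
}
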