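# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples,
# one-second data records, physical units microvolts.  Events travel in a
# sidecar TSV (columns onset_sample, code, condition) because EDF proper has
# no annotation channel; EDF+ annotations are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) .edf_pad(format(x, scientific = FALSE), width)

#' Path of the events sidecar for an EDF file
#' @param path EDF file path.
#' @return the sidecar TSV path (`<base>_events.tsv`).
#' @export
events_sidecar_path <- function(path) {
  paste0(sub("\\.edf$", "", path, ignore.case = TRUE), "_events.tsv")
}

#' Write a recording as EDF plus an events sidecar
#'
#' Samples are quantized to 16 bits over each channel's observed physical
#' range (so round-trip error is at most half a quantization step; for
#' typical EEG ranges this is well below 0.01 uV).  The true sample count is
#' stored in the header's reserved field so that the zero-padding of the
#' final one-second record can be removed on read.
#'
#' @param rec a [raw_recording()]; `sampling_rate` must be an integer.
#' @param path output `.edf` path; the events table is written next to it
#'   at [events_sidecar_path()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  n_rec <- ceiling(n_samp / fs)
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.edf_pad("0", 8))
  wr(.edf_pad("X X X X", 80))
  wr(.edf_pad("Startdate X X X X", 80))
  wr("01.01.00"); wr("00.00.00")
  wr(.edf_num(256 * (1 + ns), 8))
  wr(.edf_pad(sprintf("NSAMP=%d", n_samp), 44))
  wr(.edf_num(n_rec, 8))
  wr(.edf_num(1, 8))
  wr(.edf_num(ns, 4))
  for (l in rec$channel_labels) wr(.edf_pad(l, 16))
  for (i in seq_len(ns)) wr(.edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(.edf_pad("uV", 8))
  for (v in pmin) wr(.edf_pad(formatC(v, digits = 7, format = "g"), 8))
  for (v in pmax) wr(.edf_pad(formatC(v, digits = 7, format = "g"), 8))
  for (i in seq_len(ns)) wr(.edf_num(dmin, 8))
  for (i in seq_len(ns)) wr(.edf_num(dmax, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 80))
  for (i in seq_len(ns)) wr(.edf_num(fs, 8))
  for (i in seq_len(ns)) wr(.edf_pad("", 32))

  scale <- (dmax - dmin) / (pmax - pmin)
  padded <- matrix(0, ns, n_rec * fs)
  padded[, seq_len(n_samp)] <- rec$data
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    dig <- round((padded[, cols, drop = FALSE] - pmin) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    # EDF stores each record signal-by-signal
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }

  ev <- rec$events
  if (!"condition" %in% names(ev)) ev$condition <- NA_character_
  utils::write.table(
    data.frame(onset_sample = ev$sample, code = ev$code,
               condition = ev$condition),
    events_sidecar_path(path),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  num(8)                                   # header bytes
  reserved <- trimws(rd(44))
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80)
  dims <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.numeric(fld(8)); fld(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  bad <- !(tolower(dims) %in% c("uv", "µv", ""))
  if (any(bad))
    stop("unit mismatch: expected microvolt (uV) signals, got: ",
         paste(unique(dims[bad]), collapse = ", "))
  spr <- spr[1]
  fs <- spr / rec_dur
  total <- n_rec * spr
  data <- matrix(0, ns, total)
  for (r in seq_len(n_rec)) {
    dig <- readBin(con, integer(), n = ns * spr, size = 2,
                   endian = "little")
    data[, ((r - 1) * spr + 1):(r * spr)] <-
      t(matrix(dig, nrow = spr, ncol = ns))
  }
  data <- (data - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  if (grepl("^NSAMP=", reserved)) {
    n_samp <- as.integer(sub("^NSAMP=", "", reserved))
    data <- data[, seq_len(n_samp), drop = FALSE]
  }
  list(data = data, sampling_rate = fs, labels = labels)
}

#' Read a recording
#'
#' Reads an EDF file written by [write_recording()] (or any 16-bit EDF with
#' uniform sampling and microvolt units) together with its mandatory events
#' sidecar TSV.  A missing sidecar is an error: downstream epoching is
#' meaningless without events.
#'
#' @param path `.edf` file path.
#' @param format `"edf"`.  `"vendor"` (proprietary continuous formats such
#'   as NeuroScan CNT) is recognized but not bundled: it requires an
#'   external reader and raises an informative error.
#' @return a [raw_recording()].
#' @export
read_recording <- function(path, format = c("edf", "vendor")) {
  format <- match.arg(format)
  if (format == "vendor")
    stop("vendor-continuous ingestion is not bundled; convert to EDF ",
         "with an external tool first")
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- events_sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing events sidecar: expected ", sidecar)
  raw <- read_edf_raw(path)
  ev <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "code") %in% names(ev)))
    stop("events sidecar must have columns onset_sample and code")
  events <- data.frame(sample = as.integer(ev$onset_sample),
                       code = as.character(ev$code),
                       stringsAsFactors = FALSE)
  if ("condition" %in% names(ev)) events$condition <- as.character(ev$condition)
  raw_recording(raw$data, raw$sampling_rate, raw$labels, events = events)
}
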