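# Minimal European Data Format (EDF) writer/reader: 16-bit samples, 1-second
# data records, one physical range per signal. Covers what the pipeline
# needs -- continuous multichannel recordings at an integer sampling rate.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a continuous recording to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's physical range; the
#' quantization step is `(max - min) / 65535` per channel. Recordings are
#' stored in 1-second data records; the final record is zero-padded if the
#' recording length is not a multiple of the sampling rate.
#'
#' @param rec a `continuous_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  data <- rec$data
  ns <- nrow(data)
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n)
    data <- cbind(data, matrix(0, ns, n_rec * fs - n))
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id %||% "X", 80),
    pad_field("synthetic oddball session", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(rec$channel_names, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("a.u.", 8), ns),
    vapply(sprintf("%.6g", pmin_), pad_field, "", width = 8),
    vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
    rep(pad_field(dmin, 8), ns),
    rep(pad_field(dmax, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(fs, 8), ns),
    rep(pad_field("", 32), ns))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((data - pmin_) * gain) + dmin   # recycles by row
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  chr <- function(nc) readChar(con, nc, useBytes = TRUE)
  num <- function(nc) as.numeric(trimws(chr(nc)))
  h <- list()
  chr(8)                      # version
  h$patient <- trimws(chr(80))
  h$recording <- trimws(chr(80))
  chr(16)                     # date + time
  h$header_bytes <- num(8)
  chr(44)
  h$n_records <- num(8)
  h$record_duration <- num(8)
  h$ns <- as.integer(num(4))
  ns <- h$ns
  h$labels <- trimws(vapply(seq_len(ns), function(i) chr(16), ""))
  vapply(seq_len(ns), function(i) chr(80), "")
  vapply(seq_len(ns), function(i) chr(8), "")
  h$pmin <- vapply(seq_len(ns), function(i) num(8), 0)
  h$pmax <- vapply(seq_len(ns), function(i) num(8), 0)
  h$dmin <- vapply(seq_len(ns), function(i) num(8), 0)
  h$dmax <- vapply(seq_len(ns), function(i) num(8), 0)
  vapply(seq_len(ns), function(i) chr(80), "")
  h$spr <- vapply(seq_len(ns), function(i) num(8), 0)
  vapply(seq_len(ns), function(i) chr(32), "")
  h
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return a `continuous_recording` with an empty event table.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1)
    stop("reader supports a single common sampling rate only", call. = FALSE)
  spr <- h$spr[1]
  fs <- spr / h$record_duration
  ns <- h$ns
  data <- matrix(0, ns, h$n_records * spr, dimnames = list(h$labels, NULL))
  gain <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  for (r in seq_len(h$n_records)) {
    raw <- readBin(con, "integer", n = ns * spr, size = 2, signed = TRUE,
                   endian = "little")
    block <- matrix(raw, nrow = spr, ncol = ns)
    idx <- ((r - 1) * spr + 1):(r * spr)
    data[, idx] <- t(block) * gain + (h$pmin - h$dmin * gain)
  }
  structure(list(
    channel_names = h$labels,
    sampling_rate = fs,
    data = data,
    events = data.frame(onset_sample = integer(), onset_s = numeric(),
                        condition = character(), stringsAsFactors = FALSE),
    montage = default_montage(),
    subject_id = h$patient
  ), class = "continuous_recording")
}

#' Write / read the tab-delimited event-marker table
#'
#' Columns: `onset_sample` (1-based), `onset_s`, `condition`.
#'
#' @param events data.frame with the three columns above.
#' @param path file path.
#' @return `path` (write) / validated events data.frame (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("onset_sample", "onset_s", "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset_sample", "onset_s", "condition")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!ev$condition %in% c("explosion", "burning", "control"))
  if (length(bad))
    stop(sprintf("unknown condition label '%s' in event-table row %d",
                 ev$condition[bad[1]], bad[1]), call. = FALSE)
  ev[, need]
}

#' Persist / load a full session (EDF + event table)
#'
#' `write_session()` writes `<prefix>.edf` and `<prefix>_events.tsv`;
#' `read_session()` loads both back into a `continuous_recording`. Sample
#' values round-trip within the per-channel EDF quantization step; events
#' round-trip exactly.
#'
#' @param rec a `continuous_recording`.
#' @param prefix path prefix (without extension).
#' @return `read_session()`: a `continuous_recording`.
#' @export
write_session <- function(rec, prefix) {
  write_edf(rec, paste0(prefix, ".edf"))
  write_events(rec$events, paste0(prefix, "_events.tsv"))
  invisible(prefix)
}

#' @rdname write_session
#' @export
read_session <- function(prefix) {
  rec <- read_edf(paste0(prefix, ".edf"))
  rec$events <- read_events(paste0(prefix, "_events.tsv"))
  if (nrow(rec$events) && max(rec$events$onset_sample) > ncol(rec$data))
    stop("event onsets fall outside the recording", call. = FALSE)
  rec
}
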