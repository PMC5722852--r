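# Minimal European Data Format (EDF) input/output.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian 16-bit integers, one block per signal per record.
# We use 1-second records; a trailing partial record is zero-padded on write
# and the true sample count is restored on read from the 'reserved' header
# field. The recording start date/time is written as a fixed placeholder so
# that output bytes are a pure function of the data.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write a recording to an EDF file
#'
#' The 19 scalp channels and the two EOG references (labels `EOG V`,
#' `EOG H`) are stored as 21 EDF signals in microvolts, quantized to 16
#' bits over each channel's observed physical range.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  data <- rbind(recording$signal,
                `EOG V` = recording$eog_v,
                `EOG H` = recording$eog_h)
  ns <- nrow(data)
  n_samp <- ncol(data)
  n_rec <- as.integer(ceiling(n_samp / fs))
  if (n_rec * fs > n_samp) {
    data <- cbind(data, matrix(0, ns, n_rec * fs - n_samp))
  }

  phys_min <- apply(data, 1L, min)
  phys_max <- apply(data, 1L, max)
  flat <- phys_max - phys_min < 1e-9
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L

  labels <- rownames(data)
  sig_labels <- ifelse(grepl("^EOG", labels), labels, paste("EEG", labels))

  con <- file(path, "wb")
  on.exit(close(con))
  wrt <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wrt(pad_ascii("0", 8))                       # version
  wrt(pad_ascii("X X X X", 80))                # patient id (anonymous)
  wrt(pad_ascii(sprintf("Startdate X X X X sub-%d", recording$subject_id), 80))
  wrt(pad_ascii("01.01.00", 8))                # fixed date for reproducibility
  wrt(pad_ascii("00.00.00", 8))
  wrt(pad_ascii(256L * (1L + ns), 8))          # header bytes
  wrt(pad_ascii(sprintf("nsamples=%d", n_samp), 44)) # reserved: true length
  wrt(pad_ascii(n_rec, 8))
  wrt(pad_ascii(1L, 8))                        # record duration, seconds
  wrt(pad_ascii(ns, 4))
  for (l in sig_labels) wrt(pad_ascii(l, 16))
  for (i in seq_len(ns)) wrt(pad_ascii("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wrt(pad_ascii("uV", 8))
  for (i in seq_len(ns)) wrt(pad_ascii(sprintf("%.6g", phys_min[i]), 8))
  for (i in seq_len(ns)) wrt(pad_ascii(sprintf("%.6g", phys_max[i]), 8))
  for (i in seq_len(ns)) wrt(pad_ascii(dig_min, 8))
  for (i in seq_len(ns)) wrt(pad_ascii(dig_max, 8))
  for (i in seq_len(ns)) wrt(pad_ascii("", 80))    # prefiltering
  for (i in seq_len(ns)) wrt(pad_ascii(fs, 8))
  for (i in seq_len(ns)) wrt(pad_ascii("", 32))    # reserved

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((data[i, idx] - phys_min[i]) * scale[i]) + dig_min
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Reads 16-bit EDF files written by [write_edf()] (and plain continuous
#' EDF in general), rescaling digital values to physical units. Signals
#' labelled `EOG V`/`EOG H` are mapped back to the recording's reference
#' slots.
#'
#' @param path EDF file path.
#' @param subject_id Subject id to attach (default parsed from the header
#'   when present, else 0).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    out <- readChar(con, nc, useBytes = TRUE)
    trimws(out)
  }
  rd(8)                        # version
  rd(80)                       # patient
  rec_id <- rd(80)
  rd(8); rd(8)                 # date, time
  rd(8)                        # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8) # units
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  if (length(unique(spr)) != 1L) abort("mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L, endian = "little")
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      data[i, idx] <- phys_min[i] +
        (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    }
  }
  m <- regmatches(reserved, regexec("nsamples=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) data <- data[, seq_len(as.integer(m[2])), drop = FALSE]

  if (is.null(subject_id)) {
    sm <- regmatches(rec_id, regexec("sub-([0-9]+)", rec_id))[[1]]
    subject_id <- if (length(sm) == 2L) as.integer(sm[2]) else 0L
  }
  clean <- sub("^EEG ", "", labels)
  is_v <- clean == "EOG V"; is_h <- clean == "EOG H"
  scalp <- !(is_v | is_h)
  new_recording(data[scalp, , drop = FALSE], fs, clean[scalp],
                eog_v = if (any(is_v)) data[which(is_v)[1], ] else numeric(ncol(data)),
                eog_h = if (any(is_h)) data[which(is_h)[1], ] else numeric(ncol(data)),
                subject_id = subject_id)
}

#' Write / read an event log as tab-delimited text
#'
#' @param events Event tibble (`onset_sample` 0-based, `g`, `label`,
#'   `presentation_samples`).
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the event tibble.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset_sample", "g", "label", "presentation_samples")
                %in% names(events)))
  readr::write_tsv(as_tibble(events), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ev$onset_sample <- as.integer(ev$onset_sample)
  ev$presentation_samples <- as.integer(ev$presentation_samples)
  class(ev) <- c("eeg_events", class(ev))
  ev
}
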