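# Minimal EDF (European Data Format) reader/writer for continuous EEG.
#
# EDF stores 16-bit integers with a per-signal linear physical/digital map;
# the quantization step is (phys_max - phys_min) / (dig_max - dig_min).
# One data record per second is used, so recordings must contain a whole
# number of seconds. Subject/session/task metadata travel in the patient and
# recording-identification header fields as key=value pairs, since EDF has
# no native slots for them.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

EDF_PHYS_RANGE <- c(-500, 500)  # microvolts; covers rhythms plus artifacts
EDF_DIG_RANGE <- c(-32768L, 32767L)

#' Write a recording as an EDF file
#'
#' Samples are quantized to 16 bits over a +/-500 microvolt physical range
#' (step ~0.0153 uV); values outside the range are clipped. The recording
#' must contain a whole number of seconds (one EDF data record per second).
#'
#' @param recording an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stopf("write_edf requires an integer sampling rate")
  n <- ncol(recording$data)
  if (n %% fs != 0) {
    stopf("recording length (%d samples) must be a whole number of seconds at %g Hz", n, fs)
  }
  ns <- nrow(recording$data)
  n_rec <- n %/% fs
  con <- file(path, "wb")
  on.exit(close(con))
  rec_id <- sprintf("subject=%s session=%d task=%s", recording$subject_id,
                    recording$session_id,
                    ifelse(is.na(recording$task_id), "NA", recording$task_id))
  header <- paste0(
    edf_pad("0", 8), edf_pad(recording$subject_id, 80), edf_pad(rec_id, 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  sig <- paste0(
    paste(edf_pad(recording$channel_labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(EDF_PHYS_RANGE[1], 8), ns), collapse = ""),
    paste(rep(edf_pad(EDF_PHYS_RANGE[2], 8), ns), collapse = ""),
    paste(rep(edf_pad(EDF_DIG_RANGE[1], 8), ns), collapse = ""),
    paste(rep(edf_pad(EDF_DIG_RANGE[2], 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(header, sig), con, eos = NULL)
  scale <- diff(EDF_DIG_RANGE) / diff(EDF_PHYS_RANGE)
  dig <- round((recording$data - EDF_PHYS_RANGE[1]) * scale + EDF_DIG_RANGE[1])
  dig <- pmin(pmax(dig, EDF_DIG_RANGE[1]), EDF_DIG_RANGE[2])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

edf_field <- function(raw, off, width) trimws(rawToChar(raw[(off + 1):(off + width)]))

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return an [eeg_recording]; subject/session/task are recovered from the
#'   recording-identification header field when present.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 256) stopf("malformed EDF file (truncated header): %s", path)
  patient <- edf_field(raw, 8, 80)
  rec_id <- edf_field(raw, 88, 80)
  n_rec <- as.integer(edf_field(raw, 236, 8))
  rec_dur <- as.numeric(edf_field(raw, 244, 8))
  ns <- as.integer(edf_field(raw, 252, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stopf("malformed EDF header: %s", path)
  hdr_len <- 256 + 256 * ns
  if (length(raw) < hdr_len) stopf("malformed EDF file (truncated signal header): %s", path)
  fld <- function(block_off, width, i) {
    edf_field(raw, 256 + block_off * ns + (i - 1) * width, width)
  }
  labels <- vapply(seq_len(ns), function(i) fld(0, 16, i), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) fld(104, 8, i), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) fld(112, 8, i), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) fld(120, 8, i), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) fld(128, 8, i), character(1)))
  spr <- as.integer(vapply(seq_len(ns), function(i) fld(216, 8, i), character(1)))
  expected <- hdr_len + 2 * n_rec * sum(spr)
  if (length(raw) != expected) {
    stopf("malformed EDF file (size %d, expected %d): %s", length(raw), expected, path)
  }
  vals <- readBin(raw[(hdr_len + 1):length(raw)], "integer",
                  n = n_rec * sum(spr), size = 2, endian = "little")
  if (length(unique(spr)) != 1) stopf("mixed per-signal sampling rates unsupported: %s", path)
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  pos <- 0
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      data[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <- vals[(pos + 1):(pos + spr[i])]
      pos <- pos + spr[i]
    }
  }
  for (i in seq_len(ns)) {
    data[i, ] <- (data[i, ] - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) + pmin_[i]
  }
  meta <- function(key, default) {
    m <- regmatches(rec_id, regexpr(sprintf("%s=\\S+", key), rec_id))
    if (length(m)) sub(sprintf("%s=", key), "", m) else default
  }
  task <- meta("task", "NA")
  eeg_recording(data, fs, labels,
                subject_id = meta("subject", patient),
                session_id = as.integer(meta("session", "1")),
                task_id = if (task == "NA") NA_integer_ else as.integer(task))
}
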