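#' Default 10-channel montage
#'
#' Frontal-polar, frontal, central, parietal and occipital electrode pairs of
#' the international 10--20 system used throughout the package.
#' @export
ATTN_CHANNELS <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")

#' Construct a multichannel EEG recording
#'
#' @param data channels x samples numeric matrix in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param subject_id subject identifier string.
#' @param session_id session number (1-based).
#' @param task_id attention task 1--4 (1 = high ... 4 = non-externally
#'   directed), or `NA` for unlabelled data.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          subject_id = "S01", session_id = 1L, task_id = NA_integer_) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("data must be a numeric matrix")
  if (is.null(channel_labels)) stopf("channel_labels are required")
  if (nrow(data) != length(channel_labels)) {
    stopf("data has %d rows but %d channel labels", nrow(data), length(channel_labels))
  }
  if (anyDuplicated(channel_labels)) stopf("duplicate channel labels")
  if (!all(is.finite(data))) stopf("recording contains non-finite samples")
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0)) stopf("fs must be a positive number")
  if (!is.na(task_id) && !(task_id %in% 1:4)) stopf("task_id must be in 1..4")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = as.character(subject_id),
                 session_id = as.integer(session_id),
                 task_id = as.integer(task_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject %s, session %d, task %s\n", x$subject_id, x$session_id,
              ifelse(is.na(x$task_id), "?", x$task_id)))
  invisible(x)
}

recording_duration <- function(recording) ncol(recording$data) / recording$fs
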