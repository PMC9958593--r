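#' Segmentation parameters
#'
#' @param window_s window length in seconds (default 4).
#' @param overlap_s overlap between consecutive windows (default 2);
#'   must satisfy `0 <= overlap_s < window_s`.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(window_s = 4, overlap_s = 2) {
  if (!(overlap_s >= 0 && overlap_s < window_s)) {
    stopf("overlap_s must be in [0, window_s); got window %g, overlap %g",
          window_s, overlap_s)
  }
  structure(list(window_s = window_s, overlap_s = overlap_s),
            class = "segmentation_params")
}

#' Remove high-amplitude bad segments
#'
#' Automated stand-in for manual bad-segment marking: any contiguous run of
#' samples where any channel exceeds `amp_threshold_uV` in magnitude,
#' padded by `pad_s` seconds on both sides, is excised; the surviving
#' segments are concatenated. Rejected intervals are reported in the
#' original sample coordinates.
#'
#' @param recording an [eeg_recording].
#' @param amp_threshold_uV rejection threshold in microvolts (> 0).
#' @param pad_s padding around each bad run, in seconds.
#' @return list with `recording` (cleaned) and `rejected` (data.frame with
#'   1-based inclusive `start`/`end` columns; zero rows if nothing rejected).
#' @export
reject_bad_segments <- function(recording, amp_threshold_uV = 100, pad_s = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!(amp_threshold_uV > 0)) stopf("amp_threshold_uV must be positive")
  n <- ncol(recording$data)
  bad <- apply(abs(recording$data) > amp_threshold_uV, 2, any)
  if (!any(bad)) {
    return(list(recording = recording,
                rejected = data.frame(start = integer(0), end = integer(0))))
  }
  pad <- round(pad_s * recording$fs)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(pmax(1, starts[r$values] - pad), pmin(n, ends[r$values] + pad))
  # merge overlapping padded intervals
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[i, 1] <= merged[last, 2] + 1) {
      merged[last, 2] <- max(merged[last, 2], iv[i, 2])
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(merged))) keep[merged[i, 1]:merged[i, 2]] <- FALSE
  out <- recording
  out$data <- recording$data[, keep, drop = FALSE]
  list(recording = out,
       rejected = data.frame(start = merged[, 1], end = merged[, 2]))
}

#' Cut a recording into fixed-length overlapping epochs
#'
#' Windows of `window_s` seconds start every `window_s - overlap_s` seconds;
#' a trailing partial window is discarded. Each epoch inherits the
#' recording's task label, subject and session.
#'
#' @param recording an [eeg_recording].
#' @param params a [segmentation_params]; default 4 s windows, 2 s overlap.
#' @return list of `eeg_epoch` objects (possibly empty, with a warning, when
#'   the recording is shorter than one window).
#' @export
segment <- function(recording, params = segmentation_params()) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  L <- round(params$window_s * fs)
  hop <- round((params$window_s - params$overlap_s) * fs)
  n <- ncol(recording$data)
  if (n < L) {
    warning(sprintf("recording shorter than one window (%d < %d samples); no epochs",
                    n, L))
    return(list())
  }
  starts <- seq(1L, n - L + 1L, by = hop)
  lapply(starts, function(s) {
    structure(list(data = recording$data[, s:(s + L - 1L), drop = FALSE],
                   fs = fs, channel_labels = recording$channel_labels,
                   label = recording$task_id, subject_id = recording$subject_id,
                   session_id = recording$session_id, start_index = s),
              class = "eeg_epoch")
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d ch x %d samples @ %g Hz, label %s (%s ses %d, start %d)\n",
              nrow(x$data), ncol(x$data), x$fs, x$label, x$subject_id,
              x$session_id, x$start_index))
  invisible(x)
}

#' Preprocess a recording: band-pass then bad-segment rejection
#'
#' @param recording an [eeg_recording].
#' @param low_hz,high_hz FIR band-pass edges (see [bandpass_fir()]).
#' @param amp_threshold_uV rejection threshold (see [reject_bad_segments()]).
#' @param pad_s rejection padding in seconds.
#' @return list with `recording` and `rejected` as in [reject_bad_segments()].
#' @export
preprocess_recording <- function(recording, low_hz = 0.5, high_hz = 30,
                                 amp_threshold_uV = 100, pad_s = 0.5) {
  reject_bad_segments(bandpass_fir(recording, low_hz, high_hz),
                      amp_threshold_uV, pad_s)
}
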