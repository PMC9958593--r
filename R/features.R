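# The ten per-channel features: six time-domain statistics (F1-F6), sample
# entropy (F7), and the wavelet-packet theta/alpha/beta band-energy ratios
# (F8-F10). The assembled vector is feature-major: F1 over all channels,
# then F2, ..., F10 (100 values for the default 10-channel montage).

#' Six time-domain features of a window
#'
#' For an N-point window `x`:
#' F1 rectified average `mean(|x|)`; F2 maximum (signed); F3 peak difference
#' `max - min`; F4 root mean square; F5 population standard deviation (1/N
#' normalization); F6 margin factor `max(|x|) / mean(sqrt(|x|))^2`.
#' F6 is `NA` (with a warning) for an all-zero window.
#'
#' @param x numeric window, length >= 2, finite.
#' @return named numeric vector `F1`..`F6`.
#' @export
time_domain_features <- function(x) {
  if (length(x) < 2 || !all(is.finite(x))) stopf("x must be finite with length >= 2")
  n <- length(x)
  f1 <- mean(abs(x))
  f2 <- max(x)
  f3 <- f2 - min(x)
  f4 <- sqrt(mean(x^2))
  f5 <- sqrt(mean((x - mean(x))^2))
  denom <- mean(sqrt(abs(x)))^2
  f6 <- if (denom == 0) {
    warning("margin factor undefined for all-zero window")
    NA_real_
  } else max(abs(x)) / denom
  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5, F6 = f6)
}

#' Sample-entropy parameters
#'
#' @param m embedding dimension (default 2).
#' @param r_factor match tolerance as a multiple of the window's sample
#'   standard deviation (default 0.2).
#' @return object of class `sampen_params`.
#' @export
sampen_params <- function(m = 2L, r_factor = 0.2) {
  if (!is_count(m) || m < 1) stopf("m must be a positive integer")
  if (!(r_factor > 0)) stopf("r_factor must be positive")
  structure(list(m = as.integer(m), r_factor = r_factor), class = "sampen_params")
}

#' Sample entropy of a window
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts template pairs of length `m`
#' whose Chebyshev distance is strictly below `r`, and `A` the pairs that
#' still match when extended to length `m + 1`. Templates `i = 1..N-m`,
#' self-matches excluded, `r = r_factor * sd(x)` (sample sd). When no
#' extended match exists the value is undefined and `NA` is returned with a
#' warning rather than an infinity.
#'
#' @param x numeric window with `length(x) > m + 1` and positive variance.
#' @param params a [sampen_params].
#' @return non-negative entropy value, or `NA` when undefined.
#' @export
sample_entropy <- function(x, params = sampen_params()) {
  m <- params$m
  if (length(x) <= m + 1) stopf("window too short for m = %d", m)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stopf("zero-variance window: sample entropy undefined")
  r <- params$r_factor * s
  cnt <- .sampen_counts(as.numeric(x), m, r)
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) {
    warning("sample entropy undefined (no template matches)")
    return(NA_real_)
  }
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Extract the full feature vector of one epoch
#'
#' Computes F1--F10 for every channel and assembles them feature-major
#' (F1 over the channels in montage order, then F2, ...). Any per-channel
#' failure is rethrown with the channel identity attached.
#'
#' @param epoch an `eeg_epoch` from [segment()].
#' @param se a [sampen_params].
#' @param wpd a [wpd_params]; defaults to the epoch's sampling rate.
#' @return named numeric vector of length `10 * n_channels` with attributes
#'   `label`, `subject_id`, `session_id`.
#' @export
extract_features <- function(epoch, se = sampen_params(),
                             wpd = wpd_params(epoch$fs)) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  ch <- epoch$channel_labels
  per_channel <- matrix(NA_real_, 10, length(ch),
                        dimnames = list(paste0("F", 1:10), ch))
  for (i in seq_along(ch)) {
    x <- epoch$data[i, ]
    res <- tryCatch({
      td <- time_domain_features(x)
      sa <- sample_entropy(x, se)
      br <- wpd_band_ratios(x, epoch$fs, wpd)
      c(td, F7 = sa, F8 = unname(br[["theta"]]), F9 = unname(br[["alpha"]]),
        F10 = unname(br[["beta"]]))
    }, error = function(e) stopf("channel %s: %s", ch[i], conditionMessage(e)))
    per_channel[, i] <- res
  }
  v <- as.numeric(t(per_channel))
  names(v) <- paste0(rep(paste0("F", 1:10), each = length(ch)), "_", ch)
  attr(v, "label") <- epoch$label
  attr(v, "subject_id") <- epoch$subject_id
  attr(v, "session_id") <- epoch$session_id
  v
}

#' Extract a feature table from a list of epochs
#'
#' @param epochs list of `eeg_epoch` objects with identical montages.
#' @param se a [sampen_params].
#' @param wpd a [wpd_params]; defaults to the first epoch's sampling rate.
#' @return data.frame with one row per epoch: the feature columns in
#'   feature-major order plus `label`, `subject_id`, `session_id`.
#' @export
extract_feature_table <- function(epochs, se = sampen_params(),
                                  wpd = if (length(epochs)) wpd_params(epochs[[1]]$fs)
                                        else wpd_params()) {
  if (!length(epochs)) stopf("no epochs to extract features from")
  rows <- lapply(epochs, extract_features, se = se, wpd = wpd)
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat)
  df$label <- vapply(epochs, function(e) as.integer(e$label), integer(1))
  df$subject_id <- vapply(epochs, function(e) e$subject_id, character(1))
  df$session_id <- vapply(epochs, function(e) as.integer(e$session_id), integer(1))
  df
}

#' Names of the feature columns of a feature table
#' @param features a feature table from [extract_feature_table()].
#' @return character vector of feature column names (metadata excluded).
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("label", "subject_id", "session_id"))
}
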