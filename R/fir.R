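#' Design a linear-phase windowed-sinc band-pass kernel
#'
#' Hamming-windowed sinc band-pass built as the difference of two low-pass
#' kernels, so the DC gain is exactly zero. Kernel length is set by the
#' narrower of the two transition bands (approximately `3.3 * fs / width`
#' taps for a Hamming window), giving >= 50 dB stop-band attenuation.
#'
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz -6 dB band edges in Hz.
#' @param trans_low_hz,trans_high_hz transition widths at each edge; defaults
#'   follow the convention used throughout the package: the lower transition
#'   equals the lower cutoff, the upper transition is 1 Hz.
#' @return numeric kernel of odd length, zero DC gain, unit pass-band gain.
#' @export
fir_bandpass_kernel <- function(fs, low_hz = 0.5, high_hz = 30,
                                trans_low_hz = low_hz, trans_high_hz = 1) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stopf("band edges must satisfy 0 < low (%g) < high (%g) < fs/2 (%g)",
          low_hz, high_hz, fs / 2)
  }
  width <- min(trans_low_hz, trans_high_hz)
  n <- ceiling(3.3 * fs / width)
  if (n %% 2 == 0) n <- n + 1
  m <- (n - 1) / 2
  lowpass <- function(fc) {
    k <- (-m):m
    h <- 2 * fc / fs * sinc_fn(2 * fc / fs * k)
    w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
    h <- h * w
    h / sum(h)
  }
  lowpass(high_hz) - lowpass(low_hz)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# FFT-based linear convolution of x with kernel h, delay-compensated so the
# output is time-aligned with x and of equal length. h must have odd length.
fir_apply <- function(x, h) {
  n <- length(x)
  L <- length(h)
  m <- (L - 1) / 2
  nfft <- stats::nextn(n + L - 1)
  X <- fft(c(x, numeric(nfft - n)))
  H <- fft(c(h, numeric(nfft - L)))
  y <- Re(fft(X * H, inverse = TRUE)) / nfft
  y[(m + 1):(m + n)]
}

#' Band-pass filter a recording with a zero-phase FIR filter
#'
#' Applies a linear-phase windowed-sinc band-pass per channel with
#' group-delay compensation: the output has the same length as the input and
#' is time-aligned with it. Default pass band 0.5--30 Hz retains the delta
#' through beta EEG rhythms and suppresses line noise and slow drift.
#'
#' @param recording an [eeg_recording].
#' @param low_hz,high_hz pass-band edges in Hz.
#' @return the filtered [eeg_recording].
#' @export
bandpass_fir <- function(recording, low_hz = 0.5, high_hz = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  h <- fir_bandpass_kernel(recording$fs, low_hz, high_hz)
  out <- recording
  out$data <- t(apply(recording$data, 1, fir_apply, h = h))
  dimnames(out$data) <- dimnames(recording$data)
  out
}
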