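# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair counting for sample entropy,
# plain FFT/Welch periodograms for band power.

# O(N^2) sample-entropy match counts, straight from the definition.
oracle_sampen_counts <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0L
  B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

oracle_sampen <- function(x, m = 2, r_factor = 0.2) {
  cnt <- oracle_sampen_counts(x, m, r_factor * sd(x))
  -log(cnt[["A"]] / cnt[["B"]])
}

# Fraction of FFT power in [lo, hi) Hz relative to total power.
oracle_fft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  keep <- f <= fs / 2
  sum(p[keep][f[keep] >= lo & f[keep] < hi]) / sum(p[keep])
}

# Welch band-power fraction: averaged modified periodogram over 4 s Hann
# segments with 50% overlap, band fraction relative to total power.
oracle_welch_band_fraction <- function(x, fs, lo, hi, seg_s = 4) {
  L <- seg_s * fs
  hop <- L / 2
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  starts <- seq(1, length(x) - L + 1, by = hop)
  acc <- numeric(L)
  for (s in starts) acc <- acc + Mod(fft((x[s:(s + L - 1)] - mean(x[s:(s + L - 1)])) * w))^2
  f <- (0:(L - 1)) * fs / L
  keep <- f <= fs / 2
  sum(acc[keep][f[keep] >= lo & f[keep] < hi]) / sum(acc[keep])
}

# Small labelled feature-table builder for selection/evaluation tests:
# `informative` names groups whose columns carry the class signal, the rest
# are pure noise. Columns follow the package naming scheme F<g>_<channel>.
make_toy_features <- function(n_per_class = 30, n_classes = 4,
                              groups = paste0("F", 1:10), n_channels = 10,
                              informative = "F1", signal = 3, seed = 1) {
  set.seed(seed)
  n <- n_per_class * n_classes
  label <- rep(seq_len(n_classes), each = n_per_class)
  cols <- list()
  for (g in groups) {
    for (ch in seq_len(n_channels)) {
      v <- rnorm(n)
      if (g %in% informative) v <- v + signal * label
      cols[[paste0(g, "_ch", ch)]] <- v
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  df$label <- label
  df$subject_id <- rep(sprintf("S%02d", rep(1:2, length.out = n_per_class)), n_classes)
  df$session_id <- rep(rep(1:2, each = ceiling(n_per_class / 2), length.out = n_per_class), n_classes)
  df
}

# One small clean recording for preprocessing/IO tests.
make_test_recording <- function(duration_s = 12, fs = 512, seed = 42,
                                task_id = 1L) {
  profile <- default_state_profiles()[[1]]
  dat <- attnEEG:::with_seed(seed,
    synthesize_state_signal(profile, length(ATTN_CHANNELS), duration_s, fs,
                            ATTN_CHANNELS))
  eeg_recording(dat, fs, ATTN_CHANNELS, subject_id = "S01", session_id = 1L,
                task_id = task_id)
}
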