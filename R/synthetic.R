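# Synthetic EEG cohort generator.
#
# Each attention state is a mixture of band-limited oscillatory processes
# (delta/theta/alpha/beta, realized as spectrally shaped Gaussian noise so
# epochs are stochastic and entropy features are informative) and a 1/f
# broadband background, with per-subject and per-session multiplicative
# jitter on the band fractions. Attention is encoded as in the EEG
# literature: higher attention -> larger beta fraction, smaller theta+alpha
# fraction, plus a larger broadband (higher-complexity) share.

BAND_EDGES <- list(delta = c(0.5, 4), theta = c(4, 8),
                   alpha = c(8, 13), beta = c(13, 30))

#' Attention-state spectral profile
#'
#' @param state_id 1 = high, 2 = medium, 3 = low, 4 = non-externally directed.
#' @param band_fractions named fractions over delta/theta/alpha/beta of the
#'   oscillatory power; must be non-negative and sum to 1.
#' @param noise_mix fraction in `[0,1]` of total power carried by the 1/f
#'   broadband background (the rest is band-limited oscillation).
#' @param amplitude_uV target per-channel RMS in microvolts (before regional
#'   gain).
#' @param region_gains named amplitude multipliers per channel label;
#'   channels not named get gain 1.
#' @return object of class `attn_state_profile`.
#' @export
state_profile <- function(state_id, band_fractions, noise_mix, amplitude_uV,
                          region_gains = NULL) {
  if (!(state_id %in% 1:4)) stopf("state_id must be in 1..4")
  bf <- band_fractions[names(BAND_EDGES)]
  if (anyNA(bf)) stopf("band_fractions must name delta, theta, alpha, beta")
  if (any(bf < 0) || abs(sum(bf) - 1) > 1e-8) {
    stopf("band_fractions must be non-negative and sum to 1 (got sum %.6f)", sum(bf))
  }
  if (!(noise_mix >= 0 && noise_mix <= 1)) stopf("noise_mix must be in [0,1]")
  if (!(amplitude_uV > 0)) stopf("amplitude_uV must be positive")
  structure(list(state_id = as.integer(state_id), band_fractions = bf,
                 noise_mix = noise_mix, amplitude_uV = amplitude_uV,
                 region_gains = region_gains),
            class = "attn_state_profile")
}

#' Default state profiles for the four attention levels
#'
#' Beta fraction decreases strictly from state 1 (high attention) to state 4
#' (non-externally directed) while the theta+alpha fraction increases;
#' the broadband share decreases with decreasing attention so that signal
#' complexity (sample entropy) also separates the states; overall amplitude
#' grows toward the relaxed states.
#'
#' @param region_gains default mild regional amplitude pattern (occipital
#'   channels slightly stronger, frontal-polar slightly weaker).
#' @return list of four [state_profile] objects.
#' @export
default_state_profiles <- function(region_gains = c(Fp1 = 0.9, Fp2 = 0.9,
                                                    P3 = 1.05, P4 = 1.05,
                                                    O1 = 1.1, O2 = 1.1)) {
  list(
    state_profile(1, c(delta = 0.15, theta = 0.15, alpha = 0.20, beta = 0.50),
                  noise_mix = 0.45, amplitude_uV = 14, region_gains = region_gains),
    state_profile(2, c(delta = 0.15, theta = 0.20, alpha = 0.30, beta = 0.35),
                  noise_mix = 0.38, amplitude_uV = 15, region_gains = region_gains),
    state_profile(3, c(delta = 0.20, theta = 0.25, alpha = 0.33, beta = 0.22),
                  noise_mix = 0.30, amplitude_uV = 16, region_gains = region_gains),
    state_profile(4, c(delta = 0.25, theta = 0.30, alpha = 0.33, beta = 0.12),
                  noise_mix = 0.22, amplitude_uV = 17, region_gains = region_gains)
  )
}

#' Cohort configuration
#'
#' Defaults emulate the study design the package targets: 14 subjects, two
#' sessions 30 min apart, four tasks per session, 512 Hz, 10 channels, and a
#' task duration chosen so each subject contributes 50--80 four-second
#' windows per task across both sessions (66 s -> 32 windows per session).
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject.
#' @param fs sampling rate in Hz (> 60).
#' @param task_duration_s seconds of signal per task per session (>= 4).
#' @param channel_labels ordered montage.
#' @param subject_sd log-normal sd of the between-subject multiplicative
#'   jitter applied to band fractions.
#' @param session_sd log-normal sd of the per-session band-fraction jitter.
#' @param subject_amp_sd log-normal sd of the per-subject amplitude factor;
#'   the default 0.15 makes between-subject amplitude differences larger
#'   than the small between-state amplitude effect, as in real scalp EEG
#'   where impedance and anatomy dominate absolute microvolt levels.
#' @param session_amp_sd log-normal sd of the per-session amplitude factor
#'   (electrode re-application between sessions).
#' @param seed integer RNG seed for the whole cohort.
#' @return object of class `attn_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 14, n_sessions = 2, fs = 512,
                          task_duration_s = 66, channel_labels = ATTN_CHANNELS,
                          subject_sd = 0.08, session_sd = 0.03,
                          subject_amp_sd = 0.15, session_amp_sd = 0.05,
                          seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 1) stopf("n_subjects must be >= 1")
  if (!is_count(n_sessions) || n_sessions < 1) stopf("n_sessions must be >= 1")
  if (!(fs > 60)) stopf("fs must exceed 60 Hz (twice the upper analysis band)")
  if (anyDuplicated(channel_labels)) stopf("channel_labels must be unique")
  if (!(task_duration_s >= 4)) stopf("task_duration_s must be >= 4 s")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions), fs = fs,
                 task_duration_s = task_duration_s,
                 channel_labels = channel_labels,
                 subject_sd = subject_sd, session_sd = session_sd,
                 subject_amp_sd = subject_amp_sd, session_amp_sd = session_amp_sd,
                 seed = as.integer(seed)),
            class = "attn_cohort_config")
}

# Unit-variance Gaussian noise with power spectral density proportional to
# weight(f); DC is zero so the signal is zero-mean.
spectral_noise <- function(n, fs, weight) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  w <- sqrt(weight(f))
  re <- rnorm(nf) * w
  im <- rnorm(nf) * w
  if (n %% 2 == 0) {
    spec <- complex(real = re, imaginary = c(im[-nf], 0))
    full <- c(0, spec, Conj(rev(spec[-nf])))
  } else {
    spec <- complex(real = re, imaginary = im)
    full <- c(0, spec, Conj(rev(spec)))
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) stopf("degenerate spectral weight: zero-power signal")
  x / s
}

# Raised-cosine band window on [lo, hi] with total transition width `trans`.
band_weight <- function(lo, hi, trans = 0.4) {
  force(lo); force(hi); force(trans)
  function(f) {
    w <- numeric(length(f))
    w[f >= lo + trans / 2 & f <= hi - trans / 2] <- 1
    up <- f > lo - trans / 2 & f < lo + trans / 2
    dn <- f > hi - trans / 2 & f < hi + trans / 2
    w[up] <- 0.5 * (1 + sin(pi * (f[up] - lo) / trans))
    w[dn] <- 0.5 * (1 - sin(pi * (f[dn] - hi) / trans))
    w
  }
}

# 1/f power density restricted to the analysis band.
pink_weight <- function(lo = 0.5, hi = 30) {
  bw <- band_weight(lo, hi)
  function(f) bw(f) / pmax(f, lo)
}

#' Synthesize one multichannel state signal
#'
#' Each channel is an independent realization of
#' `region_gain * (sqrt(noise_mix) * pink + sum_b sqrt((1 - noise_mix) *
#' fraction_b) * band_b)` with every component scaled to unit RMS, then the
#' channel is rescaled so its RMS equals `amplitude_uV * region_gain`.
#'
#' @param profile a [state_profile].
#' @param n_channels number of channels to generate.
#' @param duration_s signal duration in seconds (>= 4).
#' @param fs sampling rate in Hz (>= 64).
#' @param channel_labels optional labels used to look up `region_gains`.
#' @return channels x samples matrix in microvolts.
#' @export
synthesize_state_signal <- function(profile, n_channels, duration_s, fs,
                                    channel_labels = NULL) {
  stopifnot(inherits(profile, "attn_state_profile"))
  if (duration_s < 4) stopf("duration_s must be >= 4")
  if (fs < 64) stopf("fs must be >= 64")
  n <- round(duration_s * fs)
  gains <- rep(1, n_channels)
  if (!is.null(profile$region_gains) && !is.null(channel_labels)) {
    hit <- match(channel_labels, names(profile$region_gains))
    gains <- ifelse(is.na(hit), 1, profile$region_gains[hit])
  }
  bf <- profile$band_fractions
  nm <- profile$noise_mix
  out <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    x <- if (nm > 0) sqrt(nm) * spectral_noise(n, fs, pink_weight()) else numeric(n)
    for (b in names(bf)) {
      if (bf[[b]] <= 0) next
      e <- BAND_EDGES[[b]]
      x <- x + sqrt((1 - nm) * bf[[b]]) * spectral_noise(n, fs, band_weight(e[1], e[2]))
    }
    out[ch, ] <- x / sqrt(mean(x^2)) * (profile$amplitude_uV * gains[ch])
  }
  rownames(out) <- channel_labels
  out
}

# Multiplicative log-normal jitter on band fractions, renormalized so they
# remain a valid probability vector.
jitter_fractions <- function(bf, sd) {
  if (sd <= 0) return(bf)
  j <- bf * exp(rnorm(length(bf), 0, sd))
  j / sum(j)
}

#' Generate a labelled multi-subject, multi-session cohort
#'
#' Produces `n_subjects * n_sessions * 4` recordings. Subject effects are
#' log-normal multiplicative jitter on the state band fractions (shared
#' across that subject's sessions); each session adds smaller independent
#' jitter so cross-session evaluation is non-trivial. Identical
#' `(config, profiles)` including the seed reproduce the cohort bit for bit.
#'
#' @param config a [cohort_config].
#' @param profiles list of four [state_profile] objects, one per state.
#' @return list of [eeg_recording] objects in subject/session/task order.
#' @export
make_cohort <- function(config = cohort_config(),
                        profiles = default_state_profiles()) {
  stopifnot(inherits(config, "attn_cohort_config"))
  if (length(profiles) != 4) stopf("exactly one profile per state is required")
  ids <- vapply(profiles, function(p) p$state_id, integer(1))
  if (!identical(sort(ids), 1:4)) stopf("profiles must cover states 1..4")
  profiles <- profiles[order(ids)]
  recs <- vector("list", config$n_subjects * config$n_sessions * 4L)
  k <- 0L
  with_seed(config$seed, {
    for (s in seq_len(config$n_subjects)) {
      subj_jit <- lapply(profiles, function(p)
        jitter_fractions(p$band_fractions, config$subject_sd))
      subj_amp <- exp(rnorm(1, 0, config$subject_amp_sd))
      subject_id <- sprintf("S%02d", s)
      for (sess in seq_len(config$n_sessions)) {
        sess_amp <- exp(rnorm(1, 0, config$session_amp_sd))
        for (task in 1:4) {
          p <- profiles[[task]]
          bf <- jitter_fractions(subj_jit[[task]], config$session_sd)
          p_eff <- state_profile(p$state_id, bf, p$noise_mix,
                                 p$amplitude_uV * subj_amp * sess_amp,
                                 p$region_gains)
          dat <- synthesize_state_signal(p_eff, length(config$channel_labels),
                                         config$task_duration_s, config$fs,
                                         config$channel_labels)
          k <- k + 1L
          recs[[k]] <- eeg_recording(dat, config$fs, config$channel_labels,
                                     subject_id, sess, task)
        }
      }
    }
  })
  recs
}

#' Inject transient high-amplitude artifacts
#'
#' Adds `n_spikes` Gaussian-shaped transients (width ~50 ms) of peak
#' amplitude `spike_amp_uV` at random positions, each on one random channel,
#' emulating the gross movement artifacts that bad-segment rejection must
#' remove. Spike positions are returned in the `"spikes"` attribute for test
#' assertions.
#'
#' @param recording an [eeg_recording].
#' @param spike_amp_uV peak amplitude of each spike (> 0).
#' @param n_spikes number of spikes (>= 0).
#' @param seed RNG seed for placement.
#' @return the recording with artifacts added; `attr(, "spikes")` is a
#'   data.frame with columns `channel` and `center_index`.
#' @export
inject_artifacts <- function(recording, spike_amp_uV = 500, n_spikes = 3, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!(spike_amp_uV > 0)) stopf("spike_amp_uV must be positive")
  if (!is_count(n_spikes) || n_spikes < 0) stopf("n_spikes must be a non-negative integer")
  out <- recording
  spikes <- data.frame(channel = integer(0), center_index = integer(0))
  if (n_spikes > 0) {
    n <- ncol(recording$data)
    half <- max(1L, round(0.025 * recording$fs))
    with_seed(seed, {
      centers <- sample.int(n - 2 * half, n_spikes) + half
      chans <- sample.int(nrow(recording$data), n_spikes, replace = TRUE)
      signs <- sample(c(-1, 1), n_spikes, replace = TRUE)
      for (i in seq_len(n_spikes)) {
        idx <- (centers[i] - half):(centers[i] + half)
        pulse <- spike_amp_uV * exp(-0.5 * ((idx - centers[i]) / (half / 2))^2)
        out$data[chans[i], idx] <- out$data[chans[i], idx] + signs[i] * pulse
      }
      spikes <- data.frame(channel = chans, center_index = centers)
    })
  }
  attr(out, "spikes") <- spikes
  out
}

#' Score a self-evaluation questionnaire response
#'
#' Each task's questionnaire has three questions with options A--E scored
#' 1--5. On the high-attention scale (tasks 1/2) a total above 12 matches
#' task 1 and 9--12 matches task 2; on the low-attention scale (tasks 3/4) a
#' total above 12 matches task 3 and 9--12 matches task 4. Totals below 9
#' match nothing and the recording is screened out.
#'
#' @param task_id the task the response refers to (1--4); selects the scale.
#' @param answers character vector of exactly three answers in `"A"`..`"E"`.
#' @return list with `total` (3--15) and `matched_task` (1--4 or `NA`).
#' @export
score_questionnaire <- function(task_id, answers) {
  if (!(task_id %in% 1:4)) stopf("task_id must be in 1..4")
  if (length(answers) != 3) stopf("exactly 3 answers are required, got %d", length(answers))
  sc <- match(toupper(answers), LETTERS[1:5])
  if (anyNA(sc)) stopf("answers must be in A..E")
  total <- sum(sc)
  high_scale <- task_id %in% 1:2
  matched <- if (total > 12) {
    if (high_scale) 1L else 3L
  } else if (total >= 9) {
    if (high_scale) 2L else 4L
  } else NA_integer_
  list(total = total, matched_task = matched)
}

#' Write a cohort to EDF files plus a TSV manifest
#'
#' @param cohort list of [eeg_recording] objects.
#' @param dir output directory (created if missing).
#' @return path of the written manifest (`manifest.tsv` with columns
#'   subject, session, task, file).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(r) {
    f <- sprintf("%s_ses%d_task%d.edf", r$subject_id, r$session_id, r$task_id)
    write_edf(r, file.path(dir, f))
    data.frame(subject = r$subject_id, session = r$session_id,
               task = r$task_id, file = f)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to `manifest.tsv`.
#' @return list of [eeg_recording] objects.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path, sep = "\t")
  lapply(seq_len(nrow(manifest)), function(i)
    read_edf(file.path(dirname(manifest_path), manifest$file[i])))
}
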