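test_that("make_cohort returns the full subject x session x task grid and is seed-deterministic", {
  cfg <- cohort_config(n_subjects = 2, n_sessions = 2, task_duration_s = 4, seed = 5)
  cohort <- make_cohort(cfg)
  expect_length(cohort, 16)
  meta <- data.frame(subject = sapply(cohort, `[[`, "subject_id"),
                     session = sapply(cohort, `[[`, "session_id"),
                     task = sapply(cohort, `[[`, "task_id"))
  expect_equal(nrow(unique(meta)), 16)
  expect_true(all(table(meta$subject) == 8))

  again <- make_cohort(cfg)
  expect_identical(cohort[[1]]$data, again[[1]]$data)
  expect_identical(cohort[[16]]$data, again[[16]]$data)

  other <- make_cohort(cohort_config(n_subjects = 2, n_sessions = 2,
                                     task_duration_s = 4, seed = 6))
  expect_false(identical(cohort[[1]]$data, other[[1]]$data))
  # different subjects differ within one cohort
  expect_false(identical(cohort[[1]]$data, cohort[[9]]$data))
})

test_that("synthesized signals have the configured shape, RMS and band placement", {
  p_alpha <- state_profile(1, c(delta = 0, theta = 0, alpha = 1, beta = 0),
                           noise_mix = 0, amplitude_uV = 10)
  x <- attnEEG:::with_seed(1, synthesize_state_signal(p_alpha, 2, 8, 512))
  expect_equal(dim(x), c(2, 8 * 512))
  expect_true(all(is.finite(x)))
  # >= 90% of spectral power inside 8-13 Hz (FFT oracle)
  expect_gte(oracle_fft_band_fraction(x[1, ], 512, 8, 13), 0.9)
  # RMS within 5% of the target
  expect_equal(sqrt(mean(x[1, ]^2)), 10, tolerance = 0.05)

  # region gains scale per-channel RMS
  p_g <- state_profile(2, c(delta = 0.25, theta = 0.25, alpha = 0.25, beta = 0.25),
                       noise_mix = 0.3, amplitude_uV = 20,
                       region_gains = c(A = 2, B = 0.5))
  xg <- attnEEG:::with_seed(2, synthesize_state_signal(p_g, 2, 8, 512, c("A", "B")))
  expect_equal(sqrt(mean(xg[1, ]^2)), 40, tolerance = 0.05)
  expect_equal(sqrt(mean(xg[2, ]^2)), 10, tolerance = 0.05)

  # 4 s at 512 Hz -> 2048 samples
  x4 <- attnEEG:::with_seed(3, synthesize_state_signal(p_alpha, 1, 4, 512))
  expect_equal(ncol(x4), 2048)

  bad <- p_alpha
  bad$band_fractions["alpha"] <- 2
  expect_error(do.call(state_profile, list(1, bad$band_fractions, 0, 10)), "sum to 1")
})

test_that("default profiles encode the attention band structure", {
  profs <- default_state_profiles()
  beta <- sapply(profs, function(p) p$band_fractions[["beta"]])
  slow <- sapply(profs, function(p) p$band_fractions[["theta"]] + p$band_fractions[["alpha"]])
  expect_true(all(diff(beta) < 0))   # beta strictly decreasing states 1 -> 4
  expect_true(all(diff(slow) > 0))   # theta + alpha strictly increasing
  expect_true(all(sapply(profs, function(p) abs(sum(p$band_fractions) - 1) < 1e-12)))
})

test_that("configured band fractions are recoverable from a long recording (Welch oracle)", {
  # the generator contract: measured fraction = (1 - noise_mix) * configured
  # + noise_mix * (1/f share of the band); invert it and compare.
  p <- default_state_profiles()[[1]]
  x <- attnEEG:::with_seed(9, synthesize_state_signal(p, 1, 300, 512))
  pink_share <- function(lo, hi) log(hi / lo) / log(30 / 0.5)
  for (band in c("beta", "alpha")) {
    e <- attnEEG:::BAND_EDGES[[band]]
    measured <- oracle_welch_band_fraction(x[1, ], 512, e[1], e[2])
    recovered <- (measured - p$noise_mix * pink_share(e[1], e[2])) / (1 - p$noise_mix)
    expect_equal(recovered, p$band_fractions[[band]], tolerance = 0.1)
  }
})

test_that("questionnaire scoring maps totals to tasks per the two scales", {
  expect_equal(score_questionnaire(1, c("E", "E", "E")),
               list(total = 15L, matched_task = 1L))
  expect_equal(score_questionnaire(2, c("C", "C", "C")),
               list(total = 9L, matched_task = 2L))
  expect_equal(score_questionnaire(1, c("A", "A", "A")),
               list(total = 3L, matched_task = NA_integer_))
  # low-attention scale: same totals map to tasks 3/4
  expect_equal(score_questionnaire(3, c("E", "E", "D"))$matched_task, 3L)
  expect_equal(score_questionnaire(4, c("C", "C", "D"))$matched_task, 4L)
  expect_equal(score_questionnaire(3, c("C", "C", "C"))$matched_task, 4L)
  expect_error(score_questionnaire(1, c("A", "B")), "3 answers")
  expect_error(score_questionnaire(1, c("A", "B", "F")), "A\\.\\.E")
})

test_that("inject_artifacts adds locatable spikes and n_spikes = 0 is the identity", {
  rec <- make_test_recording(duration_s = 8)
  same <- inject_artifacts(rec, 500, 0)
  expect_identical(same$data, rec$data)
  expect_equal(nrow(attr(same, "spikes")), 0)

  spiked <- inject_artifacts(rec, 500, 4, seed = 3)
  sp <- attr(spiked, "spikes")
  expect_equal(nrow(sp), 4)
  expect_true(all(sp$center_index >= 1 & sp$center_index <= ncol(rec$data)))
  for (i in seq_len(nrow(sp))) {
    expect_gt(abs(spiked$data[sp$channel[i], sp$center_index[i]]), 400)
  }
  expect_error(inject_artifacts(rec, -1, 1), "positive")
  expect_error(inject_artifacts(rec, 500, -1), "non-negative")
})
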