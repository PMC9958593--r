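test_that("time-domain features match the printed formulas on hand cases", {
  f <- time_domain_features(c(1, -1, 2, -2))
  expect_equal(unname(f["F1"]), 1.5)
  expect_equal(unname(f["F2"]), 2)
  expect_equal(unname(f["F3"]), 4)
  expect_equal(unname(f["F4"]), sqrt(2.5))
  expect_equal(unname(f["F5"]), sqrt(2.5))
  expect_equal(unname(f["F6"]), 2 / ((1 + 1 + sqrt(2) + sqrt(2)) / 4)^2)

  g <- time_domain_features(c(3, 3, 3, 3))
  expect_equal(unname(g), c(3, 3, 0, 3, 0, 1))

  expect_warning(z <- time_domain_features(c(0, 0, 0)), "all-zero")
  expect_true(is.na(z["F6"]))
  expect_equal(unname(z["F1"]), 0)
})

test_that("F4^2 = F5^2 + mean^2 identity holds under 1/N normalization", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(100, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
    f <- time_domain_features(x)
    expect_equal(f[["F4"]]^2, f[["F5"]]^2 + mean(x)^2, tolerance = 1e-9)
  }
})

test_that("sample entropy equals the brute-force oracle exactly on 50 random windows", {
  set.seed(11)
  params <- sampen_params()
  for (i in 1:50) {
    n <- sample(100:400, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                sin(2 * pi * 10 * (1:n) / 512) + rnorm(n, 0, runif(1, 0.05, 0.5)),
                cumsum(rnorm(n)))
    r <- params$r_factor * sd(x)
    expect_identical(unname(attnEEG:::.sampen_counts(x, params$m, r)),
                     unname(as.numeric(oracle_sampen_counts(x, params$m, r))))
  }
  # and at full epoch length
  x <- rnorm(2048)
  expect_equal(sample_entropy(x), oracle_sampen(x))
})

test_that("sample entropy edge cases behave as specified", {
  # near-constant signal with jitter far below r: every template matches -> 0
  x <- 5 + (1:300) * 1e-12 + rep(c(0, 1e-10), 150)
  expect_equal(sample_entropy(x), 0)
  expect_error(sample_entropy(rep(1, 100)), "zero-variance")
  expect_error(sample_entropy(rnorm(3)), "too short")
  # white noise is more complex than a pure rhythm at equal N, m, r
  set.seed(12)
  for (i in 1:20) {
    noise <- rnorm(512)
    tone <- sin(2 * pi * 10 * (1:512) / 512 + runif(1, 0, 2 * pi))
    expect_gt(sample_entropy(noise), sample_entropy(tone))
  }
})

test_that("wavelet-packet energies conserve signal energy and localize tones", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(2048)
    e <- wpd_leaf_energies(x, 7)
    expect_equal(sum(e), sum(x^2), tolerance = 1e-8)
  }
  fs <- 512
  t <- (0:2047) / fs
  # pure tones: ratios agree with the FFT band-power oracle within 0.1
  for (f0 in c(5, 10, 20, 25)) {
    br <- wpd_band_ratios(sin(2 * pi * f0 * t), fs)
    for (band in names(br)) {
      e <- wpd_params(fs)$bands[[band]]
      expect_lt(abs(br[[band]] - oracle_fft_band_fraction(sin(2 * pi * f0 * t), fs, e[1], e[2])),
                0.1)
    }
  }
  br10 <- wpd_band_ratios(sin(2 * pi * 10 * t), fs)
  expect_gte(br10[["alpha"]], 0.8)
  expect_equal(which.max(br10), c(alpha = 2))
  br20 <- wpd_band_ratios(sin(2 * pi * 20 * t), fs)
  expect_equal(which.max(br20), c(beta = 3))

  expect_error(wpd_band_ratios(rep(0, 2048), fs), "zero-energy")
  expect_error(wpd_leaf_energies(rnorm(100), 7), "divisible")
})

test_that("daubechies_filter reproduces the published db4 table and valid QMF pairs", {
  h4 <- daubechies_filter(4)
  expect_equal(h4, c(0.230377813308855, 0.714846570552542, 0.630880767929590,
                     -0.027983769416984, -0.187034811718881, 0.030841381835987,
                     0.032883011666983, -0.010597401784997), tolerance = 1e-12)
  for (p in c(2, 8, 12)) {
    h <- daubechies_filter(p)
    expect_length(h, 2 * p)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-10)
    expect_equal(sum(h^2), 1, tolerance = 1e-12)
  }
})

test_that("extract_features assembles a feature-major vector with correct structure", {
  rec <- make_test_recording(duration_s = 4)
  ep <- segment(rec)[[1]]
  v <- extract_features(ep)
  expect_length(v, 100)
  expect_identical(names(v)[1:10], paste0("F1_", ATTN_CHANNELS))
  expect_identical(names(v)[91:100], paste0("F10_", ATTN_CHANNELS))
  expect_equal(attr(v, "label"), 1L)
  # per-channel band-ratio invariants
  ratios <- v[grepl("^F(8|9|10)_", names(v))]
  expect_true(all(ratios >= 0 & ratios <= 1))
  per_ch <- v[paste0("F8_", ATTN_CHANNELS)] + v[paste0("F9_", ATTN_CHANNELS)] +
    v[paste0("F10_", ATTN_CHANNELS)]
  expect_true(all(per_ch <= 1 + 1e-12))

  # duplicating a channel duplicates its entries at the matching positions
  ep2 <- ep
  ep2$data <- ep$data[c(1, 1, 3), ]
  ep2$channel_labels <- c("Fp1", "Fp1b", "F3")
  rownames(ep2$data) <- ep2$channel_labels
  v2 <- extract_features(ep2)
  expect_length(v2, 30)
  for (f in paste0("F", 1:10)) {
    expect_identical(v2[[paste0(f, "_Fp1")]], v2[[paste0(f, "_Fp1b")]])
  }
})

test_that("amplitude scaling moves F1-F5 linearly and leaves F6-F10 invariant", {
  rec <- make_test_recording(duration_s = 4)
  ep <- segment(rec)[[1]]
  v1 <- extract_features(ep)
  ep_scaled <- ep
  ep_scaled$data <- ep$data * 3.7
  v2 <- extract_features(ep_scaled)
  for (f in paste0("F", 1:5)) {
    idx <- grepl(paste0("^", f, "_"), names(v1))
    expect_equal(unname(v2[idx]), unname(v1[idx]) * 3.7, tolerance = 1e-10)
  }
  for (f in paste0("F", 6:10)) {
    idx <- grepl(paste0("^", f, "_"), names(v1))
    expect_equal(unname(v2[idx]), unname(v1[idx]), tolerance = 1e-8)
  }
})
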