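test_that("framing yields the closed-form frame count and applies the window", {
  cfg <- stft_config()
  x <- withr::with_seed(1, stats::rnorm(5000))
  fr <- frame_signal(x, cfg)
  expect_equal(nrow(fr), 80L)            # floor((5000-240)/60)+1
  expect_equal(ncol(fr), 240L)

  # constant signal: every frame equals the Hanning window
  fr1 <- frame_signal(rep(1, 1000), cfg)
  w <- as.numeric(signal::hanning(240))
  for (i in c(1, nrow(fr1))) expect_equal(unname(fr1[i, ]), w)

  expect_equal(nrow(frame_signal(stats::rnorm(240), cfg)), 1L)
  expect_error(frame_signal(stats::rnorm(100), cfg), "shorter")

  # property: L = floor((N - W)/H) + 1 vs brute-force enumeration
  withr::with_seed(2, {
    for (i in 1:12) {
      W <- sample(16:64, 1); H <- sample(4:32, 1)
      N <- W + sample(0:500, 1)
      c2 <- stft_config(window_size = W, hop_length = H,
                        n_fft = 2^ceiling(log2(W)))
      got <- nrow(frame_signal(stats::rnorm(N), c2))
      brute <- 0L; s <- 1L
      while (s + W - 1L <= N) { brute <- brute + 1L; s <- s + H }
      expect_equal(got, brute)
    }
  })
})

test_that("STFT power spectrum localises tones and satisfies Parseval", {
  cfg <- stft_config()
  fs <- 2000
  # bin-exact tone: bin 32 of a 512-FFT at 2000 Hz -> 125 Hz
  f0_bin <- 32L
  x <- sin(2 * pi * (f0_bin * fs / cfg$n_fft) * (0:239) / fs)
  fr <- matrix(x * as.numeric(signal::hanning(240)), nrow = 1)
  ps <- stft_power(fr, cfg, fs)
  expect_equal(ncol(ps$values), 257L)
  peak <- which.max(ps$values[1, ]) - 1L
  expect_equal(peak, f0_bin)
  far <- ps$values[1, setdiff(seq_len(257), (f0_bin - 2):(f0_bin + 4))]
  expect_lt(max(far), max(ps$values) * 1e-3)

  # all-zero frames stay zero
  expect_true(all(stft_power(matrix(0, 3, 240), cfg, fs)$values == 0))

  # Parseval with the one-sided doubling convention
  frames <- frame_signal(withr::with_seed(3, stats::rnorm(2000)), cfg)
  ps2 <- stft_power(frames, cfg, fs)
  for (l in c(1L, 10L)) {
    onesided <- ps2$values[l, ]
    doubled <- onesided
    doubled[2:256] <- 2 * doubled[2:256]
    expect_equal(sum(doubled) / cfg$n_fft, sum(frames[l, ]^2),
                 tolerance = 1e-6)
  }
})

test_that("mel scale mapping agrees with an independent scalar oracle", {
  # closed form evaluated pointwise, independent of the vectorised code
  mel_scalar <- function(f) 2595 * log(1 + f / 700, base = 10)
  hz_scalar <- function(m) 700 * (exp(m / 2595 * log(10)) - 1)
  for (f in c(0, 25, 125.5, 440, 950, 1000)) {
    expect_equal(hz_to_mel(f), mel_scalar(f), tolerance = 1e-12)
    expect_lt(abs(mel_to_hz(mel_scalar(f)) - f), 1e-9)
    expect_lt(abs(hz_scalar(hz_to_mel(f)) - f), 1e-9)
  }
})

test_that("mel filterbank triangles are unimodal and cover the band", {
  fb <- build_mel_filterbank()
  expect_equal(dim(fb$weights), c(128L, 257L))
  expect_true(all(fb$weights >= 0))

  # unimodal rows: no second rise after the first fall
  for (m in c(1, 40, 128)) {
    row <- fb$weights[m, ]
    d <- diff(row[row > 0 | c(row[-1], 0) > 0])
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_lte(sign_changes, 1L)
  }

  # coverage: every interior bin within [f_low, f_high] touched
  bins <- (0:256) * 2000 / 512
  inside <- bins > fb$f_low + 5 & bins < fb$f_high - 5
  expect_true(all(colSums(fb$weights)[inside] > 0))

  # two-filter toy case partitions the range
  fb2 <- build_mel_filterbank(n_mels = 2L, f_low = 0, f_high = 1000)
  expect_equal(nrow(fb2$weights), 2L)
  expect_true(all(apply(fb2$weights, 1, max) > 0))

  expect_warning(build_mel_filterbank(n_mels = 256L), "share")
})

test_that("mel spectrum equals the brute-force weighted double loop", {
  withr::with_seed(4, {
    ps <- structure(list(values = matrix(stats::runif(5 * 257), 5, 257)),
                    class = "power_spectrogram")
    fb <- build_mel_filterbank(n_mels = 3L)
    got <- mel_spectrum(ps, fb)$values
    want <- matrix(0, 3, 5)
    for (m in 1:3) for (l in 1:5)
      want[m, l] <- sum(fb$weights[m, ] * ps$values[l, ])
    expect_equal(got, want, tolerance = 1e-12)

    # homogeneity
    ps2 <- ps; ps2$values <- 2 * ps$values
    expect_equal(mel_spectrum(ps2, fb)$values, 2 * got, tolerance = 1e-12)
    # zero in, zero out
    ps0 <- ps; ps0$values[] <- 0
    expect_true(all(mel_spectrum(ps0, fb)$values == 0))
  })
})

test_that("filterbank with unit column sums conserves in-band energy", {
  fb <- build_mel_filterbank()
  cs <- colSums(fb$weights)
  active <- cs > 0
  w_norm <- fb$weights
  w_norm[, active] <- sweep(fb$weights[, active, drop = FALSE], 2,
                            cs[active], "/")
  fbn <- fb; fbn$weights <- w_norm
  ps <- structure(
    list(values = withr::with_seed(5,
      matrix(stats::runif(10 * 257), 10, 257))),
    class = "power_spectrogram")
  total_mel <- sum(mel_spectrum(ps, fbn)$values)
  total_inband <- sum(ps$values[, active])
  expect_equal(total_mel, total_inband, tolerance = 1e-6)
})

test_that("log-mel transform floors, maps closed forms, preserves order", {
  fm <- structure(list(values = matrix(c(0, 1, exp(1), exp(2)), 2, 2),
                       flavor = "mel"), class = "feature_map")
  lm <- log_mel_spectrum(fm, epsilon = 1e-12)
  expect_equal(lm$values[1, 1], log(1e-12))
  expect_equal(lm$values[2, 1], 0, tolerance = 1e-9)
  expect_equal(lm$values[1, 2], 1, tolerance = 1e-9)
  expect_equal(lm$values[2, 2], 2, tolerance = 1e-9)
  # monotone: ordering preserved for random pairs
  withr::with_seed(6, {
    v <- matrix(stats::runif(20, 0, 5), 4, 5)
    fmv <- structure(list(values = v, flavor = "mel"),
                     class = "feature_map")
    lv <- log_mel_spectrum(fmv)$values
    expect_equal(order(v), order(lv))
  })
  expect_error(log_mel_spectrum(lm), "mel")
})

test_that("to_model_input reshapes, standardises and keeps monotone ramps", {
  # identity shape: unchanged before standardisation
  v <- withr::with_seed(7, matrix(stats::runif(128 * 128), 128, 128))
  fm <- structure(list(values = v, flavor = "mel"), class = "feature_map")
  out <- to_model_input(fm, standardize = FALSE)
  expect_equal(out$values, v)

  # constant 128 x 80 map -> all zeros after standardisation
  cm <- structure(list(values = matrix(3.7, 128, 80), flavor = "mel"),
                  class = "feature_map")
  z <- to_model_input(cm)
  expect_equal(dim(z$values), c(128L, 128L))
  expect_true(all(z$values == 0))

  # linear ramp stays monotone under interpolation, matches direct oracle
  ramp <- matrix(rep(seq(0, 1, length.out = 80), each = 128), 128, 80)
  rm_ <- structure(list(values = ramp, flavor = "mel"),
                   class = "feature_map")
  ri <- to_model_input(rm_, standardize = FALSE)
  expect_true(all(diff(ri$values[1, ]) > 0))
  oracle <- stats::approx(1:80, ramp[1, ],
                          xout = seq(1, 80, length.out = 128))$y
  expect_equal(unname(ri$values[64, ]), oracle, tolerance = 1e-12)

  # standardisation: zero mean, unit sd
  sfm <- to_model_input(fm)
  expect_lt(abs(mean(sfm$values)), 1e-12)
  expect_equal(stats::sd(as.numeric(sfm$values)), 1, tolerance = 1e-12)
})

test_that("feature chain is deterministic", {
  seg <- synth_clean_pcg(heart_sound_params(), 2.5, 2000, seed = 10)
  f1 <- segment_features(seg, "log_mel")
  f2 <- segment_features(seg, "log_mel")
  expect_identical(f1$values, f2$values)
})

test_that("log-mel channel shift is frame-constant; mel difference is not", {
  p <- heart_sound_params(murmur_present = TRUE, murmur_band = c(50, 900),
                          murmur_gain = 0.6)
  s <- synth_clean_pcg(p, duration = 5, fs = 2000, seed = 7)
  y <- acquire(s, noise_params(snr_db = Inf),
               channel_model("x", c(1, 0.4), "first-order smooth"), seed = 1)
  st <- logmel_shift_stats(s, y)
  expect_gt(nrow(st$bands), 100L)
  expect_lt(st$max_sd_ratio, 0.1)
  expect_gt(st$mel_diff_cv_median, 0.5)
})
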