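test_that("clean synthesis places S1 events at the heart rate", {
  p <- heart_sound_params(heart_rate_bpm = 60, hr_jitter_frac = 0,
                          s1_s2_interval_frac = 0.35)
  s <- synth_clean_pcg(p, duration = 5, fs = 2000, seed = 1)
  expect_equal(length(s$samples), 10000L)
  # count S1-band bursts: local maxima of the envelope spaced ~1 s
  env <- abs(s$samples)
  win <- 200L
  ste <- vapply(seq(1, 10000 - win, by = 50),
                function(i) sum(env[i:(i + win)]^2), numeric(1))
  thr <- 0.3 * max(ste)
  peaks <- which(ste > thr & c(FALSE, diff(ste) > 0) &
                   c(rev(diff(rev(ste))) > 0, FALSE))
  groups <- cumsum(c(1, diff(peaks) > 4))
  n_events <- length(unique(groups))
  expect_gte(n_events, 9L)   # 5 S1 + 5 S2 (last S2 may fall off the end)
  expect_lte(n_events, 10L)
})

test_that("murmur adds band power and determinism holds", {
  base <- heart_sound_params(murmur_present = FALSE)
  mur <- heart_sound_params(murmur_present = TRUE)
  s0 <- synth_clean_pcg(base, 5, 2000, seed = 3)
  s1 <- synth_clean_pcg(mur, 5, 2000, seed = 3)
  expect_gt(band_power(s1, c(150, 400)), band_power(s0, c(150, 400)))
  expect_identical(synth_clean_pcg(mur, 5, 2000, seed = 3)$samples,
                   s1$samples)
})

test_that("acquisition matches the brute-force convolution sum", {
  # identity channel, no noise: output equals input
  clean <- synth_clean_pcg(heart_sound_params(), 2, 2000, seed = 4)
  idn <- acquire(clean, noise_params(snr_db = Inf),
                 channel_model("d", 1), seed = 1)
  expect_equal(idn$samples, clean$samples, tolerance = 1e-12)

  # hand-computed toy case
  toy <- audio_recording(c(1, 0, 0), 10)
  y <- acquire(toy, noise_params(snr_db = Inf),
               channel_model("d", c(1, 1)), seed = 1)
  expect_equal(y$samples, c(1, 1, 0), tolerance = 1e-12)

  # random instances vs the double sum y[n] = sum_m x[m] h[n-m]
  withr::with_seed(5, {
    for (rep in 1:5) {
      x <- stats::rnorm(64); h <- stats::rnorm(8)
      got <- acquire(audio_recording(x, 100), noise_params(snr_db = Inf),
                     channel_model("d", h), seed = 1)$samples
      want <- numeric(64)
      for (n in 1:64) for (m in 1:n)
        if (n - m + 1 <= 8) want[n] <- want[n] + x[m] * h[n - m + 1]
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("realised SNR matches the requested level", {
  clean <- synth_clean_pcg(heart_sound_params(), 6, 2000, seed = 6)
  for (snr in c(10, 20)) {
    noisy <- acquire(clean, noise_params(snr_db = snr),
                     channel_model("d", 1), seed = 7)
    a <- noisy$samples - clean$samples
    realised <- 10 * log10(mean(clean$samples^2) / mean(a^2))
    expect_lt(abs(realised - snr), 0.5)
  }
})

test_that("cross-term between source and noise is small relative to powers", {
  # independence approximation: |mean of 2*S*A| << mean of S^2 + A^2,
  # accumulated over STFT cells and seeds
  clean <- synth_clean_pcg(heart_sound_params(murmur_present = TRUE),
                           3, 2000, seed = 8)
  scfg <- stft_config()
  S <- stats::mvfft(t(frame_signal(clean, scfg)))
  cross <- 0; power <- 0
  for (seed in 1:6) {
    a <- melpcg:::make_noise(length(clean$samples), 2000, "white",
                             NULL, seed) * 0.1
    A <- stats::mvfft(t(frame_signal(audio_recording(a, 2000), scfg)))
    cross <- cross + mean(2 * Re(S * Conj(A)))
    power <- power + mean(Mod(S)^2 + Mod(A)^2)
  }
  expect_lt(abs(cross) / power, 0.05)
})

test_that("domain channels are distinct, smooth and seeded", {
  chs <- make_domain_channels(6, seed = 9)
  expect_length(chs, 6L)
  expect_equal(names(chs), letters[1:6])
  freqs <- seq(25, 950, by = 25)
  mags <- sapply(chs, channel_magnitude, freqs = freqs)
  for (i in 1:5) for (j in (i + 1):6) {
    dmax <- max(abs(20 * log10(mags[, i] / mags[, j])))
    expect_gt(dmax, 1)
  }
  chs2 <- make_domain_channels(6, seed = 9)
  expect_identical(lapply(chs, `[[`, "impulse_response"),
                   lapply(chs2, `[[`, "impulse_response"))
  one <- make_domain_channels(1, seed = 1)
  expect_length(one, 1L)
  flat <- channel_magnitude(one[[1]], freqs)
  expect_lt(max(abs(20 * log10(flat / flat[1]))), 0.5)
})

test_that("dataset generation honours requested counts and reproduces", {
  counts <- data.frame(domain_id = "x", n_normal = 3L, n_abnormal = 2L)
  ch <- list(channel_model("x", 1))
  ds <- generate_dataset(dataset_spec(counts, seed = 10,
                                      record_seconds = 2), ch)
  expect_equal(nrow(ds$manifest), 5L)
  expect_equal(sum(ds$manifest$label == "normal"), 3L)
  expect_equal(sum(ds$manifest$label == "abnormal"), 2L)

  ds2 <- generate_dataset(dataset_spec(counts, seed = 10,
                                       record_seconds = 2), ch)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(lapply(ds$records, `[[`, "samples"),
                   lapply(ds2$records, `[[`, "samples"))
})

test_that("default six-domain structure mirrors the reference proportions", {
  counts <- default_domain_counts()
  expect_equal(counts$domain_id, letters[1:6])
  tot <- counts$n_normal + counts$n_abnormal
  prop_e <- tot[5] / sum(tot)
  expect_gt(prop_e, 0.60)
  expect_lt(prop_e, 0.72)
})

test_that("murmur band power separates the classes on clean sources", {
  withr::with_seed(11, {
    n <- 40L
    labs <- rep(c("normal", "abnormal"), each = n / 2)
    pw <- vapply(seq_len(n), function(i) {
      p <- heart_sound_params(
        heart_rate_bpm = stats::runif(1, 55, 95),
        murmur_present = labs[i] == "abnormal",
        murmur_gain = stats::runif(1, 0.25, 0.5))
      s <- synth_clean_pcg(p, 5, 2000, seed = 1000 + i)
      band_power(s, c(150, 400)) / mean(s$samples^2)
    }, numeric(1))
    # best single threshold on the murmur-band fraction
    ths <- sort(pw)
    acc <- vapply(ths, function(t)
      mean((pw > t) == (labs == "abnormal")), numeric(1))
    expect_gt(max(acc), 0.95)
  })
})
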