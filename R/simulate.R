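#' Heart-sound source parameters
#'
#' Parameters of the synthetic clean phonocardiogram source: a periodic
#' train of S1 and S2 valve-closure transients (Gaussian-enveloped
#' tones) with cycle-length jitter, optionally carrying a systolic
#' murmur (band-limited noise between S1 and S2), the abnormal-class
#' marker.
#'
#' @param heart_rate_bpm Heart rate in beats/min (30-200).
#' @param s1_freq,s2_freq Dominant frequencies of S1 and S2 in Hz.
#' @param s1_s2_interval_frac Position of S2 within the cycle, as a
#'   fraction of the cycle length.
#' @param transient_width_ms Gaussian envelope sigma of S1/S2 in ms.
#' @param murmur_present Logical; synthesise a systolic murmur.
#' @param murmur_band Murmur frequency band `(low, high)` in Hz.
#' @param murmur_gain Murmur amplitude relative to S1 (>= 0).
#' @param hr_jitter_frac Per-cycle uniform jitter of the cycle length,
#'   as a fraction.
#' @return A `heart_sound_params` list.
#' @export
heart_sound_params <- function(heart_rate_bpm = 70, s1_freq = 50,
                               s2_freq = 85, s1_s2_interval_frac = 0.35,
                               transient_width_ms = 20,
                               murmur_present = FALSE,
                               murmur_band = c(150, 400),
                               murmur_gain = 0.35,
                               hr_jitter_frac = 0.05) {
  if (heart_rate_bpm < 30 || heart_rate_bpm > 200)
    stop("heart_sound_params: heart_rate_bpm must be in [30, 200]")
  if (murmur_gain < 0) stop("heart_sound_params: murmur_gain must be >= 0")
  if (murmur_band[1] <= 0 || murmur_band[1] >= murmur_band[2])
    stop("heart_sound_params: murmur_band must satisfy 0 < low < high")
  structure(as.list(environment()), class = "heart_sound_params")
}

#' Additive-noise parameters
#'
#' Background noise added to the source before the stethoscope channel:
#' ambient sound, breathing, sensor-skin friction. Characterised by a
#' signal-to-noise ratio and a spectral shape.
#'
#' @param snr_db Signal-to-noise ratio in dB (clean signal power over
#'   noise power, measured before the channel). `Inf` disables noise.
#' @param noise_kind `"white"`, `"pink"` or `"band_limited"`.
#' @param band Passband in Hz for `"band_limited"` noise.
#' @return A `noise_params` list.
#' @export
noise_params <- function(snr_db = 20, noise_kind = c("white", "pink",
                                                     "band_limited"),
                         band = c(100, 500)) {
  noise_kind <- match.arg(noise_kind)
  if (is.na(snr_db)) stop("noise_params: snr_db must not be NA")
  structure(list(snr_db = snr_db, noise_kind = noise_kind, band = band),
            class = "noise_params")
}

#' Stethoscope channel model
#'
#' A finite impulse response standing for the acquisition device's
#' coloration; the simulator convolves the noisy source with it.
#'
#' @param domain_id Domain identifier this channel belongs to.
#' @param impulse_response Finite, not-all-zero numeric vector.
#' @param description Free-text description.
#' @return A `channel_model` list.
#' @export
channel_model <- function(domain_id, impulse_response, description = "") {
  impulse_response <- as.numeric(impulse_response)
  if (!all(is.finite(impulse_response)) || all(impulse_response == 0))
    stop("channel_model: impulse response must be finite and not all zero")
  structure(list(domain_id = domain_id, impulse_response = impulse_response,
                 description = description),
            class = "channel_model")
}

#' Synthesise a clean phonocardiogram
#'
#' Deterministic (per seed) clean heart-sound source: S1 and S2
#' transients as Gaussian-enveloped sinusoids placed on a jittered
#' cycle grid; abnormal sources additionally carry a band-limited
#' noise murmur spanning the S1-S2 interval.
#'
#' @param params A [heart_sound_params()].
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return An [audio_recording()] (label/domain unset).
#' @export
synth_clean_pcg <- function(params = heart_sound_params(), duration = 5,
                            fs = 2000, seed = 1L) {
  n <- round(duration * fs)
  withr::with_seed(seed, {
    x <- numeric(n)
    t_axis <- (seq_len(n) - 1L) / fs
    base_cycle <- 60 / params$heart_rate_bpm
    sigma <- params$transient_width_ms / 1000
    place_tone <- function(x, t0, freq, amp) {
      i0 <- max(1L, floor((t0 - 4 * sigma) * fs) + 1L)
      i1 <- min(n, ceiling((t0 + 4 * sigma) * fs) + 1L)
      if (i0 > n || i1 < 1L) return(x)
      tt <- t_axis[i0:i1]
      x[i0:i1] <- x[i0:i1] +
        amp * exp(-(tt - t0)^2 / (2 * sigma^2)) *
        sin(2 * pi * freq * (tt - t0))
      x
    }
    if (params$murmur_present) {
      bf <- signal::butter(2, params$murmur_band / (fs / 2), type = "pass")
    }
    t0 <- 0
    while (t0 < duration) {
      cyc <- base_cycle *
        (1 + params$hr_jitter_frac * stats::runif(1, -1, 1))
      x <- place_tone(x, t0, params$s1_freq, 1.0)
      t_s2 <- t0 + params$s1_s2_interval_frac * cyc
      x <- place_tone(x, t_s2, params$s2_freq, 0.8)
      if (params$murmur_present) {
        m0 <- t0 + 3 * sigma
        m1 <- t_s2 - 3 * sigma
        if (m1 > m0) {
          i0 <- max(1L, floor(m0 * fs) + 1L)
          i1 <- min(n, ceiling(m1 * fs))
          if (i1 > i0 + 8L) {
            len <- i1 - i0 + 1L
            burst <- signal::filtfilt(bf, stats::rnorm(len))
            env <- as.numeric(signal::hanning(len))
            rms <- sqrt(mean(burst^2))
            if (rms > 0)
              x[i0:i1] <- x[i0:i1] +
                params$murmur_gain * env * burst / (rms * 2)
          }
        }
      }
      t0 <- t0 + cyc
    }
    audio_recording(x, fs)
  })
}

# seeded noise generator at unit RMS
make_noise <- function(n, fs, kind, band, seed) {
  withr::with_seed(seed, {
    w <- stats::rnorm(n)
    x <- switch(kind,
      white = w,
      pink = {
        # 1/f amplitude shaping in the frequency domain
        spec <- stats::fft(w)
        f <- c(1, seq_len(n - 1L))
        f <- pmin(f, n - f + 1)
        shaped <- spec / sqrt(f)
        Re(stats::fft(shaped, inverse = TRUE)) / n
      },
      band_limited = {
        bf <- signal::butter(2, band / (fs / 2), type = "pass")
        signal::filtfilt(bf, w)
      })
    x / sqrt(mean(x^2))
  })
}

#' Simulate acquisition of a heart sound
#'
#' The cardiac-sound collection model: the clean source plus additive
#' background noise at the requested SNR, convolved with the
#' stethoscope impulse response, truncated to the input length (add
#' first, then convolve).
#'
#' @param clean Clean source [audio_recording()].
#' @param noise A [noise_params()].
#' @param channel A [channel_model()] whose impulse response is shorter
#'   than the signal.
#' @param seed Integer seed for the noise realisation.
#' @return The acquired [audio_recording()] (same length and metadata
#'   as `clean`).
#' @export
acquire <- function(clean, noise = noise_params(), channel, seed = 1L) {
  n <- length(clean$samples)
  h <- channel$impulse_response
  if (length(h) >= n)
    stop("acquire: channel impulse response must be shorter than the signal")
  x <- clean$samples
  if (is.finite(noise$snr_db)) {
    a <- make_noise(n, clean$fs, noise$noise_kind, noise$band, seed)
    a <- a * sqrt(mean(x^2)) * 10^(-noise$snr_db / 20)
    x <- x + a
  }
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  out <- replace_samples(clean, y)
  out$domain_id <- channel$domain_id
  out
}

#' Generate a set of per-domain stethoscope channels
#'
#' One channel per acquisition domain, pairwise distinct in magnitude
#' response: the first is a near-flat reference; the others combine a
#' spectral tilt spread across +/- `tilt_db_range` dB over the 25-950
#' Hz band with a mild random resonance. Responses are built as
#' 64-tap linear-phase FIRs from a smooth target magnitude and are
#' deterministic per seed.
#'
#' @param n_domains Number of domains (>= 1).
#' @param seed Integer seed.
#' @param fs Sampling rate the channels are designed for.
#' @param tilt_db_range Half-range of the tilt in dB.
#' @param n_taps FIR length.
#' @return A list of [channel_model()]s named by domain id (`"a"`,
#'   `"b"`, ...).
#' @export
make_domain_channels <- function(n_domains, seed = 1L, fs = 2000,
                                 tilt_db_range = 6, n_taps = 64L) {
  if (n_domains < 1L) stop("make_domain_channels: n_domains must be >= 1")
  ids <- letters[seq_len(n_domains)]
  withr::with_seed(seed, {
    out <- vector("list", n_domains)
    tilts <- if (n_domains > 1L)
      seq(-tilt_db_range, tilt_db_range, length.out = n_domains - 1L)
    else numeric(0)
    for (i in seq_len(n_domains)) {
      if (i == 1L) {
        out[[i]] <- channel_model(ids[i], 1, "near-flat reference channel")
        next
      }
      tilt <- tilts[i - 1L] + stats::runif(1, -0.5, 0.5)
      f_res <- stats::runif(1, 100, 700)
      g_res <- stats::runif(1, 2, 6) * sample(c(-1, 1), 1L)
      bw <- stats::runif(1, 60, 150)
      h <- fir_from_magnitude(fs, n_taps, function(f) {
        tilt_db <- tilt * (f - 487.5) / 925
        res_db <- g_res * exp(-((f - f_res) / bw)^2 / 2)
        10^((tilt_db + res_db) / 20)
      })
      out[[i]] <- channel_model(
        ids[i], h,
        sprintf("tilt %+0.1f dB across band, %+0.1f dB resonance at %.0f Hz",
                tilt, g_res, f_res))
    }
    names(out) <- ids
    out
  })
}

# Linear-phase FIR whose magnitude approximates mag_fun(f); built by
# frequency sampling: symmetric magnitude, inverse FFT, centre, window.
fir_from_magnitude <- function(fs, n_taps, mag_fun) {
  n_fft <- 1024L
  f <- (0:(n_fft / 2)) * fs / n_fft
  mag <- mag_fun(f)
  full <- c(mag, rev(mag[2:(n_fft / 2)]))
  h_long <- Re(stats::fft(full, inverse = TRUE)) / n_fft
  h <- c(h_long[(n_fft - n_taps / 2 + 1L):n_fft], h_long[1:(n_taps / 2)])
  h * as.numeric(signal::hanning(n_taps))
}

#' Magnitude response of a channel
#'
#' @param channel A [channel_model()].
#' @param freqs Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector `|H(f)|`.
#' @export
channel_magnitude <- function(channel, freqs, fs = 2000) {
  h <- channel$impulse_response
  k <- seq_along(h) - 1L
  vapply(freqs, function(f)
    Mod(sum(h * exp(-2i * pi * f * k / fs))), numeric(1))
}

#' Dataset specification
#'
#' Per-domain record counts and global synthesis settings for
#' [generate_dataset()]. The default emulates the structure of the six
#' public challenge sub-datasets at 1/20 scale: very unequal domain
#' sizes (domain e holds about two thirds of all records) and unequal
#' class balance within domains.
#'
#' @param domains Data frame with columns `domain_id`, `n_normal`,
#'   `n_abnormal`.
#' @param seed Master seed; every record's synthesis is derived from it.
#' @param fs Sampling rate in Hz.
#' @param record_seconds Length of each recording in seconds.
#' @param snr_db Additive-noise SNR in dB applied to every record.
#' @param noise_kind Additive-noise spectral shape (see
#'   [noise_params()]).
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(domains = default_domain_counts(), seed = 1L,
                         fs = 2000, record_seconds = 5, snr_db = 20,
                         noise_kind = "white") {
  need <- c("domain_id", "n_normal", "n_abnormal")
  if (!all(need %in% names(domains)))
    stop("dataset_spec: domains needs columns ", paste(need, collapse = ", "))
  if (any(domains$n_normal < 0 | domains$n_abnormal < 0))
    stop("dataset_spec: counts must be >= 0")
  structure(list(domains = domains, seed = as.integer(seed), fs = fs,
                 record_seconds = record_seconds, snr_db = snr_db,
                 noise_kind = noise_kind),
            class = "dataset_spec")
}

#' Default six-domain record counts
#'
#' The six-domain structure of the public heart-sound challenge
#' (normal/abnormal recordings per acquisition-device sub-dataset),
#' scaled down; with `scale = 1/20` (default) this yields 162 records
#' of which domain e holds 66%.
#'
#' @param scale Multiplier applied to the full-size counts (rounded,
#'   minimum 1 per non-empty cell).
#' @return Data frame with `domain_id`, `n_normal`, `n_abnormal`.
#' @export
default_domain_counts <- function(scale = 1 / 20) {
  full_normal <- c(a = 117, b = 386, c = 7, d = 27, e = 1958, f = 80)
  full_abnormal <- c(a = 292, b = 104, c = 24, d = 28, e = 183, f = 34)
  data.frame(domain_id = names(full_normal),
             n_normal = pmax(1L, as.integer(round(full_normal * scale))),
             n_abnormal = pmax(1L, as.integer(round(full_abnormal * scale))),
             stringsAsFactors = FALSE)
}

#' Generate a labelled multi-domain dataset
#'
#' For every domain, synthesises the requested numbers of normal and
#' abnormal recordings with per-record randomised source parameters
#' (abnormal records carry a murmur), passes each through the domain's
#' channel with additive noise, and assembles a manifest. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [dataset_spec()].
#' @param channels List of [channel_model()]s, one per domain (named or
#'   ordered as `spec$domains$domain_id`).
#' @param out_dir If non-`NULL`, WAV files and `manifest.csv` are
#'   written there.
#' @return List with `records` (list of [audio_recording()]) and
#'   `manifest` (data frame `record_id`, `path`, `label`, `domain_id`).
#' @export
generate_dataset <- function(spec, channels, out_dir = NULL) {
  dom <- spec$domains
  ids <- dom$domain_id
  ch_ids <- vapply(channels, `[[`, character(1), "domain_id")
  if (!all(ids %in% ch_ids))
    stop("generate_dataset: missing channels for domains: ",
         paste(setdiff(ids, ch_ids), collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  plan <- do.call(rbind, lapply(seq_len(nrow(dom)), function(i) {
    data.frame(domain_id = dom$domain_id[i],
               label = rep(c("normal", "abnormal"),
                           c(dom$n_normal[i], dom$n_abnormal[i])),
               stringsAsFactors = FALSE)
  }))
  n_rec <- nrow(plan)

  records <- withr::with_seed(spec$seed, {
    rec_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_rec)
    hr <- stats::runif(n_rec, 55, 95)
    s1 <- stats::runif(n_rec, 40, 60)
    s2 <- stats::runif(n_rec, 75, 95)
    gain <- stats::runif(n_rec, 0.25, 0.5)
    lapply(seq_len(n_rec), function(i) {
      p <- heart_sound_params(
        heart_rate_bpm = hr[i], s1_freq = s1[i], s2_freq = s2[i],
        murmur_present = plan$label[i] == "abnormal",
        murmur_gain = gain[i])
      clean <- synth_clean_pcg(p, duration = spec$record_seconds,
                               fs = spec$fs, seed = rec_seeds[2L * i - 1L])
      ch <- channels[[match(plan$domain_id[i], ch_ids)]]
      y <- acquire(clean,
                   noise_params(snr_db = spec$snr_db,
                                noise_kind = spec$noise_kind),
                   ch, seed = rec_seeds[2L * i])
      # normalise to a safe recording level so PCM16 export is lossless
      peak <- max(abs(y$samples))
      if (peak > 0) y$samples <- y$samples * (0.9 / max(peak, 0.9))
      y$label <- plan$label[i]
      y$record_id <- sprintf("%s_%03d_%s", plan$domain_id[i], i,
                             substr(plan$label[i], 1, 3))
      y
    })
  })

  manifest <- data.frame(
    record_id = vapply(records, `[[`, character(1), "record_id"),
    path = NA_character_,
    label = plan$label,
    domain_id = plan$domain_id,
    stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    manifest$path <- file.path(out_dir,
                               paste0(manifest$record_id, ".wav"))
    for (i in seq_len(n_rec)) write_wav(records[[i]], manifest$path[i])
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(records = records, manifest = manifest)
}

#' Band power of a recording
#'
#' Mean power in a frequency band, from the FFT of the whole signal.
#' A threshold on the murmur-band power separates the synthetic
#' classes, which is what makes the classification task learnable.
#'
#' @param rec An [audio_recording()].
#' @param band `(low, high)` in Hz.
#' @return Mean power (amplitude^2) attributable to the band.
#' @export
band_power <- function(rec, band) {
  n <- length(rec$samples)
  spec <- Mod(stats::fft(rec$samples))^2 / n^2
  f <- (seq_len(n) - 1L) * rec$fs / n
  sel <- f >= band[1] & f <= band[2]
  2 * sum(spec[sel])
}
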