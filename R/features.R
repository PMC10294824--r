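#' STFT configuration
#'
#' Framing and FFT parameters for the short-time Fourier transform:
#' 240-sample Hanning windows hopped by 60 samples and zero-padded to a
#' 512-point FFT (at 2000 Hz that is 120 ms windows with 30 ms hops).
#'
#' @param window_size Frame length in samples.
#' @param hop_length Samples between consecutive frame starts.
#' @param n_fft FFT length (>= `window_size`; frames are zero-padded).
#' @param window_function Currently only `"hanning"`.
#' @return An `stft_config` list.
#' @export
stft_config <- function(window_size = 240L, hop_length = 60L, n_fft = 512L,
                        window_function = "hanning") {
  if (window_size > n_fft)
    stop("stft_config: window_size must be <= n_fft")
  if (hop_length < 1L)
    stop("stft_config: hop_length must be >= 1")
  if (!identical(window_function, "hanning"))
    stop("stft_config: only the Hanning window is supported")
  structure(list(window_size = as.integer(window_size),
                 hop_length = as.integer(hop_length),
                 n_fft = as.integer(n_fft),
                 window_function = window_function),
            class = "stft_config")
}

#' Slice a signal into windowed frames
#'
#' Produces `L = floor((N - window_size) / hop_length) + 1` frames, each
#' multiplied elementwise by a Hanning window.
#'
#' @param segment An [audio_recording()] or numeric vector with at least
#'   `window_size` samples.
#' @param cfg An [stft_config()].
#' @return An `L x window_size` numeric matrix.
#' @export
frame_signal <- function(segment, cfg = stft_config()) {
  x <- if (inherits(segment, "audio_recording")) segment$samples
       else as.numeric(segment)
  n <- length(x)
  if (n < cfg$window_size)
    stop("frame_signal: signal (", n, ") shorter than one window (",
         cfg$window_size, ")")
  L <- (n - cfg$window_size) %/% cfg$hop_length + 1L
  w <- as.numeric(signal::hanning(cfg$window_size))
  starts <- (seq_len(L) - 1L) * cfg$hop_length
  idx <- outer(starts, seq_len(cfg$window_size), `+`)
  frames <- matrix(x[idx], nrow = L)
  sweep(frames, 2L, w, `*`)
}

#' Power spectrogram of windowed frames
#'
#' Periodogram-style power spectrum per frame: each row is zero-padded
#' to `n_fft`, Fourier transformed, and the squared magnitude of the
#' one-sided spectrum (`K = n_fft/2 + 1` bins) is kept. No `1/N`
#' normalisation is applied; the global scale is immaterial downstream
#' because log-Mel differences and the final per-map standardisation
#' are scale-free.
#'
#' @param frames Windowed frame matrix from [frame_signal()].
#' @param cfg An [stft_config()].
#' @param fs Sampling rate in Hz (for the time/frequency axes).
#' @return A `power_spectrogram`: list with `values` (L x K, power),
#'   `frame_times` (s, frame centres) and `bin_freqs` (Hz).
#' @export
stft_power <- function(frames, cfg = stft_config(), fs = 2000) {
  L <- nrow(frames)
  K <- cfg$n_fft %/% 2L + 1L
  padded <- matrix(0, nrow = cfg$n_fft, ncol = L)
  padded[seq_len(ncol(frames)), ] <- t(frames)
  spec <- stats::mvfft(padded)
  values <- t(Mod(spec[seq_len(K), , drop = FALSE])^2)
  structure(
    list(values = values,
         frame_times = ((seq_len(L) - 1L) * cfg$hop_length +
                          cfg$window_size / 2) / fs,
         bin_freqs = (seq_len(K) - 1L) * fs / cfg$n_fft),
    class = "power_spectrogram")
}

#' Hz to Mel and back
#'
#' The standard Mel warping `mel = 2595 * log10(1 + f / 700)` and its
#' inverse.
#'
#' @param f Frequency in Hz.
#' @param m Frequency in Mel.
#' @return The converted frequency.
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filterbank
#'
#' Builds `n_mels` triangular filters whose centres are equally spaced
#' on the Mel scale between `f_low` and `f_high`. Filter `m` rises
#' linearly from centre `m - 1`, peaks at its own centre and falls to
#' centre `m + 1`, evaluated at the FFT bin frequencies.
#'
#' @param n_mels Number of filters.
#' @param f_low,f_high Frequency span in Hz (defaults match the 25-950
#'   Hz Butterworth passband).
#' @param n_fft FFT length the filterbank will be applied to.
#' @param fs Sampling rate in Hz.
#' @return A `mel_filterbank`: list with `weights` (n_mels x K),
#'   `center_freqs` (Hz), and the construction parameters.
#' @export
build_mel_filterbank <- function(n_mels = 128L, f_low = 25, f_high = 950,
                                 n_fft = 512L, fs = 2000) {
  if (f_high > fs / 2)
    stop("build_mel_filterbank: f_high must be <= fs/2")
  K <- n_fft %/% 2L + 1L
  bin_freqs <- (seq_len(K) - 1L) * fs / n_fft
  mel_pts <- seq(hz_to_mel(f_low), hz_to_mel(f_high), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)

  bin_of <- findInterval(hz_pts, bin_freqs)
  if (any(diff(bin_of[2:(n_mels + 1L)]) == 0L))
    warning("build_mel_filterbank: adjacent filter centres share an FFT bin; ",
            "n_mels is large for this frequency resolution")

  weights <- matrix(0, nrow = n_mels, ncol = K)
  for (m in seq_len(n_mels)) {
    f_l <- hz_pts[m]; f_c <- hz_pts[m + 1L]; f_r <- hz_pts[m + 2L]
    up <- (bin_freqs - f_l) / (f_c - f_l)
    down <- (f_r - bin_freqs) / (f_r - f_c)
    weights[m, ] <- pmax(0, pmin(up, down))
  }
  structure(
    list(weights = weights, center_freqs = hz_pts[2:(n_mels + 1L)],
         n_mels = as.integer(n_mels), f_low = f_low, f_high = f_high,
         n_fft = as.integer(n_fft), fs = fs,
         mel_scale = "2595*log10(1 + f/700)"),
    class = "mel_filterbank")
}

#' MelSpectrum of a power spectrogram
#'
#' Applies the triangular filterbank to each frame's power spectrum:
#' `values[m, l] = sum_k weights[m, k] * power[l, k]`. This is the
#' filterbank output energy ("MelSpectrum"); under the acquisition
#' model a stethoscope channel acts multiplicatively on these values.
#'
#' @param ps A [stft_power()] spectrogram.
#' @param fb A [build_mel_filterbank()] filterbank.
#' @return A `feature_map` with `values` (n_mels x L) and flavor
#'   `"mel"`.
#' @export
mel_spectrum <- function(ps, fb) {
  if (ncol(fb$weights) != ncol(ps$values))
    stop("mel_spectrum: filterbank has ", ncol(fb$weights),
         " bins but spectrogram has ", ncol(ps$values))
  structure(
    list(values = fb$weights %*% t(ps$values), flavor = "mel",
         epsilon = NA_real_),
    class = "feature_map")
}

#' Log-MelSpectrum
#'
#' Elementwise natural logarithm of the MelSpectrum (with a small
#' floor `epsilon` keeping silent bands finite). In the log domain a
#' convolutive channel becomes, band by band, an additive offset that
#' is constant across frames -- the property that makes this flavor
#' robust to acquisition-device differences.
#'
#' @param mel A `feature_map` of flavor `"mel"`.
#' @param epsilon Positive floor added before the log. Default:
#'   `1e-10 * max(values)` (or `1e-300` for an all-zero map).
#' @return A `feature_map` of flavor `"log_mel"`.
#' @export
log_mel_spectrum <- function(mel, epsilon = NULL) {
  if (!identical(mel$flavor, "mel"))
    stop("log_mel_spectrum: input must be a 'mel' feature map")
  if (is.null(epsilon)) {
    mx <- max(mel$values)
    epsilon <- if (mx > 0) 1e-10 * mx else 1e-300
  }
  if (epsilon <= 0) stop("log_mel_spectrum: epsilon must be positive")
  structure(
    list(values = log(mel$values + epsilon), flavor = "log_mel",
         epsilon = epsilon),
    class = "feature_map")
}

#' Shape a feature map for the classifier
#'
#' Maps the time axis to a fixed number of columns (by linear
#' interpolation, default, or by right-padding with the flavor's floor
#' value) and then standardises the map to zero mean and unit variance.
#' The frequency axis (rows) is left untouched.
#'
#' @param fm A `feature_map`.
#' @param target_frames Number of output columns (128 for the default
#'   classifier input of 128 x 128).
#' @param mode `"interpolate"` or `"pad"`.
#' @param standardize Standardise after reshaping (default `TRUE`).
#' @return A `feature_map` with `values` of size n_mels x
#'   `target_frames`.
#' @export
to_model_input <- function(fm, target_frames = 128L,
                           mode = c("interpolate", "pad"),
                           standardize = TRUE) {
  mode <- match.arg(mode)
  v <- fm$values
  L <- ncol(v)
  if (L != target_frames) {
    if (mode == "interpolate") {
      if (L == 1L) {
        v <- v[, rep(1L, target_frames), drop = FALSE]
      } else {
        xout <- seq(1, L, length.out = target_frames)
        v <- t(apply(v, 1L, function(r) stats::approx(seq_len(L), r,
                                                      xout = xout)$y))
      }
    } else {
      floor_val <- if (identical(fm$flavor, "log_mel"))
        log(fm$epsilon) else 0
      if (L > target_frames) {
        v <- v[, seq_len(target_frames), drop = FALSE]
      } else {
        v <- cbind(v, matrix(floor_val, nrow = nrow(v),
                             ncol = target_frames - L))
      }
    }
  }
  if (standardize) {
    s <- stats::sd(as.numeric(v))
    v <- if (s > 0) (v - mean(v)) / s else v * 0
  }
  fm$values <- v
  fm
}

#' Segment to model-ready feature map
#'
#' Convenience chain: frame, STFT power, Mel filterbank, optional log,
#' reshape and standardise.
#'
#' @param segment A preprocessed fixed-length [audio_recording()].
#' @param flavor `"mel"` or `"log_mel"`.
#' @param scfg An [stft_config()].
#' @param fb A [build_mel_filterbank()]; built from defaults if `NULL`.
#' @param target_frames Output columns (see [to_model_input()]).
#' @param ... Passed to [to_model_input()].
#' @return A standardised `feature_map` of the requested flavor.
#' @export
segment_features <- function(segment, flavor = c("log_mel", "mel"),
                             scfg = stft_config(), fb = NULL,
                             target_frames = 128L, ...) {
  flavor <- match.arg(flavor)
  if (is.null(fb))
    fb <- build_mel_filterbank(n_fft = scfg$n_fft, fs = segment$fs)
  ps <- stft_power(frame_signal(segment, scfg), scfg, fs = segment$fs)
  fm <- mel_spectrum(ps, fb)
  if (flavor == "log_mel") fm <- log_mel_spectrum(fm)
  to_model_input(fm, target_frames = target_frames, ...)
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %s: %d mel bands x %d frames\n",
              x$flavor, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Frame-constancy of the log-Mel channel shift
#'
#' Quantifies the additive-shift property: for a clean signal `s` and
#' the same signal passed through an LTI channel, the difference of
#' their log-Mel maps should be, in every Mel band, (approximately)
#' constant across frames -- the channel's log-magnitude in that band.
#' By contrast the Mel-domain difference scales with the frame energy
#' and is far from frame-constant for a non-stationary signal.
#'
#' For each band, frames whose clean Mel value falls below
#' `silence_frac` of that band's maximum are discarded (there the
#' epsilon floor or spectral leakage dominates and the shift carries no
#' channel information); STFT edge frames are dropped too. The headline
#' constancy statistic compares each band's frame-wise SD of the shift
#' with the grand mean absolute shift, which stays meaningful in bands
#' where the channel's log-magnitude crosses zero.
#'
#' @param clean,channeled [audio_recording()]s of equal length and rate
#'   (the latter the channel-filtered version of the former).
#' @param scfg An [stft_config()].
#' @param fb Optional [build_mel_filterbank()].
#' @param silence_frac Band-relative non-silence threshold.
#' @param min_frames Minimum retained frames for a band to be reported.
#' @return A list: `bands`, a data.frame with one row per retained band
#'   (`band`, `n_frames`, `mean_shift`, `sd_shift`, `cv`,
#'   `mel_diff_cv`); `mean_abs_shift`, the grand mean of `|shift|`;
#'   `max_sd_ratio`, `max(sd_shift) / mean_abs_shift` (the additive-
#'   shift property asks for < 0.1); and `mel_diff_cv_median`, the
#'   median frame-variation of the Mel-domain difference (large when
#'   the channel acts multiplicatively).
#' @export
logmel_shift_stats <- function(clean, channeled, scfg = stft_config(),
                               fb = NULL, silence_frac = 0.01,
                               min_frames = 8L) {
  if (is.null(fb))
    fb <- build_mel_filterbank(n_fft = scfg$n_fft, fs = clean$fs)
  mel_of <- function(rec) {
    ps <- stft_power(frame_signal(rec, scfg), scfg, fs = rec$fs)
    mel_spectrum(ps, fb)$values
  }
  m_s <- mel_of(clean)
  m_y <- mel_of(channeled)
  eps <- 1e-10 * max(m_s, m_y)
  L <- ncol(m_s)
  keep_frames <- 3:(L - 2L)   # STFT edge transients
  rows <- lapply(seq_len(nrow(m_s)), function(m) {
    v <- m_s[m, keep_frames]
    fr <- keep_frames[v >= silence_frac * max(v)]
    if (length(fr) < min_frames) return(NULL)
    shift <- log(m_y[m, fr] + eps) - log(m_s[m, fr] + eps)
    mel_diff <- m_y[m, fr] - m_s[m, fr]
    data.frame(band = m, n_frames = length(fr),
               mean_shift = mean(shift), sd_shift = stats::sd(shift),
               cv = stats::sd(shift) /
                 max(abs(mean(shift)), .Machine$double.eps),
               mel_diff_cv = stats::sd(mel_diff) /
                 max(abs(mean(mel_diff)), .Machine$double.eps))
  })
  bands <- do.call(rbind, rows)
  if (is.null(bands)) stop("logmel_shift_stats: no band retained")
  mean_abs <- mean(abs(bands$mean_shift))
  list(bands = bands,
       mean_abs_shift = mean_abs,
       max_sd_ratio = max(bands$sd_shift) / mean_abs,
       mel_diff_cv_median = stats::median(bands$mel_diff_cv))
}
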