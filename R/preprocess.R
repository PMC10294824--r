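#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain applied to every recording
#' before feature extraction: resampling to a common rate, Butterworth
#' band-limiting, Savitzky-Golay smoothing and fixed-length
#' segmentation. Defaults follow the standard phonocardiogram setup:
#' 2000 Hz sampling, a 25-950 Hz passband and 2.5 s segments.
#'
#' @param target_fs Working sampling rate in Hz.
#' @param band_low,band_high Butterworth passband edges in Hz.
#' @param butter_order Butterworth order (applied forward-backward, so
#'   the effective magnitude response is squared and the phase is zero).
#' @param sg_window Savitzky-Golay window length in samples (odd).
#' @param sg_polyorder Savitzky-Golay polynomial order (< `sg_window`).
#' @param segment_seconds Segment length in seconds; must give an
#'   integer sample count at `target_fs`.
#' @param segment_overlap Fractional overlap between consecutive
#'   segments in `[0, 1)`; 0 means non-overlapping.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_fs = 2000, band_low = 25,
                              band_high = 950, butter_order = 4L,
                              sg_window = 11L, sg_polyorder = 3L,
                              segment_seconds = 2.5, segment_overlap = 0) {
  if (!(band_low > 0 && band_low < band_high && band_high < target_fs / 2))
    stop("preprocess_config: need 0 < band_low < band_high < target_fs/2")
  if (sg_window %% 2L != 1L)
    stop("preprocess_config: sg_window must be odd")
  if (sg_polyorder >= sg_window)
    stop("preprocess_config: sg_polyorder must be < sg_window")
  n_seg <- segment_seconds * target_fs
  if (abs(n_seg - round(n_seg)) > 1e-9)
    stop("preprocess_config: segment_seconds * target_fs must be an integer")
  if (segment_overlap < 0 || segment_overlap >= 1)
    stop("preprocess_config: segment_overlap must be in [0, 1)")
  structure(
    list(target_fs = target_fs, band_low = band_low, band_high = band_high,
         butter_order = as.integer(butter_order),
         sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         segment_seconds = segment_seconds,
         segment_overlap = segment_overlap),
    class = "preprocess_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-limits a recording to `[band_low, band_high]` with a Butterworth
#' filter of the configured order, applied forward and backward
#' (`signal::filtfilt`) so the result has zero phase distortion.
#'
#' @param rec An [audio_recording()] already at `cfg$target_fs`.
#' @param cfg A [preprocess_config()].
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  if (rec$fs != cfg$target_fs)
    stop("bandpass_filter: recording at ", rec$fs, " Hz; resample to ",
         cfg$target_fs, " Hz first (see resample_to)")
  nyq <- cfg$target_fs / 2
  if (cfg$band_high >= nyq)
    stop("bandpass_filter: band_high must be below the Nyquist frequency")
  bf <- signal::butter(cfg$butter_order,
                       c(cfg$band_low, cfg$band_high) / nyq, type = "pass")
  replace_samples(rec, signal::filtfilt(bf, rec$samples))
}

#' Savitzky-Golay smoothing
#'
#' Replaces each sample with the value of a local least-squares
#' polynomial fit over a sliding window, preserving signal length.
#'
#' @inheritParams bandpass_filter
#' @return The smoothed recording.
#' @export
smooth_savitzky_golay <- function(rec, cfg = preprocess_config()) {
  if (cfg$sg_window > length(rec$samples))
    stop("smooth_savitzky_golay: window (", cfg$sg_window,
         ") longer than signal (", length(rec$samples), ")")
  replace_samples(rec, signal::sgolayfilt(rec$samples,
                                          p = cfg$sg_polyorder,
                                          n = cfg$sg_window))
}

#' Resample a recording
#'
#' Band-limited polyphase resampling to `target_fs`. The output length
#' is `round(n * target_fs / fs)`. An identity rate returns the input
#' unchanged.
#'
#' @param rec An [audio_recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return The resampled recording at `target_fs`.
#' @export
resample_to <- function(rec, target_fs) {
  if (!is.numeric(target_fs) || target_fs <= 0)
    stop("resample_to: target_fs must be positive")
  if (rec$fs == target_fs) return(rec)
  p <- round(target_fs); q <- round(rec$fs)
  g <- pracma_gcd(p, q)
  p <- p / g; q <- q / g
  y <- signal::resample(rec$samples, p, q)
  n_out <- round(length(rec$samples) * target_fs / rec$fs)
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, rep(y[length(y)], n_out - length(y)))
  replace_samples(rec, y, fs = target_fs)
}

pracma_gcd <- function(a, b) if (b == 0) a else pracma_gcd(b, a %% b)

#' Split a recording into fixed-length segments
#'
#' Cuts non-overlapping (or partially overlapping, per config)
#' consecutive segments of exactly `segment_seconds * target_fs`
#' samples, discarding any shorter trailing remainder. Each segment
#' inherits the recording's label and domain, with the segment index
#' appended to the record id.
#'
#' With `align = "energy_peak"` the first segment starts at the first
#' prominent short-time-energy peak, a stand-in for the start of a
#' cardiac cycle (typically S1); with `align = "none"` (default)
#' segmentation starts at sample 1.
#'
#' @inheritParams bandpass_filter
#' @param align `"none"` or `"energy_peak"`.
#' @return A list of [audio_recording()] segments (possibly empty).
#' @export
segment_fixed <- function(rec, cfg = preprocess_config(),
                          align = c("none", "energy_peak")) {
  align <- match.arg(align)
  if (rec$fs != cfg$target_fs)
    stop("segment_fixed: recording must be at cfg$target_fs")
  seg_len <- round(cfg$segment_seconds * cfg$target_fs)
  offset <- if (align == "energy_peak") energy_peak_offset(rec) else 0L
  stride <- max(1L, round(seg_len * (1 - cfg$segment_overlap)))
  n <- length(rec$samples)
  starts <- seq.int(offset + 1L, by = stride,
                    length.out = max(0L, (n - offset - seg_len) %/% stride + 1L))
  starts <- starts[starts + seg_len - 1L <= n]
  if (length(starts) == 0L) {
    message("segment_fixed: recording '", rec$record_id,
            "' shorter than one segment; returning no segments")
    return(list())
  }
  lapply(seq_along(starts), function(i) {
    s <- rec$samples[starts[i]:(starts[i] + seg_len - 1L)]
    audio_recording(s, rec$fs, label = rec$label, domain_id = rec$domain_id,
                    record_id = paste0(rec$record_id, "_seg", i))
  })
}

# First prominent short-time-energy peak (rectangular 50 ms window,
# 10 ms hop): the first local maximum reaching half the global maximum.
energy_peak_offset <- function(rec, win_s = 0.05, hop_s = 0.01) {
  win <- max(2L, round(win_s * rec$fs))
  hop <- max(1L, round(hop_s * rec$fs))
  x2 <- rec$samples^2
  starts <- seq.int(1L, length(x2) - win + 1L, by = hop)
  if (length(starts) < 3L) return(0L)
  cs <- c(0, cumsum(x2))
  ste <- cs[starts + win] - cs[starts]
  thr <- 0.5 * max(ste)
  for (i in 2:(length(ste) - 1L)) {
    if (ste[i] >= thr && ste[i] > ste[i - 1L] && ste[i] >= ste[i + 1L])
      return(starts[i] - 1L)
  }
  which.max(ste)[1L] * hop - hop
}

#' Full preprocessing chain
#'
#' Resample to the working rate, band-limit, smooth, and segment:
#' the standard path from a raw recording to model-ready segments.
#'
#' @inheritParams segment_fixed
#' @return A list of preprocessed segments.
#' @export
preprocess_record <- function(rec, cfg = preprocess_config(),
                              align = c("none", "energy_peak")) {
  rec <- resample_to(rec, cfg$target_fs)
  rec <- bandpass_filter(rec, cfg)
  rec <- smooth_savitzky_golay(rec, cfg)
  segment_fixed(rec, cfg, align = match.arg(align))
}
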