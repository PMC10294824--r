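#' Audio recording container
#'
#' A lightweight S3 container for a mono heart-sound signal together with
#' its sampling rate and the metadata the evaluation protocol needs: the
#' class label (`"normal"` / `"abnormal"`) and an acquisition-domain
#' identifier (the sub-dataset the recording belongs to, e.g. the
#' stethoscope model it was captured with).
#'
#' @param samples Numeric vector of amplitudes (dimensionless, finite).
#' @param fs Sampling frequency in Hz (> 0).
#' @param label Optional class label, one of `"normal"`, `"abnormal"` or
#'   `NA`.
#' @param domain_id Optional domain identifier (e.g. `"a"` ... `"f"`).
#' @param record_id Optional record identifier string.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, fs, label = NA_character_,
                            domain_id = NA_character_,
                            record_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("audio_recording: signal must contain at least one sample")
  if (!all(is.finite(samples)))
    stop("audio_recording: samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("audio_recording: fs must be a single positive number")
  if (!is.na(label) && !label %in% c("normal", "abnormal"))
    stop("audio_recording: label must be 'normal', 'abnormal' or NA")
  structure(
    list(samples = samples, fs = fs, label = label,
         domain_id = domain_id, record_id = record_id),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf(
    "<audio_recording> %s: %d samples @ %g Hz (%.2f s), label=%s, domain=%s\n",
    ifelse(is.na(x$record_id), "?", x$record_id),
    length(x$samples), x$fs, length(x$samples) / x$fs,
    x$label, x$domain_id))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [audio_recording()].
#' @return Duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$fs

# internal: keep metadata, swap samples (and possibly fs)
replace_samples <- function(rec, samples, fs = rec$fs) {
  audio_recording(samples, fs, label = rec$label,
                  domain_id = rec$domain_id, record_id = rec$record_id)
}
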