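# Shared fixtures, all generated in code.

sine_rec <- function(freq, duration = 1, fs = 2000, amp = 1) {
  audio_recording(amp * sin(2 * pi * freq * (0:(duration * fs - 1)) / fs),
                  fs)
}

rms <- function(x) sqrt(mean(x^2))

# tiny two-domain dataset for fast end-to-end tests
tiny_dataset <- function(seed = 42L, n_per = 3L, record_seconds = 2.6) {
  counts <- data.frame(domain_id = c("a", "b"),
                       n_normal = c(n_per, n_per),
                       n_abnormal = c(n_per, n_per))
  channels <- make_domain_channels(2L, seed = seed)
  generate_dataset(dataset_spec(counts, seed = seed,
                                record_seconds = record_seconds),
                   channels)
}

# locate a segment's start offset inside its source by matching samples
segment_offset <- function(seg, rec) {
  n <- length(seg$samples)
  for (off in 0:(length(rec$samples) - n)) {
    if (identical(rec$samples[(off + 1):(off + n)], seg$samples)) return(off)
  }
  stop("segment not found in source")
}

# small separable feature set: class difference is a horizontal band
toy_maps <- function(n = 40L, seed = 1L, size = 128L, shift = 1.5) {
  withr::with_seed(seed, {
    X <- array(stats::rnorm(size * size * n), dim = c(size, size, n))
    labels <- rep(c("normal", "abnormal"), length.out = n)
    for (i in which(labels == "abnormal"))
      X[40:60, , i] <- X[40:60, , i] + shift
    list(maps = X, labels = labels)
  })
}
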