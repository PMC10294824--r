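#' Confusion counts
#'
#' Binary confusion counts with the abnormal class as positive.
#'
#' @param y_true,y_pred Character vectors of equal length with values
#'   in `{"normal", "abnormal"}`.
#' @return A `confusion_counts` list with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("confusion: length mismatch")
  ok <- c("normal", "abnormal")
  bad <- setdiff(unique(c(y_true, y_pred)), ok)
  if (length(bad))
    stop("confusion: labels outside {normal, abnormal}: ",
         paste(bad, collapse = ", "))
  structure(list(
    tp = sum(y_true == "abnormal" & y_pred == "abnormal"),
    fn = sum(y_true == "abnormal" & y_pred == "normal"),
    tn = sum(y_true == "normal" & y_pred == "normal"),
    fp = sum(y_true == "normal" & y_pred == "abnormal")),
    class = "confusion_counts")
}

#' Sensitivity, specificity and mean accuracy
#'
#' `Se = tp / (tp + fn)` (abnormal recall), `Sp = tn / (tn + fp)`
#' (normal recall), and their mean `MAcc = (Se + Sp) / 2`, the headline
#' score of the heart-sound challenge.
#'
#' @param c A [confusion()] object.
#' @return A `metrics` list with `se`, `sp`, `macc` in `[0, 1]`.
#' @export
metrics_from_confusion <- function(c) {
  if (c$tp + c$fn == 0)
    stop("metrics_from_confusion: no abnormal records; Se undefined")
  if (c$tn + c$fp == 0)
    stop("metrics_from_confusion: no normal records; Sp undefined")
  se <- c$tp / (c$tp + c$fn)
  sp <- c$tn / (c$tn + c$fp)
  structure(list(se = se, sp = sp, macc = (se + sp) / 2),
            class = "metrics")
}

#' Round half away from zero
#'
#' Display rounding matching the convention used in the reported
#' tables (half-up, not banker's rounding).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Population standard deviation
#'
#' Standard deviation with the `1/n` divisor (not the `1/(n-1)` sample
#' version); this is the dispersion the reported validation-accuracy
#' summaries use.
#'
#' @param x Numeric vector.
#' @return Population SD.
#' @export
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Leave-one-domain-out protocol
#'
#' One fold per test domain: the model trains on all remaining domains
#' (the `always_train` domains are never tested — the analogue of the
#' dominant sub-dataset that is too large to hold out) and is evaluated
#' on the held-out domain.
#'
#' @param test_domains Domains each used once as the test set.
#' @param always_train Domains present in every training set and never
#'   tested.
#' @return A `lodo_protocol` list with a `folds` list of
#'   `(train_domains, test_domain)` pairs.
#' @export
lodo_protocol <- function(test_domains = c("a", "b", "c", "d", "f"),
                          always_train = "e") {
  if (length(intersect(test_domains, always_train)))
    stop("lodo_protocol: a domain cannot be both always-train and test")
  all_domains <- c(test_domains, always_train)
  folds <- lapply(test_domains, function(d)
    list(train_domains = setdiff(all_domains, d), test_domain = d))
  structure(list(folds = folds, test_domains = test_domains,
                 always_train = always_train, domains = all_domains),
            class = "lodo_protocol")
}

# stratified record-level split: returns list(train=, val=) of indices
stratified_split <- function(labels, val_fraction, seed) {
  withr::with_seed(seed, {
    val <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_val <- max(1L, round(length(idx) * val_fraction))
      if (n_val >= length(idx)) n_val <- length(idx) - 1L
      if (n_val > 0L)
        val <- c(val, idx[sample.int(length(idx), n_val)])
    }
    list(train = setdiff(seq_along(labels), val), val = sort(val))
  })
}

#' Run the leave-one-domain-out evaluation
#'
#' For each fold of the protocol: extract features of the requested
#' flavor from every recording, make a stratified 20% validation split
#' of the training domains at the record level, oversample the
#' remaining training records to class balance, train a
#' Kaiming-initialised classifier, and score sensitivity, specificity
#' and mean accuracy on the held-out domain. Predictions are made at
#' the segment level; recording-level scores (majority vote over a
#' recording's segments) are reported alongside.
#'
#' @param dataset A [generate_dataset()] result, or a manifest data
#'   frame with `path` columns pointing at WAV files.
#' @param flavor `"mel"` or `"log_mel"`.
#' @param protocol A [lodo_protocol()].
#' @param arch An [architecture_spec()].
#' @param cfg A [train_config()]; its seed drives the split, the
#'   oversampling and the training.
#' @param pcfg A [preprocess_config()].
#' @param scfg An [stft_config()].
#' @param features Optional precomputed feature store from
#'   [extract_features()] (skips extraction).
#' @return An `eval_report`: list with `flavor`, `seed`, per-fold
#'   data.frame `folds` (`test_domain`, `se`, `sp`, `macc`,
#'   `se_record`, `sp_record`, `macc_record`, `val_acc`), and a
#'   `summary` with cross-fold mean `se`/`sp`/`macc` and the mean and
#'   population SD of the validation accuracies.
#' @export
run_lodo <- function(dataset, flavor = c("log_mel", "mel"),
                     protocol = lodo_protocol(),
                     arch = desk_architecture(),
                     cfg = train_config(),
                     pcfg = preprocess_config(),
                     scfg = stft_config(),
                     features = NULL) {
  flavor <- match.arg(flavor)
  if (is.null(features))
    features <- extract_features(dataset, flavor, pcfg = pcfg, scfg = scfg)
  stopifnot(identical(features$flavor, flavor))
  seg <- features$segments   # data.frame: record_id, label, domain_id, idx

  present <- unique(seg$domain_id)
  missing <- setdiff(protocol$domains, present)
  if (length(missing))
    stop("run_lodo: protocol domains absent from dataset: ",
         paste(missing, collapse = ", "))

  fold_rows <- list()
  for (f in protocol$folds) {
    res <- tryCatch(
      run_fold(features, f, arch, cfg),
      error = function(e) {
        message("run_lodo: fold '", f$test_domain, "' skipped: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(res)) fold_rows[[length(fold_rows) + 1L]] <- res
  }
  if (!length(fold_rows)) stop("run_lodo: every fold failed")
  folds <- do.call(rbind, fold_rows)
  structure(list(
    flavor = flavor, seed = cfg$seed,
    protocol = protocol, folds = folds,
    summary = list(
      mean_se = mean(folds$se), mean_sp = mean(folds$sp),
      mean_macc = mean(folds$macc),
      val_mean = mean(folds$val_acc), val_sd = pop_sd(folds$val_acc))),
    class = "eval_report")
}

run_fold <- function(features, fold, arch, cfg) {
  seg <- features$segments
  test_i <- which(seg$domain_id == fold$test_domain)
  train_recs <- unique(seg$record_id[seg$domain_id %in% fold$train_domains])
  rec_labels <- seg$label[match(train_recs, seg$record_id)]

  sp <- stratified_split(rec_labels, cfg$val_fraction, cfg$seed)
  train_manifest <- data.frame(record_id = train_recs[sp$train],
                               label = rec_labels[sp$train],
                               stringsAsFactors = FALSE)
  if (cfg$oversample)
    train_manifest <- oversample_balance(train_manifest, seed = cfg$seed)
  val_recs <- train_recs[sp$val]

  tr_i <- unlist(lapply(train_manifest$record_id,
                        function(r) which(seg$record_id == r)))
  va_i <- which(seg$record_id %in% val_recs)

  model <- build_model(arch, seed = cfg$seed)
  model <- train_model(model,
                       features$maps[, , tr_i, drop = FALSE],
                       seg$label[tr_i], cfg,
                       features$maps[, , va_i, drop = FALSE],
                       seg$label[va_i])
  pred <- predict(model, features$maps[, , test_i, drop = FALSE])

  m_seg <- metrics_from_confusion(confusion(seg$label[test_i], pred$labels))

  # recording-level: majority vote over each recording's segments
  rec_of <- seg$record_id[test_i]
  rec_true <- tapply(seg$label[test_i], rec_of, `[`, 1L)
  rec_pred <- tapply(pred$labels, rec_of, function(v)
    if (sum(v == "abnormal") * 2L >= length(v)) "abnormal" else "normal")
  m_rec <- metrics_from_confusion(
    confusion(as.character(rec_true), as.character(rec_pred)))

  h <- model$history
  data.frame(test_domain = fold$test_domain,
             se = m_seg$se, sp = m_seg$sp, macc = m_seg$macc,
             se_record = m_rec$se, sp_record = m_rec$sp,
             macc_record = m_rec$macc,
             val_acc = h$val_acc[nrow(h)],
             stringsAsFactors = FALSE)
}

#' Extract a feature store from a dataset
#'
#' Preprocesses every recording (resample, band-pass, smooth, segment)
#' and converts each segment to a standardised model-ready feature map.
#'
#' @inheritParams run_lodo
#' @param align Segment alignment mode (see [segment_fixed()]).
#' @param target_frames Number of time columns of the model input.
#' @return A `feature_store`: list with `flavor`, `maps` (an
#'   `128 x 128 x n_segments` array) and `segments` (data.frame
#'   `record_id`, `label`, `domain_id`).
#' @export
extract_features <- function(dataset, flavor = c("log_mel", "mel"),
                             pcfg = preprocess_config(),
                             scfg = stft_config(),
                             align = "none", target_frames = 128L) {
  flavor <- match.arg(flavor)
  records <- dataset_records(dataset)
  fb <- build_mel_filterbank(n_fft = scfg$n_fft, fs = pcfg$target_fs)
  maps <- list(); meta <- list()
  for (rec in records) {
    segs <- preprocess_record(rec, pcfg, align = align)
    for (s in segs) {
      fm <- segment_features(s, flavor, scfg = scfg, fb = fb,
                             target_frames = target_frames)
      maps[[length(maps) + 1L]] <- fm$values
      meta[[length(meta) + 1L]] <- data.frame(
        record_id = rec$record_id, label = rec$label,
        domain_id = rec$domain_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(maps)) stop("extract_features: no segments produced")
  arr <- array(unlist(maps),
               dim = c(nrow(maps[[1L]]), ncol(maps[[1L]]), length(maps)))
  structure(list(flavor = flavor, maps = arr,
                 segments = do.call(rbind, meta)),
            class = "feature_store")
}

# accept a generate_dataset() result, a list of recordings, or a
# manifest data.frame with WAV paths
dataset_records <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$records)) return(dataset$records)
  if (is.data.frame(dataset)) {
    return(lapply(seq_len(nrow(dataset)), function(i)
      read_wav(dataset$path[i], label = dataset$label[i],
               domain_id = dataset$domain_id[i],
               record_id = dataset$record_id[i])))
  }
  if (is.list(dataset) && all(vapply(dataset, inherits, logical(1),
                                     "audio_recording")))
    return(dataset)
  stop("dataset_records: unrecognised dataset form")
}

#' Compare the two feature flavors
#'
#' Per-fold and average differences (log-Mel minus Mel) of Se, Sp and
#' MAcc between two reports run under the same protocol and seed.
#'
#' @param report_mel,report_logmel `eval_report`s from [run_lodo()]
#'   with flavors `"mel"` and `"log_mel"`.
#' @return A `flavor_comparison`: data.frame of per-fold deltas plus
#'   average deltas.
#' @export
compare_flavors <- function(report_mel, report_logmel) {
  if (!identical(report_mel$flavor, "mel") ||
      !identical(report_logmel$flavor, "log_mel"))
    stop("compare_flavors: pass the mel report first, log_mel second")
  if (!identical(report_mel$protocol$test_domains,
                 report_logmel$protocol$test_domains) ||
      report_mel$seed != report_logmel$seed)
    stop("compare_flavors: reports use different protocols or seeds")
  common <- intersect(report_mel$folds$test_domain,
                      report_logmel$folds$test_domain)
  fm <- report_mel$folds[match(common, report_mel$folds$test_domain), ]
  fl <- report_logmel$folds[match(common, report_logmel$folds$test_domain), ]
  deltas <- data.frame(test_domain = common,
                       d_se = fl$se - fm$se,
                       d_sp = fl$sp - fm$sp,
                       d_macc = fl$macc - fm$macc,
                       stringsAsFactors = FALSE)
  structure(list(deltas = deltas,
                 avg = c(d_se = mean(deltas$d_se),
                         d_sp = mean(deltas$d_sp),
                         d_macc = mean(deltas$d_macc))),
            class = "flavor_comparison")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> flavor=%s seed=%d\n", x$flavor, x$seed))
  print(transform(x$folds,
                  se = round_half_up(se), sp = round_half_up(sp),
                  macc = round_half_up(macc)))
  cat(sprintf("mean Se %.4f, Sp %.4f, MAcc %.4f; validation %.2f%% +/- %.2f%%\n",
              x$summary$mean_se, x$summary$mean_sp, x$summary$mean_macc,
              100 * x$summary$val_mean, 100 * x$summary$val_sd))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-fold metrics as CSV and the summary as JSON.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- paste0("lodo_", report$flavor, "_seed", report$seed)
  utils::write.csv(report$folds, file.path(dir, paste0(stem, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(report$summary,
                       file.path(dir, paste0(stem, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
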