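#' Default run configuration
#'
#' A single nested configuration covering every stage of an
#' experiment: simulation, preprocessing, STFT/Mel features,
#' architecture, training and the evaluation protocol. Serialises
#' losslessly to YAML via [save_run_config()] / [load_run_config()].
#'
#' The training defaults here are the desk-scale ones (learning rate
#' 1e-3, few epochs, narrow architecture) chosen so the whole
#' leave-one-domain-out experiment converges in minutes on one CPU;
#' [train_config()] carries the full-scale defaults instead.
#'
#' @param seed Global seed; stage seeds derive from it.
#' @param scale Scale of the simulated dataset relative to the
#'   full-size six-domain structure.
#' @param record_seconds Length of each simulated recording.
#' @param snr_db Additive-noise SNR for the simulator.
#' @param epochs Training epochs.
#' @param seeds Seeds for repeated evaluation runs.
#' @param reduced Use the narrow desk-scale architecture (default) or
#'   the full-width one.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, scale = 1 / 20, record_seconds = 5,
                       snr_db = 20, epochs = 12L, seeds = seed,
                       reduced = TRUE) {
  structure(list(
    seed = as.integer(seed), seeds = as.integer(seeds),
    simulate = list(scale = scale, record_seconds = record_seconds,
                    snr_db = snr_db, fs = 2000),
    preprocess = list(target_fs = 2000, band_low = 25, band_high = 950,
                      butter_order = 4L, sg_window = 11L, sg_polyorder = 3L,
                      segment_seconds = 2.5),
    stft = list(window_size = 240L, hop_length = 60L, n_fft = 512L,
                n_mels = 128L),
    train = list(learning_rate = 1e-3, batch_size = 160L,
                 epochs = as.integer(epochs), val_fraction = 0.2,
                 oversample = TRUE),
    protocol = list(test_domains = c("a", "b", "c", "d", "f"),
                    always_train = "e"),
    reduced = reduced),
    class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

config_objects <- function(config) {
  list(
    pcfg = do.call(preprocess_config, config$preprocess[
      intersect(names(config$preprocess),
                names(formals(preprocess_config)))]),
    scfg = do.call(stft_config, config$stft[
      intersect(names(config$stft), names(formals(stft_config)))]),
    arch = if (isTRUE(config$reduced)) desk_architecture()
           else architecture_spec(),
    protocol = do.call(lodo_protocol, config$protocol))
}

#' Simulate a dataset to disk
#'
#' Wraps [generate_dataset()]: builds the per-domain channel set and
#' the domain-count table from the configuration, writes WAVs and
#' `manifest.csv` to `out_dir`, and logs per-domain counts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The dataset (records + manifest), invisibly.
#' @export
cmd_simulate <- function(config = run_config(), out_dir) {
  counts <- default_domain_counts(config$simulate$scale)
  channels <- make_domain_channels(nrow(counts), seed = config$seed,
                                  fs = config$simulate$fs)
  spec <- dataset_spec(counts, seed = config$seed,
                       fs = config$simulate$fs,
                       record_seconds = config$simulate$record_seconds,
                       snr_db = config$simulate$snr_db)
  ds <- generate_dataset(spec, channels, out_dir = out_dir)
  tab <- table(ds$manifest$domain_id, ds$manifest$label)
  message("simulated ", nrow(ds$manifest), " records:")
  for (d in rownames(tab))
    message(sprintf("  domain %s: %d normal / %d abnormal",
                    d, tab[d, "normal"], tab[d, "abnormal"]))
  invisible(ds)
}

#' Extract and persist a feature store
#'
#' Preprocesses and featurises every manifest record, storing the maps
#' (RDS) with a JSON metadata sidecar describing shapes, flavor and
#' the configuration used.
#'
#' @param manifest Manifest data frame or path to `manifest.csv`.
#' @param flavor `"mel"` or `"log_mel"`.
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The `feature_store`, invisibly.
#' @export
cmd_extract <- function(manifest, flavor = c("log_mel", "mel"),
                        config = run_config(), out_dir) {
  flavor <- match.arg(flavor)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  obj <- config_objects(config)
  fs <- extract_features(manifest, flavor, pcfg = obj$pcfg,
                         scfg = obj$scfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  saveRDS(fs, file.path(out_dir, paste0("features_", flavor, ".rds")))
  jsonlite::write_json(
    list(flavor = flavor, n_segments = dim(fs$maps)[3],
         map_shape = dim(fs$maps)[1:2],
         stft = config$stft, preprocess = config$preprocess),
    file.path(out_dir, paste0("features_", flavor, ".json")),
    auto_unbox = TRUE, digits = NA)
  invisible(fs)
}

#' Run the full evaluation experiment
#'
#' The end-to-end driver: simulate (or load) a six-domain dataset, run
#' the leave-one-domain-out protocol for both feature flavors across
#' the configured seeds, write per-seed reports, and summarise the
#' flavor comparison.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for reports (`NULL` to skip
#'   writing).
#' @param dataset Optional pre-generated dataset (from
#'   [cmd_simulate()] or [generate_dataset()]); simulated fresh when
#'   `NULL`.
#' @return List with per-seed `reports` (nested: seed, then flavor),
#'   `comparisons` per seed, and `across_seeds` mean MAcc per flavor.
#' @export
cmd_evaluate <- function(config = run_config(), out_dir = NULL,
                         dataset = NULL) {
  obj <- config_objects(config)
  if (is.null(dataset)) {
    counts <- default_domain_counts(config$simulate$scale)
    channels <- make_domain_channels(nrow(counts), seed = config$seed,
                                    fs = config$simulate$fs)
    spec <- dataset_spec(counts, seed = config$seed,
                         fs = config$simulate$fs,
                         record_seconds = config$simulate$record_seconds,
                         snr_db = config$simulate$snr_db)
    dataset <- generate_dataset(spec, channels)
  }
  feats <- list(
    mel = extract_features(dataset, "mel", pcfg = obj$pcfg,
                           scfg = obj$scfg),
    log_mel = extract_features(dataset, "log_mel", pcfg = obj$pcfg,
                               scfg = obj$scfg))
  reports <- list(); comparisons <- list()
  for (s in config$seeds) {
    cfg <- train_config(learning_rate = config$train$learning_rate,
                        batch_size = config$train$batch_size,
                        epochs = config$train$epochs,
                        val_fraction = config$train$val_fraction,
                        oversample = config$train$oversample,
                        seed = s)
    rep_mel <- run_lodo(dataset, "mel", obj$protocol, obj$arch, cfg,
                        features = feats$mel)
    rep_log <- run_lodo(dataset, "log_mel", obj$protocol, obj$arch, cfg,
                        features = feats$log_mel)
    key <- paste0("seed", s)
    reports[[key]] <- list(mel = rep_mel, log_mel = rep_log)
    comparisons[[key]] <- compare_flavors(rep_mel, rep_log)
    if (!is.null(out_dir)) {
      write_eval_report(rep_mel, out_dir)
      write_eval_report(rep_log, out_dir)
    }
  }
  macc_mel <- mean(vapply(reports, function(r)
    r$mel$summary$mean_macc, numeric(1)))
  macc_log <- mean(vapply(reports, function(r)
    r$log_mel$summary$mean_macc, numeric(1)))
  out <- list(reports = reports, comparisons = comparisons,
              across_seeds = c(macc_mel = macc_mel,
                               macc_log_mel = macc_log,
                               d_macc = macc_log - macc_mel))
  if (!is.null(out_dir)) {
    jsonlite::write_json(as.list(out$across_seeds),
                         file.path(out_dir, "across_seeds.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(comparison_markdown(out), file.path(out_dir,
                                                   "comparison.md"))
  }
  out
}

#' Recompute aggregates from stored fold results
#'
#' Reads the per-fold CSVs written by [write_eval_report()] and
#' recomputes the cross-fold averages and the validation mean and
#' population SD, verifying report self-consistency.
#'
#' @param dir Directory holding `lodo_*.csv` files.
#' @return Data frame with one row per report file.
#' @export
reproduce_metrics <- function(dir) {
  files <- list.files(dir, pattern = "^lodo_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("reproduce_metrics: no report CSVs in ", dir)
  do.call(rbind, lapply(files, function(f) {
    folds <- utils::read.csv(f, stringsAsFactors = FALSE)
    data.frame(report = basename(f),
               mean_se = mean(folds$se), mean_sp = mean(folds$sp),
               mean_macc = mean(folds$macc),
               val_mean = mean(folds$val_acc),
               val_sd = pop_sd(folds$val_acc),
               stringsAsFactors = FALSE)
  }))
}

# markdown table mirroring the per-test-domain Se/Sp/MAcc layout
comparison_markdown <- function(result) {
  lines <- c("| Test domain | Flavor | Se | Sp | MAcc |",
             "|---|---|---|---|---|")
  first <- result$reports[[1L]]
  for (d in first$mel$folds$test_domain) {
    for (fl in c("mel", "log_mel")) {
      row <- first[[fl]]$folds
      row <- row[row$test_domain == d, ]
      lines <- c(lines, sprintf("| %s | %s | %.4f | %.4f | %.4f |",
                                d, fl, round_half_up(row$se),
                                round_half_up(row$sp),
                                round_half_up(row$macc)))
    }
  }
  lines <- c(lines, "",
             sprintf("Across seeds: mean MAcc mel %.4f, log-mel %.4f, delta %+.4f",
                     result$across_seeds["macc_mel"],
                     result$across_seeds["macc_log_mel"],
                     result$across_seeds["d_macc"]))
  lines
}
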