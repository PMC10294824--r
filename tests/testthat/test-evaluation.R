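test_that("confusion counts match a brute-force loop", {
  yt <- c("normal", "abnormal", "abnormal", "normal")
  expect_equal(unclass(confusion(yt, yt))[c("fn", "fp")],
               list(fn = 0L, fp = 0L), ignore_attr = TRUE)
  all_norm <- confusion(yt, rep("normal", 4))
  expect_equal(all_norm$tp, 0L)
  expect_equal(all_norm$fp, 0L)

  withr::with_seed(1, {
    yt <- sample(c("normal", "abnormal"), 50, replace = TRUE)
    yp <- sample(c("normal", "abnormal"), 50, replace = TRUE)
    c0 <- confusion(yt, yp)
    tp <- fn <- tn <- fp <- 0L
    for (i in 1:50) {
      if (yt[i] == "abnormal" && yp[i] == "abnormal") tp <- tp + 1L
      if (yt[i] == "abnormal" && yp[i] == "normal") fn <- fn + 1L
      if (yt[i] == "normal" && yp[i] == "normal") tn <- tn + 1L
      if (yt[i] == "normal" && yp[i] == "abnormal") fp <- fp + 1L
    }
    expect_equal(c0$tp, tp); expect_equal(c0$fn, fn)
    expect_equal(c0$tn, tn); expect_equal(c0$fp, fp)
  })
  expect_error(confusion(c("normal", "weird"), c("normal", "normal")),
               "outside")
})

test_that("metrics reproduce the published arithmetic", {
  # MAcc from printed Se/Sp pairs agrees with the printed MAcc to the
  # table's precision (the underlying fractions were rounded first)
  expect_lt(abs((0.7143 + 0.9508) / 2 - 0.8325), 5.01e-5)
  expect_equal(round_half_up((0.6267 + 0.5299) / 2), 0.5783)

  c1 <- structure(list(tp = 5, fn = 2, tn = 58, fp = 3),
                  class = "confusion_counts")
  m <- metrics_from_confusion(c1)
  expect_equal(m$se, 5 / 7)
  expect_equal(m$sp, 58 / 61)
  expect_equal(m$macc, (m$se + m$sp) / 2)

  perfect <- metrics_from_confusion(
    structure(list(tp = 4, fn = 0, tn = 6, fp = 0),
              class = "confusion_counts"))
  expect_equal(perfect$macc, 1)

  expect_error(metrics_from_confusion(
    structure(list(tp = 0, fn = 0, tn = 5, fp = 1),
              class = "confusion_counts")), "Se undefined")
})

test_that("validation-accuracy aggregation uses the population SD", {
  vals <- c(97.0, 93.0, 87.3, 87.7, 93.7)
  expect_equal(round_half_up(mean(vals), 2), 91.74)
  expect_equal(round_half_up(pop_sd(vals), 2), 3.72)
  # the sample SD does not reproduce the published dispersion
  expect_false(isTRUE(all.equal(round_half_up(stats::sd(vals), 2), 3.72)))
  # second published row
  vals2 <- c(93.9, 86.4, 82.3, 85, 89.5)
  expect_equal(round_half_up(mean(vals2), 2), 87.42)
  expect_equal(round_half_up(pop_sd(vals2), 2), 3.99)
})

test_that("protocol construction enforces the train/test separation", {
  p <- lodo_protocol()
  expect_length(p$folds, 5L)
  for (f in p$folds) {
    expect_false(f$test_domain %in% f$train_domains)
    expect_true("e" %in% f$train_domains)
  }
  expect_error(lodo_protocol(test_domains = c("a", "e")), "both")
})

test_that("stratified split is disjoint, stratified and precedes oversampling", {
  labels <- rep(c("normal", "abnormal"), c(30, 10))
  sp <- melpcg:::stratified_split(labels, 0.2, seed = 1)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_equal(sort(c(sp$train, sp$val)), 1:40)
  expect_equal(sum(labels[sp$val] == "normal"), 6L)
  expect_equal(sum(labels[sp$val] == "abnormal"), 2L)

  # oversampling the training portion never touches validation entries
  man <- data.frame(record_id = paste0("r", sp$train),
                    label = labels[sp$train])
  bal <- oversample_balance(man, seed = 1)
  expect_false(any(paste0("r", sp$val) %in% bal$record_id))
})

test_that("LODO on a separable two-domain toy set scores well per fold", {
  ds <- tiny_dataset(seed = 21L, n_per = 12L, record_seconds = 2.6)
  proto <- lodo_protocol(test_domains = c("a", "b"),
                         always_train = character(0))
  cfg <- train_config(learning_rate = 1e-3, epochs = 15, batch_size = 16,
                      seed = 1)
  rep_log <- run_lodo(ds, "log_mel", proto, desk_architecture(), cfg)
  expect_equal(nrow(rep_log$folds), 2L)
  expect_true(all(rep_log$folds$macc > 0.8))
  # report invariants
  expect_equal(rep_log$summary$mean_macc, mean(rep_log$folds$macc))
  expect_equal(rep_log$folds$macc,
               (rep_log$folds$se + rep_log$folds$sp) / 2)
  expect_equal(rep_log$summary$val_sd, pop_sd(rep_log$folds$val_acc))
})

test_that("flavor comparison validates protocols and computes deltas", {
  folds <- data.frame(test_domain = c("a", "b"),
                      se = c(0.6, 0.7), sp = c(0.8, 0.9),
                      macc = c(0.7, 0.8), val_acc = c(0.9, 0.92))
  proto <- lodo_protocol(test_domains = c("a", "b"),
                         always_train = character(0))
  mk <- function(flavor, folds, seed = 1) {
    structure(list(flavor = flavor, seed = seed, protocol = proto,
                   folds = folds,
                   summary = list(mean_macc = mean(folds$macc))),
              class = "eval_report")
  }
  same <- compare_flavors(mk("mel", folds), mk("log_mel", folds))
  expect_true(all(same$deltas$d_macc == 0))

  better <- folds; better$macc <- better$macc + 0.05
  cmp <- compare_flavors(mk("mel", folds), mk("log_mel", better))
  expect_equal(cmp$avg[["d_macc"]], 0.05)
  # delta of averages equals average of deltas
  expect_equal(cmp$avg[["d_macc"]], mean(cmp$deltas$d_macc))

  expect_error(compare_flavors(mk("mel", folds),
                               mk("log_mel", folds, seed = 2)), "seeds")
  expect_error(compare_flavors(mk("log_mel", folds), mk("mel", folds)),
               "first")
})

test_that("published per-fold MAcc differences favour log-mel in all folds", {
  mel_macc <- c(0.5783, 0.7598, 0.7024, 0.6005, 0.6461)
  log_macc <- c(0.6765, 0.8325, 0.7232, 0.6892, 0.6654)
  expect_true(all(log_macc - mel_macc > 0))
})

test_that("eval report writing and metric reproduction are consistent", {
  folds <- data.frame(test_domain = c("a", "b"),
                      se = c(0.6, 0.7), sp = c(0.8, 0.9),
                      macc = c(0.7, 0.8),
                      se_record = c(0.6, 0.7), sp_record = c(0.8, 0.9),
                      macc_record = c(0.7, 0.8),
                      val_acc = c(0.9, 0.92))
  rep <- structure(list(flavor = "mel", seed = 3,
                        protocol = lodo_protocol(c("a", "b"),
                                                 character(0)),
                        folds = folds,
                        summary = list(mean_se = 0.65, mean_sp = 0.85,
                                       mean_macc = 0.75,
                                       val_mean = 0.91,
                                       val_sd = pop_sd(c(0.9, 0.92)))),
                   class = "eval_report")
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  redo <- reproduce_metrics(dir)
  expect_equal(redo$mean_macc, 0.75)
  expect_equal(redo$val_mean, 0.91)
  expect_equal(redo$val_sd, pop_sd(c(0.9, 0.92)))
})
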