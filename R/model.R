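#' Classifier architecture specification
#'
#' The modified VGG16-style layer census used throughout: exactly seven
#' 3x3 convolution layers, three max-pooling layers (after convolution
#' layers 2, 4 and 7, tracing the spatial size 128 -> 64 -> 32 -> 16)
#' and four fully-connected layers ending in a 2-way softmax over
#' {normal, abnormal}. Channel and FC widths are configurable; the
#' census and the spatial trace are not.
#'
#' @param conv_widths Seven output-channel counts for the convolution
#'   layers.
#' @param pool_after 1-based indices of the three convolution layers
#'   followed by a 2x2 max pool.
#' @param fc_widths Four fully-connected layer widths; the last must
#'   be 2.
#' @param input_size Side length of the square single-channel input.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(conv_widths = c(32, 32, 64, 64, 128, 128, 128),
                              pool_after = c(2L, 4L, 7L),
                              fc_widths = c(256, 128, 64, 2),
                              input_size = 128L) {
  if (length(conv_widths) != 7L)
    stop("architecture_spec: exactly 7 convolution layers are required")
  if (length(pool_after) != 3L)
    stop("architecture_spec: exactly 3 pooling layers are required")
  if (length(fc_widths) != 4L)
    stop("architecture_spec: exactly 4 fully-connected layers are required")
  if (fc_widths[4L] != 2L)
    stop("architecture_spec: the final layer width must be 2")
  if (any(!pool_after %in% seq_len(7L)) || anyDuplicated(pool_after))
    stop("architecture_spec: pool_after must be distinct conv indices")
  structure(list(conv_widths = as.integer(conv_widths),
                 pool_after = sort(as.integer(pool_after)),
                 fc_widths = as.integer(fc_widths),
                 input_size = as.integer(input_size)),
            class = "architecture_spec")
}

#' Reduced architecture for desk-scale experiments
#'
#' Same 7 conv / 3 pool / 4 FC census and 128 -> 64 -> 32 -> 16 spatial
#' trace as the full [architecture_spec()], with narrow channels so
#' that a full leave-one-domain-out experiment trains in minutes on one
#' CPU.
#'
#' @return An `architecture_spec`.
#' @export
desk_architecture <- function() {
  architecture_spec(conv_widths = c(2, 2, 4, 4, 8, 8, 8),
                    fc_widths = c(16, 16, 8, 2))
}

#' Spatial size after each pooling stage
#'
#' @param arch An [architecture_spec()].
#' @return Integer vector of side lengths, starting at the input size.
#' @export
spatial_trace <- function(arch) {
  arch$input_size / 2^(0:length(arch$pool_after))
}

#' Training configuration
#'
#' Hyper-parameters of the classifier's training loop: Adam on softmax
#' cross-entropy, learning rate 1e-4, mini-batches of up to 160 maps,
#' a 20% stratified validation split taken before oversampling, and
#' Kaiming-initialised weights.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (capped at the training-set size).
#' @param epochs Number of passes over the training data.
#' @param val_fraction Fraction held out for validation (stratified by
#'   label, split at the record level before oversampling).
#' @param oversample Balance classes in the training portion by
#'   duplicating minority examples.
#' @param seed Integer seed governing initialisation, the split and
#'   batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 160L,
                         epochs = 30L, val_fraction = 0.2,
                         oversample = TRUE, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("train_config: val_fraction must be in (0, 1)")
  if (batch_size < 1L) stop("train_config: batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_fraction = val_fraction, oversample = oversample,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Kaiming-normal init: sd = sqrt(2 / fan_in), biases zero.
init_params <- function(arch, seed) {
  withr::with_seed(seed, {
    conv <- list()
    cin <- 1L
    for (i in seq_along(arch$conv_widths)) {
      cout <- arch$conv_widths[i]
      fan_in <- 9L * cin
      conv[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = cout),
        b = numeric(cout))
      cin <- cout
    }
    final_hw <- arch$input_size / 2^length(arch$pool_after)
    dim_in <- as.integer(final_hw^2 * cin)
    fc <- list()
    for (j in seq_along(arch$fc_widths)) {
      dim_out <- arch$fc_widths[j]
      fc[[j]] <- list(
        W = matrix(stats::rnorm(dim_in * dim_out, sd = sqrt(2 / dim_in)),
                   nrow = dim_in, ncol = dim_out),
        b = numeric(dim_out))
      dim_in <- dim_out
    }
    list(conv = conv, fc = fc)
  })
}

#' Build a classifier
#'
#' Instantiates the network of an [architecture_spec()] with
#' Kaiming-normal weights (variance `2 / fan_in`, zero biases),
#' deterministic per seed.
#'
#' @param arch An [architecture_spec()].
#' @param seed Integer seed for the initialisation.
#' @return A `pcg_cnn` model object.
#' @export
build_model <- function(arch = architecture_spec(), seed = 1L) {
  structure(list(arch = arch, params = init_params(arch, seed),
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "pcg_cnn")
}

#' @export
print.pcg_cnn <- function(x, ...) {
  cat(sprintf(
    "<pcg_cnn> %d conv (%s) / %d pool / %d fc (%s), input %dx%d, %s\n",
    length(x$arch$conv_widths),
    paste(x$arch$conv_widths, collapse = ","),
    length(x$arch$pool_after), length(x$arch$fc_widths),
    paste(x$arch$fc_widths, collapse = ","),
    x$arch$input_size, x$arch$input_size,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# stack a list of feature maps (or an n x h x w array) into an
# h x w x n array for the C++ core
as_input_array <- function(x, input_size) {
  if (is.list(x))
    x <- vapply(x, function(fm) {
      v <- if (inherits(fm, "feature_map")) fm$values else fm
      if (!all(dim(v) == c(input_size, input_size)))
        stop("model input must be ", input_size, " x ", input_size)
      v
    }, matrix(0, input_size, input_size))
  if (length(dim(x)) != 3L)
    stop("model input must be a list of maps or a 3-d array")
  x
}

label_to_int <- function(labels) {
  bad <- setdiff(unique(labels), c("normal", "abnormal"))
  if (length(bad))
    stop("labels outside {normal, abnormal}: ", paste(bad, collapse = ", "))
  ifelse(labels == "abnormal", 1L, 0L)
}

#' Train a classifier
#'
#' Mini-batch Adam on softmax cross-entropy. Training and validation
#' curves (loss and accuracy per epoch) are recorded in
#' `model$history`. Training is deterministic for a fixed seed on a
#' fixed machine.
#'
#' @param model A [build_model()] object.
#' @param x Training feature maps: list of `feature_map`s or an
#'   `h x w x n` array.
#' @param labels Character labels (`"normal"` / `"abnormal"`).
#' @param cfg A [train_config()].
#' @param x_val,labels_val Optional validation set in the same formats.
#' @return The trained model, with `history` a data.frame of per-epoch
#'   `train_loss`, `train_acc`, `val_loss`, `val_acc`.
#' @export
train_model <- function(model, x, labels, cfg = train_config(),
                        x_val = NULL, labels_val = NULL) {
  X <- as_input_array(x, model$arch$input_size)
  y <- label_to_int(labels)
  if (dim(X)[3] != length(y))
    stop("train_model: sample/label count mismatch")
  if (is.null(x_val)) {
    Xv <- array(0, dim = c(model$arch$input_size, model$arch$input_size, 0))
    yv <- integer(0)
  } else {
    Xv <- as_input_array(x_val, model$arch$input_size)
    yv <- label_to_int(labels_val)
  }
  arch <- list(pool_after = model$arch$pool_after,
               input_size = model$arch$input_size)
  res <- cnn_train_cpp(X, y, model$params, arch, cfg$learning_rate,
                       cfg$epochs, min(cfg$batch_size, dim(X)[3]),
                       cfg$seed, Xv, yv)
  model$params <- res$params
  model$trained <- TRUE
  model$history <- data.frame(
    epoch = seq_len(cfg$epochs),
    train_loss = as.numeric(res$train_loss),
    train_acc = as.numeric(res$train_acc),
    val_loss = as.numeric(res$val_loss),
    val_acc = as.numeric(res$val_acc))
  model
}

#' Predict labels and probabilities
#'
#' @param object A `pcg_cnn` model.
#' @param x Feature maps (list or `h x w x n` array).
#' @param ... Unused.
#' @return List with `labels` (character) and `probabilities` (n x 2
#'   matrix, columns `normal`, `abnormal`; rows sum to 1).
#' @export
predict.pcg_cnn <- function(object, x, ...) {
  X <- as_input_array(x, object$arch$input_size)
  arch <- list(pool_after = object$arch$pool_after,
               input_size = object$arch$input_size)
  probs <- cnn_predict_cpp(X, object$params, arch)
  colnames(probs) <- c("normal", "abnormal")
  list(labels = ifelse(probs[, 2] > probs[, 1], "abnormal", "normal"),
       probabilities = probs)
}

#' Balance classes by oversampling
#'
#' Keeps every entry of the input and appends minority-class entries
#' drawn with replacement until both classes have equal counts.
#' Deterministic per seed; a no-op on balanced input.
#'
#' @param manifest Data frame with a `label` column.
#' @param seed Integer seed.
#' @return The balanced data frame (rows of the input only).
#' @export
oversample_balance <- function(manifest, seed = 1L) {
  tab <- table(factor(manifest$label, levels = c("normal", "abnormal")))
  if (any(tab == 0L))
    stop("oversample_balance: class absent: ",
         names(tab)[tab == 0L][1L])
  if (tab[1L] == tab[2L]) return(manifest)
  minority <- names(tab)[which.min(tab)]
  deficit <- abs(tab[1L] - tab[2L])
  idx <- which(manifest$label == minority)
  extra <- withr::with_seed(seed,
    idx[sample.int(length(idx), deficit, replace = TRUE)])
  rbind(manifest, manifest[extra, , drop = FALSE])
}

#' Save / load a model checkpoint
#'
#' Stores architecture, parameters and training history in an RDS
#' file; the training-curve export companion writes `history` as CSV.
#'
#' @param model A `pcg_cnn`.
#' @param path Output path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pcg_cnn")) stop("load_checkpoint: not a pcg_cnn file")
  m
}

#' Export training curves
#'
#' @param model A trained `pcg_cnn`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
export_history <- function(model, path) {
  if (is.null(model$history)) stop("export_history: model has no history")
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
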