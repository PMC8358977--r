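#' CNN architecture specification
#'
#' The compact two-convolution network used for per-subject epoch
#' classification: a temporal convolution (12 filters, 1 x 4 kernel, no
#' activation) followed by a spatio-temporal convolution (12 filters,
#' kernel spanning all channels x 4 samples, ELU), a 1 x 4 max-pool
#' (stride 4, floor on the remainder), flatten, 30% dropout, a 32-unit
#' ELU dense layer, and a single sigmoid output unit. Convolutions are
#' unpadded ("valid") with stride 1. For the standard 60-channel, 2-s /
#' 100 Hz input the shape chain is
#' 60x200 -> 60x197 -> 1x194 -> 1x48 -> 576 -> 32 -> 1 and the trainable
#' parameter count is 53,129.
#'
#' @param n_channels input channel count (default 60)
#' @param n_samples input samples per epoch (default 200)
#' @param n_filters filters per convolutional layer (default 12)
#' @param kernel temporal kernel length (default 4)
#' @param pool max-pool width and stride (default 4)
#' @param dense_units dense-layer width (default 32)
#' @param dropout dropout rate after pooling (default 0.30)
#' @return a `cnn_spec`: layer table with output shapes and per-layer
#'   parameter counts (closed-form), plus `total_params`
#' @export
cnn_spec <- function(n_channels = 60, n_samples = 200, n_filters = 12,
                     kernel = 4, pool = 4, dense_units = 32,
                     dropout = 0.30) {
  assert_that(n_samples >= 2 * kernel, "input too short for two convolutions")
  l1 <- n_samples - kernel + 1
  l2 <- l1 - kernel + 1
  np <- l2 %/% pool
  flat <- n_filters * np
  params <- c(conv1 = n_filters * kernel + n_filters,
              conv2 = n_filters * (n_channels * kernel * n_filters) + n_filters,
              pool = 0, flatten = 0, dropout = 0,
              dense1 = dense_units * flat + dense_units,
              dense2 = dense_units + 1)
  layers <- data.frame(
    operation = c("conv2d", "conv2d", "maxpool", "flatten", "dropout",
                  "dense", "dense"),
    activation = c("", "elu", "", "", "", "elu", "sigmoid"),
    output_shape = c(sprintf("%d x %d", n_channels, l1),
                     sprintf("1 x %d", l2),
                     sprintf("1 x %d", np),
                     sprintf("%d", flat),
                     sprintf("%d", flat),
                     sprintf("%d", dense_units), "1"),
    parameters = as.integer(params),
    stringsAsFactors = FALSE)
  structure(list(n_channels = n_channels, n_samples = n_samples,
                 n_filters = n_filters, kernel = kernel, pool = pool,
                 dense_units = dense_units, dropout = dropout,
                 layers = layers, total_params = sum(params)),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> input %d x %d, %s trainable parameters\n",
              x$n_channels, x$n_samples, format(x$total_params, big.mark = ",")))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Build (initialise) a CNN
#'
#' Instantiates the network with seeded Glorot-uniform weights and zero
#' biases.
#'
#' @param spec a [cnn_spec()]
#' @param seed integer seed for the weight initialisation
#' @return a `cnn_model` holding the weight matrices and the spec
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1) {
  assert_that(inherits(spec, "cnn_spec"), "`spec` must be a cnn_spec")
  w <- cnn_init_cpp(spec$n_channels, spec$n_samples, as.integer(seed))
  structure(list(weights = w, spec = spec, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %d x %d, %s parameters%s\n",
              x$spec$n_channels, x$spec$n_samples,
              format(count_params(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Count trainable parameters of a built model
#'
#' Counts the actual elements of every weight and bias array, which must
#' agree with the closed-form per-layer counts in the spec.
#'
#' @param model a `cnn_model`
#' @return integer total parameter count
#' @export
count_params <- function(model) {
  w <- model$weights
  sum(vapply(list(w$W1, w$b1, w$W2, w$b2, w$W3, w$b3, w$W4),
             length, numeric(1))) + 1L  # + scalar output bias
}

#' Min-max normalisation of an epoch array to [-1, 1]
#'
#' The affine map is computed from the global minimum and maximum over the
#' whole array (the subject's dataset), preserving relative amplitudes
#' across epochs and channels. Constant data map to all zeros.
#'
#' @param x numeric array, epochs x channels x samples
#' @return the normalised array, spanning exactly `[-1, 1]` (or all zero)
#' @export
normalize_minmax <- function(x) {
  assert_that(length(x) > 0, "empty epoch array")
  apply_minmax(minmax_transform(x), x)
}

#' Fit the min-max transform on training data
#' @param x numeric array (training epochs)
#' @return list with `min` and `max` to be used by [apply_minmax()]
#' @export
minmax_transform <- function(x) {
  list(min = min(x), max = max(x))
}

#' Apply a frozen min-max transform
#' @param transform list from [minmax_transform()]
#' @param x numeric array to scale
#' @return scaled array (training data spans `[-1, 1]`)
#' @export
apply_minmax <- function(transform, x) {
  rng <- transform$max - transform$min
  if (rng == 0) return(x * 0)
  2 * (x - transform$min) / rng - 1
}

#' Balanced class weights from a label distribution
#'
#' `weight_c = N_total / (2 * N_c)`: the under-represented class is
#' up-weighted so that both classes contribute equally to the loss.
#'
#' @param labels per-epoch class labels (both classes required)
#' @return named numeric vector `c("0" = ..., "1" = ...)` where `1` is the
#'   syllable class
#' @export
class_weights <- function(labels) {
  y <- as_binary_labels(labels)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  assert_that(n0 > 0 && n1 > 0,
              "both classes must be present to derive class weights")
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' CNN training configuration
#'
#' Defaults follow the per-subject training protocol: Adam
#' (lr 0.001, beta1 0.9, beta2 0.999, epsilon 1e-7), binary cross-entropy
#' with class weights, batch size 32, and a fixed 25 passes through the
#' training data. Early stopping on validation AUC with patience 6 is the
#' model-development variant, enabled by `early_stopping = TRUE`.
#'
#' @param lr,beta1,beta2,eps Adam hyperparameters
#' @param batch_size minibatch size (default 32)
#' @param n_epochs training passes through the data (default 25)
#' @param dropout dropout rate (default 0.30)
#' @param validation_split fraction of training data held out for the
#'   history/early-stopping metrics (default 0.2; 0 disables)
#' @param early_stopping stop when validation AUC has not improved for
#'   `patience` passes and restore the best weights (default `FALSE`)
#' @param patience early-stopping patience (default 6)
#' @param class_weighting apply balanced class weights (default `TRUE`)
#' @param rng_seed integer seed for initialisation, shuffling, dropout and
#'   the validation split
#' @return a `cnn_train_config` list
#' @export
cnn_train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                             eps = 1e-7, batch_size = 32, n_epochs = 25,
                             dropout = 0.30, validation_split = 0.2,
                             early_stopping = FALSE, patience = 6,
                             class_weighting = TRUE, rng_seed = 1) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_size = batch_size, n_epochs = n_epochs,
                 dropout = dropout, validation_split = validation_split,
                 early_stopping = early_stopping, patience = patience,
                 class_weighting = class_weighting, rng_seed = rng_seed),
            class = "cnn_train_config")
}

#' Train the CNN on normalised epochs
#'
#' Trains a per-subject network with seeded minibatch Adam. Input epochs
#' must already be normalised to `[-1, 1]` (see [normalize_minmax()] /
#' [minmax_transform()]; in cross-validation the transform is fitted on
#' the training folds only). The history records the weighted training
#' loss and, if a validation split is held out, validation loss and AUC
#' per pass.
#'
#' @param x numeric array, epochs x channels x samples, normalised
#' @param labels per-epoch class labels (both classes required)
#' @param config a [cnn_train_config()]
#' @param model optionally, a pre-built `cnn_model` to train (defaults to
#'   a fresh seeded build matching the input shape)
#' @return the trained `cnn_model`; `$history` is a data.frame with
#'   columns `epoch`, `loss`, `val_loss`, `val_auc`
#' @export
train_cnn <- function(x, labels, config = cnn_train_config(), model = NULL) {
  assert_that(length(dim(x)) == 3 && dim(x)[1] > 0,
              "x must be a non-empty epochs x channels x samples array")
  y <- as_binary_labels(labels)
  assert_that(length(unique(y)) == 2,
              "both classes must be present in the training set")
  n <- dim(x)[1]
  if (is.null(model)) {
    model <- build_cnn(cnn_spec(n_channels = dim(x)[2], n_samples = dim(x)[3]),
                       seed = config$rng_seed)
  }
  cw <- if (config$class_weighting) class_weights(y) else c("0" = 1, "1" = 1)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$rng_seed, "valsplit"))
  n_val <- floor(config$validation_split * n)
  if (n_val > 0) {
    val_idx <- sort(sample.int(n, n_val))
    # a validation split must contain both classes to score AUC
    if (length(unique(y[val_idx])) < 2) {
      miss <- setdiff(unique(y), y[val_idx])
      swap <- which(y == miss[1])[1]
      val_idx <- sort(c(val_idx[-1], swap))
    }
    train_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer(0)
    train_idx <- seq_len(n)
  }

  cfg <- list(lr = config$lr, beta1 = config$beta1, beta2 = config$beta2,
              eps = config$eps, dropout = config$dropout,
              weight0 = unname(cw["0"]), weight1 = unname(cw["1"]),
              batch_size = as.integer(config$batch_size),
              n_epochs = as.integer(config$n_epochs),
              patience = as.integer(config$patience),
              early_stopping = isTRUE(config$early_stopping),
              rng_seed = as.integer(config$rng_seed %% 2147483647L))
  xc <- aperm(x, c(2, 3, 1))  # channels x samples x epochs for the C++ core
  out <- cnn_train_cpp(model$weights, xc, as.numeric(y),
                       as.integer(train_idx - 1), as.integer(val_idx - 1), cfg)
  model$weights <- out$weights
  model$history <- data.frame(epoch = seq_along(out$loss),
                              loss = out$loss,
                              val_loss = out$val_loss,
                              val_auc = out$val_auc)
  model$stopped_at <- out$stopped_at
  model$config <- config
  model
}

#' Per-epoch class probabilities from a CNN
#'
#' @param model a (trained) `cnn_model`
#' @param x numeric array, epochs x channels x samples, normalised with
#'   the training transform
#' @return numeric vector of probabilities of the syllable class, in
#'   `[0, 1]`; hard labels follow the 0.5 threshold
#' @export
predict_proba <- function(model, x) {
  assert_that(length(dim(x)) == 3, "x must be epochs x channels x samples")
  assert_that(dim(x)[2] == model$spec$n_channels &&
              dim(x)[3] == model$spec$n_samples,
              "input shape does not match the network")
  as.numeric(cnn_predict_cpp(model$weights, aperm(x, c(2, 3, 1))))
}
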