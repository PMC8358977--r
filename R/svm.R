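#' Canonical EEG band definitions
#'
#' Delta, theta and alpha bands as half-open frequency intervals
#' `[low, high)` so adjacent bands never double-count a bin.
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz)
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha"),
             low = c(1, 4, 8), high = c(4, 8, 12),
             stringsAsFactors = FALSE)
}

#' Per-channel band-power features
#'
#' For each epoch and channel, computes a Hann-windowed periodogram (0.5 Hz
#' resolution for 2-s epochs at 100 Hz) and sums the spectral-density bins
#' whose frequency falls in each band's half-open interval. With 60
#' channels and the three canonical bands this yields 180 features per
#' epoch.
#'
#' @param epochs an `epoch_set`
#' @param bands band table as returned by [band_definitions()]
#' @return a `feature_matrix`: list with `values` (epochs x features,
#'   non-negative), `feature_names` (`"chNN_band"`), `n_features`
#' @export
bandpower_features <- function(epochs, bands = band_definitions()) {
  d <- dim(epochs$data)
  ne <- d[1]; nch <- d[2]; ns <- d[3]
  nyq <- epochs$rate / 2
  assert_that(all(bands$high <= nyq),
              "band edge above the Nyquist frequency")
  w <- hann_window(ns)
  scale <- 1 / (epochs$rate * sum(w^2))
  freqs <- seq(0, epochs$rate - epochs$rate / ns, by = epochs$rate / ns)
  half <- seq_len(floor(ns / 2) + 1)
  band_bins <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs[half] >= bands$low[b] & freqs[half] < bands$high[b])
  })
  nb <- nrow(bands)
  values <- matrix(0, ne, nch * nb)
  for (e in seq_len(ne)) {
    seg <- epochs$data[e, , , drop = TRUE] * rep(w, each = nch)  # ch x samples
    sp <- Mod(t(stats::mvfft(t(seg))))^2 * scale                 # periodogram
    sp <- sp[, half, drop = FALSE]
    for (b in seq_len(nb)) {
      values[e, (b - 1) * nch + seq_len(nch)] <-
        rowSums(sp[, band_bins[[b]], drop = FALSE])
    }
  }
  names_ <- as.vector(vapply(seq_len(nb), function(b)
    sprintf("ch%02d_%s", seq_len(nch), bands$name[b]), character(nch)))
  structure(list(values = values, feature_names = names_,
                 n_features = nch * nb, bands = bands),
            class = "feature_matrix")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Fit a PCA reduction on training features and apply it to both sets
#'
#' The projection (and centring) is estimated on the training features
#' only, then applied unchanged to the test features — no information from
#' the test set leaks into the fit.
#'
#' @param train_features,test_features numeric matrices (rows = epochs)
#' @param k number of components to keep (default 30)
#' @return list with `train`, `test` (reduced matrices, `k` columns),
#'   `rotation`, `center`, and `explained_variance` (component variances,
#'   non-increasing)
#' @export
pca_reduce <- function(train_features, test_features, k = 30) {
  assert_that(k <= min(nrow(train_features), ncol(train_features)),
              "k exceeds min(n_train, n_features)")
  fit <- prcomp(train_features, center = TRUE, scale. = FALSE)
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  ctr <- fit$center
  list(train = sweep(train_features, 2, ctr) %*% rot,
       test = sweep(test_features, 2, ctr) %*% rot,
       rotation = rot, center = ctr,
       explained_variance = fit$sdev[seq_len(k)]^2)
}

#' SVM pipeline settings
#'
#' @param k_pca number of principal components (default 30)
#' @param cost SVM regularisation constant (default 1)
#' @param log_transform log-transform and z-score band powers (on training
#'   statistics) before PCA (default `FALSE`: raw band powers go into PCA
#'   with centring only, the literal classical pipeline; the robust
#'   variant tames heavy-tailed power outliers and is kept as an option)
#' @param bands band table (default [band_definitions()])
#' @return an `svm_config` list
#' @export
svm_config <- function(k_pca = 30, cost = 1, log_transform = FALSE,
                       bands = band_definitions()) {
  structure(list(k_pca = k_pca, cost = cost, log_transform = log_transform,
                 bands = bands), class = "svm_config")
}

#' Train a linear SVM on reduced features
#'
#' @param train_reduced numeric matrix of training features (rows = epochs)
#' @param labels per-epoch class labels (both classes must be present)
#' @param cost regularisation constant (default 1)
#' @return a fitted `e1071::svm` model (linear kernel)
#' @export
train_svm <- function(train_reduced, labels, cost = 1) {
  y <- factor(as_binary_labels(labels), levels = c(0, 1))
  assert_that(nlevels(droplevels(y)) == 2,
              "both classes must be present in the training data")
  e1071::svm(x = train_reduced, y = y, kernel = "linear", cost = cost,
             scale = FALSE)
}

#' Signed decision values for a fitted SVM
#'
#' @param classifier a model from [train_svm()]
#' @param test_reduced feature matrix to score
#' @return numeric decision values oriented so larger = more
#'   syllable-like; hard labels follow the sign
#' @export
predict_score <- function(classifier, test_reduced) {
  pr <- predict(classifier, test_reduced, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the decision value towards its first training class;
  # flip if that class is the negative one so larger = class "1"
  if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
}

# --- internal: full band-power -> standardise -> PCA -> SVM pipeline -----

svm_pipeline_fit <- function(train_epochs, config = svm_config()) {
  feats <- bandpower_features(train_epochs, config$bands)$values
  if (config$log_transform) {
    feats <- log(feats + 1e-12)
    ctr <- colMeans(feats)
    scl <- apply(feats, 2, sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(feats))
    # one global scalar (mean training band power) for numerical
    # conditioning of the solver; relative feature geometry is untouched
    scl <- rep(max(mean(feats), 1e-12), ncol(feats))
  }
  feats <- sweep(sweep(feats, 2, ctr), 2, scl, "/")
  k <- min(config$k_pca, nrow(feats) - 1, ncol(feats))
  pca <- pca_reduce(feats, feats[0, , drop = FALSE], k = k)
  model <- train_svm(pca$train, train_epochs$labels, cost = config$cost)
  list(model = model, center = ctr, scale = scl, pca = pca, config = config)
}

svm_pipeline_score <- function(fit, test_epochs) {
  feats <- bandpower_features(test_epochs, fit$config$bands)$values
  if (fit$config$log_transform) feats <- log(feats + 1e-12)
  feats <- sweep(sweep(feats, 2, fit$center), 2, fit$scale, "/")
  red <- sweep(feats, 2, fit$pca$center) %*% fit$pca$rotation
  predict_score(fit$model, red)
}

# default-argument helper: avoids the argument name shadowing the
# constructor during lazy default evaluation
default_svm_config <- function() svm_config()
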