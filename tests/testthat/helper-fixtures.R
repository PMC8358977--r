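# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Small labelled epoch set with an optional class-dependent signal:
# syllable epochs get `signal` added to a fixed time/channel patch.
tiny_epochs <- function(n = 40, nch = 8, ns = 24, seed = 1, signal = 0,
                        rate = 100, labels = NULL) {
  set.seed(seed)
  x <- array(rnorm(n * nch * ns), c(n, nch, ns))
  if (is.null(labels)) labels <- rep(c("drum", "syllable"), length.out = n)
  if (signal != 0) {
    idx <- labels == "syllable"
    x[idx, , 5:min(10, ns)] <- x[idx, , 5:min(10, ns)] + signal
  }
  epoch_set(x, labels, rate = rate, epoch_length = ns / rate)
}

# Scaled-down generator configuration for unit tests: fewer channels and
# repetitions, everything else at the study defaults.
small_config <- function(n_repetitions = 40, n_channels = 16, n_usable = 12,
                         seed = 1, ...) {
  extra <- list(...)
  if (!"artifact_channel_count" %in% names(extra)) {
    extra$artifact_channel_count <- 2
  }
  do.call(generator_config,
          c(list(n_channels = n_channels, n_usable = n_usable,
                 n_repetitions = n_repetitions, rng_seed = seed), extra))
}

# Independent AUC oracle: trapezoidal integration of the empirical ROC
# curve (thresholds swept over all distinct scores, ties handled by the
# simultaneous step).
auc_trapezoid <- function(labels, scores) {
  y <- as.integer(labels == 1)
  ths <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- c(0, vapply(ths, function(t) sum(scores >= t & y == 1) / n1, numeric(1)))
  fpr <- c(0, vapply(ths, function(t) sum(scores >= t & y == 0) / n0, numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Independent brute-force significance threshold: enumerate the exact
# binomial upper tail from binomial coefficients.
threshold_bruteforce <- function(n, alpha) {
  tail_p <- function(c) sum(choose(n, c:n)) / 2^n
  for (c in 0:n) {
    if (tail_p(c) < alpha) return(100 * (c - 1) / n)
  }
  NA_real_
}
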