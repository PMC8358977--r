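#' @useDynLib rhythmdecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats density approx prcomp rnorm runif sd var dist
#'   pbinom pnorm pwilcox fft mvfft aggregate predict
#' @importFrom utils write.csv read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' A single master seed fans out into independent sub-streams for every
#' subject, session and stage, so any subset of a cohort can be regenerated
#' without running the rest. The derivation hashes the master seed together
#' with a string tag through a small multiplicative congruential mix and
#' returns a value in `[0, 2^31 - 2]`.
#'
#' @param seed master integer seed
#' @param ... character or numeric tags identifying the sub-stream
#'   (e.g. subject id, session label, stage name)
#' @return an integer usable with [set.seed()]
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 48271) %% 2147483647)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Evenly spaced, deterministic sensor layout: Fibonacci (golden-angle)
# spiral on the unit sphere. Stands in for a montage file; only relative
# distances matter (neighbour finding, spatial mixing).
sphere_spiral_positions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Construct a continuous EEG recording object
#'
#' The package's container for continuous multi-channel EEG: a channels x
#' samples matrix in microvolts plus sampling rate, channel metadata and a
#' stimulus-event table.
#'
#' @param data numeric matrix, channels x samples (microvolts)
#' @param rate sampling rate in Hz
#' @param channel_labels character vector, one per channel
#' @param channel_positions numeric matrix (channels x 3) of unit-sphere
#'   sensor coordinates
#' @param events data.frame with columns `onset_sample` (0-based sample
#'   index at `rate`) and `label` (`"drum"` or `"syllable"`)
#' @param site_label recording-site identifier (e.g. `"A"`, `"B"`)
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(data, rate, channel_labels = NULL,
                          channel_positions = NULL,
                          events = empty_events(), site_label = "A") {
  assert_that(is.matrix(data) && is.numeric(data),
              "`data` must be a numeric channels x samples matrix")
  assert_that(is.numeric(rate) && length(rate) == 1 && rate > 0,
              "`rate` must be a positive scalar (Hz)")
  nch <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- sprintf("E%02d", seq_len(nch))
  if (is.null(channel_positions)) channel_positions <- sphere_spiral_positions(nch)
  assert_that(length(channel_labels) == nch, "one label per channel required")
  assert_that(nrow(channel_positions) == nch, "one position per channel required")
  if (nrow(events) > 0) {
    assert_that(all(events$onset_sample >= 0 & events$onset_sample < ncol(data)),
                "all event onsets must lie within [0, n_samples)")
    assert_that(all(diff(events$onset_sample) > 0),
                "event onsets must be strictly increasing")
  }
  structure(list(data = data, rate = rate,
                 channel_labels = channel_labels,
                 channel_positions = channel_positions,
                 events = events, site_label = site_label),
            class = "eeg_recording")
}

empty_events <- function() {
  data.frame(onset_sample = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events, site %s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$events), x$site_label))
  invisible(x)
}

#' Construct an epoch set
#'
#' Fixed-length stimulus-locked epochs stacked into an epochs x channels x
#' samples array, with per-epoch class labels and an optional rejection mask
#' filled in by [reject_improbable_epochs()].
#'
#' @param data numeric array, epochs x channels x samples (microvolts)
#' @param labels character/factor vector of per-epoch class labels
#'   (`"drum"` / `"syllable"`)
#' @param rate sampling rate in Hz
#' @param epoch_length epoch duration in seconds
#' @param reject_mask logical per-epoch vector (`TRUE` = improbable), or
#'   `NULL` if rejection has not been run
#' @param channel_labels optional channel names
#' @param channel_positions optional channels x 3 position matrix
#' @return an object of class `epoch_set`
#' @export
epoch_set <- function(data, labels, rate, epoch_length,
                      reject_mask = NULL, channel_labels = NULL,
                      channel_positions = NULL) {
  assert_that(length(dim(data)) == 3,
              "`data` must be a 3-d array: epochs x channels x samples")
  assert_that(dim(data)[1] == length(labels),
              "one label per epoch required")
  assert_that(abs(dim(data)[3] - epoch_length * rate) < 1e-9,
              "samples per epoch must equal epoch_length * rate exactly")
  labels <- factor(as.character(labels), levels = c("drum", "syllable"))
  if (!is.null(reject_mask))
    assert_that(length(reject_mask) == dim(data)[1],
                "reject_mask must have one entry per epoch")
  structure(list(data = data, labels = labels, rate = rate,
                 epoch_length = epoch_length, reject_mask = reject_mask,
                 channel_labels = channel_labels,
                 channel_positions = channel_positions),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  rej <- if (is.null(x$reject_mask)) "not assessed"
         else sprintf("%.1f%% flagged", 100 * mean(x$reject_mask))
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (%s)\n",
              d[1], d[2], d[3], x$rate, rej))
  print(table(x$labels))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x an `epoch_set`
#' @return integer epoch count
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Subset an epoch set by epoch index
#' @param x an `epoch_set`
#' @param i integer or logical epoch index
#' @param ... unused
#' @return an `epoch_set` containing the selected epochs
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[i, , , drop = FALSE], x$labels[i], x$rate, x$epoch_length,
            reject_mask = if (!is.null(x$reject_mask)) x$reject_mask[i],
            channel_labels = x$channel_labels,
            channel_positions = x$channel_positions)
}

#' Combine epoch sets (e.g. a subject's drum and syllable sessions)
#' @param ... `epoch_set` objects with identical geometry and rate
#' @return a single concatenated `epoch_set`
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  assert_that(length(sets) >= 1, "at least one epoch_set required")
  d <- dim(sets[[1]]$data)
  for (s in sets) {
    assert_that(all(dim(s$data)[2:3] == d[2:3]) && s$rate == sets[[1]]$rate,
                "epoch sets must share channels, samples and rate")
  }
  data <- do.call(abind3, lapply(sets, function(s) s$data))
  labels <- unlist(lapply(sets, function(s) as.character(s$labels)))
  masks <- lapply(sets, function(s) s$reject_mask)
  mask <- if (all(!vapply(masks, is.null, logical(1)))) unlist(masks) else NULL
  epoch_set(data, labels, sets[[1]]$rate, sets[[1]]$epoch_length,
            reject_mask = mask, channel_labels = sets[[1]]$channel_labels,
            channel_positions = sets[[1]]$channel_positions)
}

# rbind for 3-d arrays along the first (epoch) dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
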