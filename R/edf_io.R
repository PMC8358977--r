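#' Write a recording to a European Data Format (EDF) file
#'
#' Minimal EDF writer: 16-bit samples, physical units microvolts, 1-second
#' data records. Per-channel physical min/max are taken from the data, so
#' the quantisation step is (max - min) / 65535 per channel. A recording
#' whose length is not a whole number of seconds is zero-padded to the
#' next record boundary. Events are not embedded; they travel in a TSV
#' sidecar (see [write_events_tsv()]).
#'
#' @param recording an `eeg_recording` with an integer sampling rate
#' @param path output file path (conventionally `.edf`)
#' @return invisibly, `path`
#' @export
write_edf <- function(recording, path) {
  assert_that(abs(recording$rate - round(recording$rate)) < 1e-9,
              "EDF writer requires an integer sampling rate")
  rate <- round(recording$rate)
  x <- recording$data
  nch <- nrow(x)
  n <- ncol(x)
  n_rec <- ceiling(n / rate)
  if (n_rec * rate > n) {
    x <- cbind(x, matrix(0, nch, n_rec * rate - n))
  }
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  # widen the stored bounds so their 4-significant-digit header encoding
  # can never round inward and clip samples at the extremes
  margin <- 0.002 * (pmax_ - pmin_)
  pmin_ <- pmin_ - margin
  pmax_ <- pmax_ + margin
  dmin <- -32768; dmax <- 32767

  pad <- function(s, width) {
    s <- substr(s, 1, width)
    formatC(s, width = -width, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("X X X X", 80),
                pad(paste("Startdate 01-JAN-2026 synthetic site",
                          recording$site_label), 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(as.character(256 * (nch + 1)), 8), pad("", 44),
                pad(as.character(n_rec), 8), pad("1", 8),
                pad(as.character(nch), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(recording$channel_labels, 16)
  field(rep("AgAgCl electrode", nch), 80)
  field(rep("uV", nch), 8)
  field(formatC(pmin_, digits = 4, format = "g"), 8)
  field(formatC(pmax_, digits = 4, format = "g"), 8)
  field(rep(as.character(dmin), nch), 8)
  field(rep(as.character(dmax), nch), 8)
  field(rep("", nch), 80)
  field(rep(as.character(rate), nch), 8)
  field(rep("", nch), 32)

  # re-read the physical bounds exactly as the 8-char header will store them
  pmin_h <- as.numeric(formatC(pmin_, digits = 4, format = "g"))
  pmax_h <- as.numeric(formatC(pmax_, digits = 4, format = "g"))
  gain <- (pmax_h - pmin_h) / (dmax - dmin)
  dig <- round(sweep(sweep(x, 1, pmin_h), 1, gain, "/")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  out <- integer(nch * rate * n_rec)
  at <- 0
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * rate + 1):(r * rate)
    block <- t(dig[, cols, drop = FALSE])          # samples x channels
    out[at + seq_len(rate * nch)] <- as.integer(block)
    at <- at + rate * nch
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the plain 16-bit EDF layout (uniform sampling rate across
#' signals, no annotations channel).
#'
#' @param path EDF file path
#' @return an `eeg_recording` (events empty; see [read_events_tsv()])
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)                    # physical dimension
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nch)) rd(32)
  assert_that(length(unique(spr)) == 1,
              "reader supports a uniform sampling rate only")
  rate <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little")
  data <- matrix(0, nch, n_rec * spr[1])
  at <- 0
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[at + seq_len(spr[1] * nch)], spr[1], nch)
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
    at <- at + spr[1] * nch
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- sweep(sweep(data, 1, dmin, "-") * gain, 1, pmin_, "+")
  site <- sub(".*site ", "", rec_id)
  eeg_recording(data, rate, channel_labels = labels,
                site_label = if (nchar(site) == 1) site else "A")
}

#' Write / read the stimulus-event sidecar
#'
#' Tab-separated file with columns `onset_sample` (0-based, at the
#' recording's native rate) and `label` (`drum` / `syllable`).
#'
#' @param events event data.frame (as in an `eeg_recording`)
#' @param path TSV file path
#' @return `read_events_tsv` returns the event data.frame
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  ev$onset_sample <- as.integer(ev$onset_sample)
  ev
}

#' Write / read one subject's session pair as EDF + sidecars
#'
#' The on-disk layout per subject is
#' `<dir>/<id>_drum.edf`, `<dir>/<id>_drum_events.tsv`, the same pair for
#' the syllable session, and `<dir>/<id>_manifest.json` holding the
#' subject's ground-truth contamination manifests and metadata.
#'
#' @param subject one element of a [generate_cohort()] list
#' @param dir output directory (created if needed)
#' @param id subject identifier used in file names
#' @return `read_subject_edf` returns a subject list in the cohort layout
#' @export
write_subject_edf <- function(subject, dir, id = subject$subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in c("drum", "syllable")) {
    rec <- subject[[cl]]
    write_edf(rec, file.path(dir, sprintf("%s_%s.edf", id, cl)))
    write_events_tsv(rec$events,
                     file.path(dir, sprintf("%s_%s_events.tsv", id, cl)))
  }
  jsonlite::write_json(
    list(subject_id = id, snr = subject$snr, site = subject$site,
         manifest_drum = subject$manifest_drum,
         manifest_syllable = subject$manifest_syllable),
    file.path(dir, sprintf("%s_manifest.json", id)),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_subject_edf
#' @export
read_subject_edf <- function(dir, id) {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_manifest.json", id)),
                              simplifyVector = TRUE)
  sessions <- lapply(c("drum", "syllable"), function(cl) {
    rec <- read_edf(file.path(dir, sprintf("%s_%s.edf", id, cl)))
    rec$events <- read_events_tsv(
      file.path(dir, sprintf("%s_%s_events.tsv", id, cl)))
    rec$site_label <- meta$site %||% rec$site_label
    rec
  })
  list(subject_id = id, snr = meta$snr, site = meta$site,
       drum = sessions[[1]], syllable = sessions[[2]],
       manifest_drum = meta$manifest_drum,
       manifest_syllable = meta$manifest_syllable)
}
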