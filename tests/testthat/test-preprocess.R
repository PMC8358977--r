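make_rec <- function(data, rate = 1000) eeg_recording(data, rate)

test_that("band-pass filter suppresses out-of-band and passes in-band components", {
  rate <- 1000
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  rms <- function(v) sqrt(mean(v^2))
  # 50 Hz tone: above the 45 Hz edge
  rec <- make_rec(rbind(sin(2 * pi * 50 * t), sin(2 * pi * 50 * t)))
  out <- bandpass(rec, 0.5, 45)
  expect_lt(rms(out$data[1, ]), 0.1 * rms(rec$data[1, ]))
  # DC: below the 0.5 Hz edge (judge the central half, away from edges)
  rec <- make_rec(matrix(1, 2, length(t)))
  out <- bandpass(rec, 0.5, 45)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_lt(rms(out$data[1, mid]), 0.1)
  # 10 Hz tone: passband
  rec <- make_rec(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)))
  out <- bandpass(rec, 0.5, 45)
  expect_lt(abs(rms(out$data[1, ]) - rms(rec$data[1, ])) / rms(rec$data[1, ]), 0.05)
  expect_error(bandpass(rec, 45, 0.5), "band edges")
})

test_that("unused channels are dropped, order preserved", {
  set.seed(1)
  rec <- make_rec(matrix(rnorm(64 * 100), 64))
  out <- drop_unused_channels(rec)
  expect_equal(nrow(out$data), 60)
  expect_identical(out$data, rec$data[1:60, ])
  rec60 <- make_rec(matrix(rnorm(60 * 100), 60))
  expect_identical(drop_unused_channels(rec60)$data, rec60$data)
  expect_error(drop_unused_channels(make_rec(matrix(0, 32, 100))), "32 channels")
})

test_that("downsampling keeps in-band content, rescales lengths and events", {
  rate <- 1000
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  x <- rbind(sin(2 * pi * 5 * t), cos(2 * pi * 5 * t))
  rec <- eeg_recording(x, rate,
                       events = data.frame(onset_sample = c(500L, 2000L),
                                           label = "drum"))
  out <- downsample(rec, 100)
  expect_equal(out$rate, 100)
  expect_equal(ncol(out$data), 1000)
  expect_equal(out$events$onset_sample, c(50L, 200L))
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(out$data[1, ]) - rms(x[1, ])) / rms(x[1, ]), 0.05)
  expect_error(downsample(out, 100), "below the current rate")
})

test_that("bad-channel detection flags contaminated channels only", {
  set.seed(42)
  n <- 5000
  x <- matrix(rnorm(60 * n), 60)
  x[13, ] <- 0.001 * rnorm(n)                       # flat channel
  x[47, ] <- rnorm(n)
  hits <- sample.int(n, 40)
  x[47, hits] <- x[47, hits] + 12 * sample(c(-1, 1), 40, TRUE)  # heavy transients
  rec <- make_rec(x, rate = 100)
  rep_ <- detect_bad_channels(rec)
  expect_setequal(rep_$flagged, c(13, 47))

  # identical channels: degenerate, no flags
  same <- make_rec(matrix(rep(rnorm(n), each = 8), 8, n, byrow = FALSE), 100)
  same$data <- matrix(rep(rnorm(n), 8), 8, n, byrow = TRUE)
  expect_length(detect_bad_channels(same)$flagged, 0)

  # threshold Inf disables flagging
  expect_length(detect_bad_channels(rec, threshold = Inf)$flagged, 0)
})

test_that("interpolation averages the nearest good neighbours", {
  set.seed(3)
  x <- matrix(rnorm(8 * 500), 8)
  pos <- rhythmdecode:::sphere_spiral_positions(8)
  rec <- eeg_recording(x, 100, channel_positions = pos)
  # closed form: flagged channel becomes the mean of its 4 nearest others
  rep_ <- list(flagged = 3L,
               interpolation_map = list(`3` = c(1L, 2L, 4L, 5L)))
  out <- interpolate_channels(rec, rep_)
  expect_equal(out$data[3, ], colMeans(x[c(1, 2, 4, 5), ]))
  expect_identical(out$data[-3, ], x[-3, ])
  # identical neighbours carrying s(t): replacement equals s(t)
  s_t <- sin(seq_len(500) / 10)
  x2 <- x; for (ch in c(1, 2, 4, 5)) x2[ch, ] <- s_t
  rec2 <- eeg_recording(x2, 100, channel_positions = pos)
  expect_equal(interpolate_channels(rec2, rep_)$data[3, ], s_t)
  # averaging cannot exceed the largest neighbour variance
  expect_lte(var(out$data[3, ]), max(apply(x[c(1, 2, 4, 5), ], 1, var)))
  # no flags: unchanged
  expect_identical(interpolate_channels(rec, integer(0))$data, x)
})

test_that("average re-referencing zeroes the instantaneous channel mean", {
  set.seed(4)
  x <- matrix(rnorm(6 * 300), 6)
  out <- rereference_average(make_rec(x, 100))
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # invariant to adding a common offset
  out2 <- rereference_average(make_rec(x + 7.5, 100))
  expect_equal(out$data, out2$data)
  # two-channel closed form
  ab <- make_rec(rbind(x[1, ], x[2, ]), 100)
  outab <- rereference_average(ab)
  expect_equal(outab$data[1, ], (x[1, ] - x[2, ]) / 2)
  expect_equal(outab$data[2, ], (x[2, ] - x[1, ]) / 2)
})

test_that("epoching cuts non-overlapping stimulus-locked windows with 4 beats each", {
  cfg <- small_config(n_repetitions = 40, seed = 6)
  rec <- generate_session(cfg, "drum", seed = 6)
  rec <- downsample(drop_unused_channels(rec, 12), 100)
  ep <- epoch_recording(rec, 2)
  expect_equal(n_epochs(ep), 10)          # 20 s / 2 s
  expect_equal(dim(ep$data)[2:3], c(12, 200))
  expect_true(all(ep$labels == "drum"))
  # each epoch window contains exactly 4 stimulus onsets
  onsets <- rec$events$onset_sample
  starts <- onsets[seq(1, length(onsets), by = 4)]
  for (s in starts) {
    expect_equal(sum(onsets >= s & onsets < s + 200), 4)
  }
  # a recording shorter than one epoch yields zero epochs with a warning
  short <- eeg_recording(matrix(0, 4, 50), 100,
                         events = data.frame(onset_sample = 0L, label = "drum"))
  expect_warning(ep0 <- epoch_recording(short, 2), "0 epochs")
  expect_equal(n_epochs(ep0), 0)
  expect_error(epoch_recording(eeg_recording(matrix(0, 4, 500), 100), 2),
               "no events")
})

test_that("improbable-epoch rejection separates transient-hit epochs from clean ones", {
  set.seed(8)
  n <- 60; nch <- 8; ns <- 200
  x <- array(rnorm(n * nch * ns), c(n, nch, ns))
  hit <- sort(sample.int(n, 9))
  for (e in hit) {
    at <- sample(30:150, 1)
    x[e, , at:(at + 30)] <- x[e, , at:(at + 30)] + 10
  }
  ep <- epoch_set(x, rep(c("drum", "syllable"), each = n / 2), 100, 2)
  out <- reject_improbable_epochs(ep)
  expect_true(all(out$reject_mask[hit]))
  expect_lt(mean(out$reject_mask[-hit]), 0.10)

  # homogeneous Gaussian epochs: flag rate below the 3-SD tail budget
  ep0 <- epoch_set(array(rnorm(100 * nch * ns), c(100, nch, ns)),
                   rep(c("drum", "syllable"), 50), 100, 2)
  out0 <- reject_improbable_epochs(ep0, z_single = 3, z_all = 3)
  expect_lt(mean(out0$reject_mask), 0.05)

  # clean and rejected views partition the epoch set
  expect_equal(n_epochs(out[out$reject_mask]) + n_epochs(out[!out$reject_mask]),
               n_epochs(out))
})

test_that("the full chain runs in the documented order with session-harmonised interpolation", {
  cfg <- small_config(n_repetitions = 60, seed = 10, artifact_channel_count = 2)
  subj <- generate_cohort(1, cfg)[[1]]
  pp <- preprocess_subject(subj, keep_channels = 12)
  expect_s3_class(pp$epochs, "epoch_set")
  expect_equal(dim(pp$epochs$data)[2:3], c(12, 200))
  expect_equal(n_epochs(pp$epochs), 2 * 15)
  expect_equal(as.vector(table(pp$epochs$labels)), c(15, 15))
  # labels constant within each session block
  expect_equal(as.character(pp$epochs$labels),
               rep(c("drum", "syllable"), each = 15))
  # both sessions' flagged channels are interpolated in both sessions
  expect_true(all(pp$reports$drum$flagged %in% pp$interpolated))
  expect_true(all(pp$reports$syllable$flagged %in% pp$interpolated))
  # epochs have 200 samples = 2 s x 100 Hz exactly
  expect_equal(pp$epochs$epoch_length * pp$epochs$rate, 200)
})

test_that("a contamination-free session passes preprocessing nearly untouched", {
  # trial variability off: this isolates the specificity of the flagging
  cfg <- small_config(n_repetitions = 120, seed = 12,
                      artifact_channel_count = 0, artifact_transient_rate = 0,
                      evoked_amp_sd = 0, evoked_jitter_ms = 0)
  subj <- generate_cohort(1, cfg)[[1]]
  pp <- preprocess_subject(subj, keep_channels = 12)
  # an outlier criterion over finitely many channels can false-flag by
  # chance; specificity here means at most one channel touched
  expect_lte(length(pp$interpolated), 1)
  expect_lte(mean(pp$epochs$reject_mask), 0.05)
})
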