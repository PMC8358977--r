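test_that("templates are deterministic, class-distinct and fit the inter-onset interval", {
  t_drum <- make_template("drum", seed = 1)
  t_syll <- make_template("syllable", seed = 1)
  expect_identical(t_drum$waveform, make_template("drum", seed = 1)$waveform)
  expect_false(identical(t_drum$waveform, make_template("drum", seed = 2)$waveform))
  expect_lt(t_drum$duration, 0.5)
  expect_lt(t_syll$duration, 0.5)
  expect_error(make_template("bell"), "unknown class_label")

  # band-power signatures of the two classes differ well beyond the
  # numerical floor of a weak-noise epoch (computed with the SVM path's
  # own feature extractor at the analysis rate)
  embed_template <- function(tmpl) {
    wave100 <- tmpl$waveform[seq(1, length(tmpl$waveform), by = 10)]
    x <- array(0, c(1, 60, 200))
    for (beat in 0:3) {
      idx <- beat * 50 + seq_along(wave100)
      x[1, , idx] <- x[1, , idx] +
        tmpl$spatial_profile[1:60] %o% wave100
    }
    x
  }
  ep <- epoch_set(rhythmdecode:::abind3(embed_template(t_drum), embed_template(t_syll)),
                  c("drum", "syllable"), rate = 100, epoch_length = 2)
  bp <- bandpower_features(ep)
  per_band <- function(row) tapply(bp$values[row, ],
                                   rep(c("delta", "theta", "alpha"), each = 60), sum)
  set.seed(1)
  noise_ep <- epoch_set(array(rnorm(60 * 200, sd = 1e-3), c(1, 60, 200)),
                        "drum", rate = 100, epoch_length = 2)
  floor_power <- max(bandpower_features(noise_ep)$values)
  expect_gt(max(abs(per_band(1) - per_band(2))), 3 * floor_power)
})

test_that("background noise has the expected shape, spectral slope and determinism", {
  bg <- generate_background(16, 20, 1000, seed = 5)
  expect_equal(dim(bg$data), c(16, 20000))
  expect_equal(nrow(bg$events), 0)
  expect_identical(bg$data, generate_background(16, 20, 1000, seed = 5)$data)
  expect_false(identical(bg$data, generate_background(16, 20, 1000, seed = 6)$data))
  expect_error(generate_background(16, -1, 1000), "duration")

  # log-log slope of the channel-averaged spectrum in 1-40 Hz near -1
  n <- ncol(bg$data)
  freqs <- seq(0, 1000 / 2, by = 1000 / n)
  spec <- rowMeans(vapply(seq_len(nrow(bg$data)), function(ch) {
    Mod(fft(bg$data[ch, ]))[seq_along(freqs)]^2
  }, numeric(length(freqs))))
  keep <- freqs >= 1 & freqs <= 40
  fit <- lm(log(spec[keep]) ~ log(freqs[keep]))
  expect_gt(coef(fit)[2], -1.5)
  expect_lt(coef(fit)[2], -0.5)
})

test_that("sessions carry exactly n_repetitions equally spaced events", {
  cfg <- small_config(n_repetitions = 40, seed = 2)
  rec <- generate_session(cfg, "drum", seed = 2)
  expect_equal(nrow(rec$events), 40)
  expect_true(all(diff(rec$events$onset_sample) == 500))
  expect_equal(rec$events$onset_sample[1], 0)
  expect_equal(ncol(rec$data), 40 / 2 * 1000)
  expect_true(all(rec$events$label == "drum"))
})

test_that("zero-SNR sessions equal the background alone, events still marked", {
  cfg <- small_config(n_repetitions = 20, seed = 7, snr = 0)
  rec <- generate_session(cfg, "syllable", seed = 7)
  bg <- generate_background(16, 10, 1000,
                            seed = derive_seed(7, "bg", "syllable"),
                            rms = cfg$background_rms)
  expect_identical(rec$data, bg$data)
  expect_equal(nrow(rec$events), 20)
})

test_that("the stimulus-locked average converges to the evoked template", {
  # variability disabled: this checks averaging convergence of the mean
  cfg <- small_config(n_repetitions = 300, n_channels = 8, n_usable = 8,
                      seed = 4, snr = 1, evoked_amp_sd = 0, evoked_jitter_ms = 0)
  tmpl <- make_template("syllable", n_channels = 8, seed = 4,
                        class_sep = cfg$class_sep)
  rec <- generate_session(cfg, "syllable", seed = 4)
  L <- length(tmpl$waveform)
  ch <- which.max(tmpl$spatial_profile)
  avg_over <- function(n_use) {
    on <- rec$events$onset_sample[seq_len(n_use)]
    rowMeans(vapply(on, function(o) rec$data[ch, (o + 1):(o + L)], numeric(L)))
  }
  r_full <- cor(avg_over(300), tmpl$waveform)
  r_small <- cor(avg_over(50), tmpl$waveform)
  expect_gt(r_full, 0.8)
  expect_gt(r_full, r_small)   # more repetitions, cleaner average
})

test_that("artifact injection matches its manifest and its amplitude contract", {
  cfg <- small_config(n_repetitions = 60, seed = 9,
                      artifact_channel_count = 2,
                      artifact_transient_rate = 6)
  rec <- generate_session(cfg, "drum", seed = 9)
  out <- inject_artifacts(rec, cfg, seed = 9)
  expect_length(out$manifest$bad_channels, 2)
  expect_true(all(out$manifest$bad_channels <= cfg$n_usable))
  expect_equal(length(out$manifest$transient_onsets),
               round(6 * ncol(rec$data) / 1000 / 60))

  # transient peak amplitude >= 10x background RMS on unaffected channels
  good <- setdiff(seq_len(16), out$manifest$bad_channels)
  delta <- out$recording$data[good, ] - rec$data[good, ]
  expect_gte(max(abs(delta)), 10 * sqrt(mean(rec$data^2)))

  # no artifacts configured -> identity
  cfg0 <- small_config(n_repetitions = 20, seed = 9,
                       artifact_channel_count = 0,
                       artifact_transient_rate = 0)
  rec0 <- generate_session(cfg0, "drum", seed = 9)
  out0 <- inject_artifacts(rec0, cfg0, seed = 9)
  expect_identical(out0$recording$data, rec0$data)
  expect_length(out0$manifest$bad_channels, 0)
  expect_length(out0$manifest$transient_onsets, 0)
})

test_that("cohorts are reproducible, subject-varied and share bad channels within subject", {
  cfg <- small_config(n_repetitions = 20, seed = 11, subject_snr_spread = 0.3)
  co <- generate_cohort(3, cfg)
  expect_length(co, 3)
  expect_equal(vapply(co, `[[`, character(1), "subject_id"),
               c("s01", "s02", "s03"))
  co2 <- generate_cohort(3, cfg)
  expect_identical(co[[2]]$drum$data, co2[[2]]$drum$data)
  # per-subject SNR varies under a positive spread
  expect_gt(sd(vapply(co, `[[`, numeric(1), "snr")), 0)
  # electrode problems persist across a subject's two sessions
  for (s in co) {
    expect_identical(s$manifest_drum$bad_channels,
                     s$manifest_syllable$bad_channels)
  }
  # sessions differ across subjects
  expect_false(identical(co[[1]]$drum$data, co[[2]]$drum$data))
})

test_that("site-B subjects carry the extra noise floor and the site label", {
  cfg <- small_config(n_repetitions = 20, seed = 13, site_b_count = 1, snr = 0,
                      artifact_channel_count = 0, artifact_transient_rate = 0)
  co <- generate_cohort(3, cfg)
  expect_equal(vapply(co, `[[`, character(1), "site"), c("A", "A", "B"))
  expect_equal(co[[3]]$drum$site_label, "B")
  # the added stationary floor raises broadband power above site A's
  pwr <- vapply(co, function(s) mean(s$drum$data^2), numeric(1))
  expect_gt(pwr[3], 1.05 * max(pwr[1:2]))
})
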