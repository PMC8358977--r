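#' Configuration for the synthetic EEG cohort generator
#'
#' Defines the study conditions the simulator emulates: two ~16-minute
#' sessions per subject (one per stimulus class), stimuli repeated at a
#' constant 2 Hz so that each full session contains 2000 repetitions,
#' recorded from a 64-channel net (channels 61-64 unused) at 1000 Hz, with
#' stimulus-locked class-specific evoked responses embedded in spatially
#' mixed 1/f background noise and artifact contamination (bad channels and
#' high-amplitude transients).
#'
#' @param n_channels number of recorded channels (default 64; the last
#'   `n_channels - n_usable` are "unused" and dropped during preprocessing)
#' @param n_usable number of usable channels (default 60)
#' @param native_rate native sampling rate in Hz (default 1000)
#' @param stim_rate stimulus repetition rate in Hz (default 2)
#' @param n_repetitions stimulus repetitions per session (default 2000;
#'   session duration = `n_repetitions / stim_rate` seconds)
#' @param snr evoked-to-background RMS ratio of the stimulus-locked
#'   response, measured over the template's support (default 1.5)
#' @param subject_snr_spread SD of the per-subject log-normal SNR jitter
#'   (default 0.3, on the log scale); 0 gives identical subjects
#' @param background_rms background noise RMS in microvolts (default 20)
#' @param class_sep fraction of evoked-template power that is
#'   class-specific (default 0.8); the remainder is a common auditory
#'   response shared by both stimuli, so class separability is graded
#' @param evoked_amp_sd SD of the per-repetition log-normal amplitude
#'   variability of the evoked response (default 0.3, log scale)
#' @param evoked_jitter_ms half-width (ms) of the uniform per-repetition
#'   latency jitter of the evoked response (default 10)
#' @param artifact_channel_count number of channels replaced by flat or
#'   noisy traces per session (default 10)
#' @param artifact_transient_rate high-amplitude transient rate in
#'   events/minute (default 8)
#' @param artifact_transient_gain transient peak amplitude as a multiple
#'   of background RMS (default 12)
#' @param site_b_count number of cohort subjects assigned to recording
#'   site B, which carries an additional stationary noise floor (default 0)
#' @param site_b_noise_rms RMS (microvolts) of site B's added noise floor
#' @param rng_seed master seed; every subject/session sub-stream is derived
#'   from it with [derive_seed()]
#' @return a `generator_config` list
#' @export
generator_config <- function(n_channels = 64, n_usable = 60,
                             native_rate = 1000, stim_rate = 2,
                             n_repetitions = 2000,
                             snr = 1.5, subject_snr_spread = 0.3,
                             class_sep = 0.8, evoked_amp_sd = 0.3,
                             evoked_jitter_ms = 10,
                             background_rms = 20,
                             artifact_channel_count = 10,
                             artifact_transient_rate = 8,
                             artifact_transient_gain = 12,
                             site_b_count = 0, site_b_noise_rms = 5,
                             rng_seed = 1) {
  assert_that(n_repetitions >= 1, "n_repetitions must be at least 1")
  assert_that(snr >= 0, "snr must be non-negative")
  assert_that(native_rate > 0 && stim_rate > 0, "rates must be positive")
  assert_that(n_usable <= n_channels, "n_usable cannot exceed n_channels")
  assert_that(artifact_channel_count < n_channels,
              "artifact_channel_count must be below n_channels")
  spacing <- native_rate / stim_rate
  assert_that(abs(spacing - round(spacing)) < 1e-9,
              "native_rate must be an integer multiple of stim_rate")
  assert_that(class_sep >= 0 && class_sep <= 1,
              "class_sep must lie in [0, 1]")
  structure(list(n_channels = n_channels, n_usable = n_usable,
                 native_rate = native_rate, stim_rate = stim_rate,
                 n_repetitions = n_repetitions, snr = snr,
                 subject_snr_spread = subject_snr_spread,
                 class_sep = class_sep, evoked_amp_sd = evoked_amp_sd,
                 evoked_jitter_ms = evoked_jitter_ms,
                 background_rms = background_rms,
                 artifact_channel_count = artifact_channel_count,
                 artifact_transient_rate = artifact_transient_rate,
                 artifact_transient_gain = artifact_transient_gain,
                 site_b_count = site_b_count,
                 site_b_noise_rms = site_b_noise_rms,
                 rng_seed = rng_seed),
            class = "generator_config")
}

#' Class-specific evoked-response template
#'
#' Models the *neural* response to one stimulus repetition directly (the
#' decoder only ever sees brain responses). Both stimulus classes evoke a
#' shared auditory component (a theta-range burst); superimposed on it is
#' a class-specific part — for the drum a brief broadband damped
#' oscillation with an alpha-range carrier, for the syllable a longer,
#' slower envelope burst carrying mostly delta-band energy. The mixing
#' weight `class_sep` sets how much of the template's power is
#' class-specific, grading how separable the two classes are. Each
#' template has a smooth scalp topography; small seeded jitters in
#' carrier frequency, decay and topography individuate subjects. The
#' same seed always returns the same template.
#'
#' @param class_label `"drum"` or `"syllable"`
#' @param rate sampling rate in Hz for the waveform (default 1000)
#' @param n_channels number of channels for the spatial profile
#' @param seed integer seed
#' @param class_sep fraction of template power that is class-specific,
#'   in `[0, 1]` (default 0.8)
#' @return a `stimulus_template`: list with `class_label`, `waveform`
#'   (microvolts at `rate`), `duration` (s), `spatial_profile`
#'   (per-channel gain in `[0, 1]`)
#' @export
make_template <- function(class_label, rate = 1000, n_channels = 64, seed = 1,
                          class_sep = 0.8) {
  assert_that(class_label %in% c("drum", "syllable"),
              sprintf("unknown class_label '%s': must be 'drum' or 'syllable'", class_label))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  # subject-level jitters come from a class-independent stream so the
  # common component really is common to the subject's two sessions
  set.seed(derive_seed(seed, "template-common"))
  jit <- function(x, frac = 0.1) x * exp(rnorm(1, 0, frac))
  dur <- 0.25
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  f_com <- jit(5)                        # shared theta-range burst
  common <- sin(pi * t / dur)^2 * sin(2 * pi * f_com * t)
  src <- c(0.2, 0.1, 0.97)               # vertex-centred auditory response

  set.seed(derive_seed(seed, "template", class_label))
  if (class_label == "drum") {
    f0 <- jit(11)                        # alpha-range carrier
    tau <- jit(0.03)                     # fast decay -> broadband transient
    specific <- exp(-t / tau) * sin(2 * pi * f0 * t)
  } else {
    f0 <- jit(2.5)                       # delta-range carrier
    specific <- sin(pi * t / dur)^2 * sin(2 * pi * f0 * t + pi / 4)
  }
  unit_rms <- function(v) v / sqrt(mean(v^2))
  w <- sqrt(1 - class_sep) * unit_rms(common) +
       sqrt(class_sep) * unit_rms(specific)
  src <- src + rnorm(3, 0, 0.08)         # slight class/subject topography shift
  src <- src / sqrt(sum(src^2))
  pos <- sphere_spiral_positions(n_channels)
  d2 <- rowSums(sweep(pos, 2, src)^2)
  profile <- 0.25 + 0.75 * exp(-d2 / 0.8)
  structure(list(class_label = class_label, waveform = w, duration = dur,
                 rate = rate, spatial_profile = profile),
            class = "stimulus_template")
}

#' Generate spatially correlated 1/f background EEG
#'
#' Produces per-channel pink noise (power density proportional to
#' 1/f^alpha with alpha = 1) by spectral shaping of white noise, then mixes
#' channels through a Gaussian spatial kernel over the sensor positions so
#' that nearby channels are correlated, and scales to the requested RMS.
#'
#' @param n_channels channel count
#' @param duration recording length in seconds
#' @param rate sampling rate in Hz
#' @param seed integer seed (same seed, identical output)
#' @param rms target per-channel RMS in microvolts
#' @param alpha spectral slope exponent (default 1, pink)
#' @param site_label site identifier; `"B"` recordings receive an added
#'   stationary white-noise floor of RMS `site_noise_rms`
#' @param site_noise_rms RMS of the site-B noise floor (microvolts)
#' @return an `eeg_recording` with zero events
#' @export
generate_background <- function(n_channels, duration, rate, seed = 1,
                                rms = 20, alpha = 1,
                                site_label = "A", site_noise_rms = 5) {
  assert_that(duration > 0, "duration must be positive")
  assert_that(rate > 0, "rate must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "background"))
  n <- round(duration * rate)
  freqs <- seq(0, rate / 2, by = rate / n)
  # amplitude shaping |H(f)| ~ f^(-alpha/2); DC removed. The slope
  # saturates below 0.6 Hz (as under an acquisition high-pass), so the
  # process carries no diverging ultra-slow power that would correlate
  # epochs minutes apart.
  shape <- c(0, pmax(freqs[-1], 0.6)^(-alpha / 2))
  data <- matrix(0, n_channels, n)
  nfft_half <- length(shape)
  for (ch in seq_len(n_channels)) {
    z <- complex(real = rnorm(nfft_half), imaginary = rnorm(nfft_half)) * shape
    # build a conjugate-symmetric spectrum -> real signal
    if (n %% 2 == 0) {
      spec <- c(z[1], z[2:(nfft_half - 1)], complex(real = Re(z[nfft_half])),
                Conj(rev(z[2:(nfft_half - 1)])))
    } else {
      spec <- c(z[1], z[2:nfft_half], Conj(rev(z[2:nfft_half])))
    }
    data[ch, ] <- Re(fft(spec, inverse = TRUE)) / n
  }
  # spatial mixing: Gaussian kernel over sensor distances
  pos <- sphere_spiral_positions(n_channels)
  d2 <- as.matrix(dist(pos))^2
  K <- exp(-d2 / (2 * 0.35^2))
  K <- K / sqrt(rowSums(K^2))           # keep per-channel power comparable
  data <- K %*% data
  # scale each channel to the target RMS (in expectation across channels)
  g <- rms / sqrt(mean(data^2))
  data <- data * g
  if (site_label == "B") {
    data <- data + matrix(rnorm(length(data), 0, site_noise_rms),
                          n_channels, n)
  }
  eeg_recording(data, rate, site_label = site_label)
}

#' Generate one synthetic stimulation session
#'
#' Background noise plus the class-specific evoked template added at each
#' of `n_repetitions` stimulus onsets, spaced exactly
#' `native_rate / stim_rate` samples apart, with the template scaled so
#' that the ratio of evoked RMS (over the template's support, across
#' channels) to background RMS equals `config$snr`.
#'
#' @param config a [generator_config()]
#' @param class_label `"drum"` or `"syllable"`
#' @param seed integer seed (defaults to `config$rng_seed`)
#' @param site_label recording site for the background model
#' @return an `eeg_recording` with `n_repetitions` labelled events
#' @export
generate_session <- function(config, class_label, seed = config$rng_seed,
                             site_label = "A") {
  tmpl <- make_template(class_label, rate = config$native_rate,
                        n_channels = config$n_channels, seed = seed,
                        class_sep = config$class_sep)
  spacing <- config$native_rate / config$stim_rate
  assert_that(tmpl$duration < 1 / config$stim_rate,
              "template longer than the inter-onset interval")
  duration <- config$n_repetitions / config$stim_rate
  bg <- generate_background(config$n_channels, duration, config$native_rate,
                            seed = derive_seed(seed, "bg", class_label),
                            rms = config$background_rms,
                            site_label = site_label,
                            site_noise_rms = config$site_b_noise_rms)
  data <- bg$data
  onsets <- as.integer(round((seq_len(config$n_repetitions) - 1) * spacing))
  if (config$snr > 0) {
    evoked <- tmpl$spatial_profile %o% tmpl$waveform       # channels x L
    rms_ev <- sqrt(mean(evoked^2))
    rms_bg <- sqrt(mean(bg$data^2))
    evoked <- evoked * (config$snr * rms_bg / rms_ev)
    L <- length(tmpl$waveform)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, "trials", class_label))
    # single-trial variability: amplitude (log-normal around 1) and
    # response-latency jitter; event markers stay at the nominal onsets
    amp <- exp(rnorm(length(onsets), 0, config$evoked_amp_sd))
    amp <- amp / mean(amp)
    jit_max <- round(config$evoked_jitter_ms / 1000 * config$native_rate)
    jitter <- if (jit_max > 0)
      sample(-jit_max:jit_max, length(onsets), replace = TRUE)
    else rep(0L, length(onsets))
    n <- ncol(data)
    for (i in seq_along(onsets)) {
      start <- max(0L, min(onsets[i] + jitter[i], n - L))
      idx <- (start + 1):(start + L)
      data[, idx] <- data[, idx] + amp[i] * evoked
    }
  }
  events <- data.frame(onset_sample = onsets,
                       label = class_label, stringsAsFactors = FALSE)
  eeg_recording(data, config$native_rate, events = events,
                site_label = site_label)
}

#' Inject bad channels and high-amplitude transients
#'
#' Emulates the contamination infant EEG preprocessing must cope with:
#' `artifact_channel_count` channels (among the usable ones) are replaced
#' by either a flat trace or a noisy kurtotic trace, and high-amplitude
#' low-frequency transients (peak `artifact_transient_gain` times the
#' background RMS, ~0.3 s long, with a random scalp profile) are added at
#' `artifact_transient_rate` events per minute. Returns the contaminated
#' recording together with a ground-truth manifest for testing recovery.
#'
#' @param recording an `eeg_recording`
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param channel_seed separate seed for the bad-channel draw; a subject's
#'   two sessions share it, because electrode problems persist across one
#'   recording visit (defaults to a stream derived from `seed`)
#' @return list with `recording` (contaminated) and `manifest`
#'   (`bad_channels`, `bad_channel_type`, `transient_onsets` in samples,
#'   `transient_duration` in seconds)
#' @export
inject_artifacts <- function(recording, config, seed = config$rng_seed,
                             channel_seed = derive_seed(seed, "badch")) {
  assert_that(config$artifact_channel_count < nrow(recording$data),
              "artifact_channel_count must be below the channel count")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(channel_seed)
  data <- recording$data
  rate <- recording$rate
  n <- ncol(data)
  rms_bg <- sqrt(mean(data^2))

  n_bad <- config$artifact_channel_count
  bad <- integer(0); type <- character(0)
  if (n_bad > 0) {
    usable <- seq_len(min(config$n_usable, nrow(data)))
    bad <- sort(sample(usable, n_bad))
    type <- sample(c("flat", "noisy"), n_bad, replace = TRUE)
    for (i in seq_len(n_bad)) {
      ch <- bad[i]
      if (type[i] == "flat") {
        data[ch, ] <- rnorm(n, 0, 0.01)
      } else {
        # high-variance in-band trace: slow AR(1) noise with occasional
        # large excursions (loose-electrode signature)
        tr <- as.numeric(stats::filter(rnorm(n), 0.98, "recursive"))
        tr <- tr * (6 * rms_bg / sqrt(mean(tr^2)))
        n_exc <- max(1, round(n / rate / 5))       # one excursion per ~5 s
        Le <- round(0.2 * rate)
        for (on in sample.int(n - Le, n_exc)) {
          tr[on:(on + Le - 1)] <- tr[on:(on + Le - 1)] +
            sample(c(-1, 1), 1) * 25 * rms_bg * sin(pi * seq_len(Le) / Le)^2
        }
        data[ch, ] <- tr
      }
    }
  }

  set.seed(derive_seed(seed, "transients"))
  dur_tr <- 0.3
  L <- round(dur_tr * rate)
  minutes <- n / rate / 60
  n_tr <- if (config$artifact_transient_rate > 0)
    max(0, round(config$artifact_transient_rate * minutes)) else 0
  onsets <- integer(0)
  if (n_tr > 0 && n > L + 1) {
    onsets <- sort(sample.int(n - L - 1, n_tr))
    t <- seq_len(L) / rate
    pulse <- sin(pi * t / dur_tr)^2 *
      (1 + 0.4 * sin(2 * pi * 6 * t))          # in-band energy (~2-8 Hz)
    amp <- config$artifact_transient_gain * rms_bg
    nch <- nrow(data)
    for (on in onsets) {
      profile <- runif(nch, 0.2, 1)
      idx <- (on + 1):(on + L)
      data[, idx] <- data[, idx] + amp * (profile %o% pulse)
    }
  }
  rec <- recording
  rec$data <- data
  list(recording = rec,
       manifest = list(bad_channels = bad, bad_channel_type = type,
                       transient_onsets = onsets,
                       transient_duration = dur_tr))
}

#' Generate a synthetic cohort of subject session pairs
#'
#' Each subject receives a drum session and a syllable session sharing the
#' subject's background statistics, with per-subject SNR drawn from a
#' log-normal spread around `config$snr`, and artifact contamination per
#' session. The last `config$site_b_count` subjects are assigned to
#' recording site B (distinct stationary noise floor).
#'
#' @param n_subjects number of subjects (the study cohort was 95)
#' @param config a [generator_config()]
#' @return list of subjects, each a list with `subject_id`, `snr`, `site`,
#'   `drum`, `syllable` (contaminated `eeg_recording`s) and the two
#'   artifact `manifest`s
#' @export
generate_cohort <- function(n_subjects = 95, config = generator_config()) {
  assert_that(n_subjects >= 1, "n_subjects must be at least 1")
  lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("s%02d", i)
    sseed <- derive_seed(config$rng_seed, "subject", i)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(sseed)
    snr_i <- config$snr * exp(rnorm(1, 0, config$subject_snr_spread))
    site <- if (i > n_subjects - config$site_b_count) "B" else "A"
    cfg_i <- config
    cfg_i$snr <- snr_i
    sessions <- lapply(c("drum", "syllable"), function(cl) {
      rec <- generate_session(cfg_i, cl, seed = sseed, site_label = site)
      inject_artifacts(rec, cfg_i, seed = derive_seed(sseed, cl, "art"),
                       channel_seed = derive_seed(sseed, "badch"))
    })
    list(subject_id = sid, snr = snr_i, site = site,
         drum = sessions[[1]]$recording,
         syllable = sessions[[2]]$recording,
         manifest_drum = sessions[[1]]$manifest,
         manifest_syllable = sessions[[2]]$manifest)
  })
}
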