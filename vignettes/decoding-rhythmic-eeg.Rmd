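---
title: "Decoding rhythmic auditory stimulation from infant EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding rhythmic auditory stimulation from infant EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rhythmdecode)
```

# The problem

An infant listens to one of two rhythmic sounds — a spoken syllable or a
drumbeat — repeated at a constant 2 Hz while 64-channel scalp EEG is
recorded at 1000 Hz. Each ~16-minute session contains 2000 stimulus
repetitions of a single class. The analysis question is whether the
*brain response alone* reveals which stimulus was playing: a binary,
within-subject decoding problem. Two decoders are compared — a compact
convolutional network operating on raw 2-s epochs, and a classical
band-power + PCA + linear-SVM pipeline — under 5-fold cross-validation
with ROC-AUC as the metric, and under two data regimes: "clean"
(statistically improbable epochs removed) and "all epochs" (noisy epochs
retained). The comparison probes a practical question for infant EEG,
where roughly a quarter of epochs are typically discarded: which decoder
family is more robust to that noise?

Because no infant recordings ship with this package, a synthetic-EEG
cohort generator reproduces the statistical structure the analysis
assumes, with known ground truth at every stage. Every experiment here
runs end-to-end on simulated subjects.

# The synthetic cohort generator

`generator_config()` fixes the study conditions: 64 recorded channels of
which 60 are usable, 1000 Hz native sampling, 2 Hz stimulation, 2000
repetitions per session (tests and examples scale `n_repetitions` down;
see *Problem sizes* below).

**Evoked templates.** `make_template()` models the neural response to a
single stimulus directly — the decoders only ever see brain responses, so
no audio is synthesised. Both classes share a common auditory component
(a theta-range burst, ~5 Hz carrier under a 250 ms envelope); on top of
it rides a class-specific component — a fast damped alpha-carrier
transient for the drum, a slower delta-carrier burst for the syllable.
The mixing weight `class_sep` (default 0.8) sets the fraction of
template power that is class-specific and thereby grades how separable
the classes are; `class_sep = 0` makes the two stimuli evoke identical
responses. Topographies are smooth gain profiles around a vertex-centred
source with small seeded subject- and class-level jitter. Carrier
frequencies and decay constants receive ~10% per-subject log-normal
jitter so no two subjects are identical.

**Background noise.** `generate_background()` draws per-channel pink
noise (power ~ 1/f) by spectral shaping, mixes channels through a
Gaussian spatial kernel over the sensor positions (nearby channels
correlate, as volume conduction dictates), and scales to 20 µV RMS. The
1/f slope saturates below 0.6 Hz, as it would under an acquisition
high-pass; this matters for decoding validity (below). Site "B"
recordings add a stationary 5 µV white-noise floor, giving the
site-comparison analysis something site-specific to (fail to) find.

**Single-trial variability.** Each repetition's evoked response is
scaled by a log-normal amplitude factor (`evoked_amp_sd`, default 0.3)
and shifted by a uniform latency jitter (`evoked_jitter_ms`, default
±10 ms). Event markers stay at the nominal onsets, as a stimulus-locked
trigger would.

**Artifacts.** `inject_artifacts()` contaminates sessions the way infant
EEG is contaminated: `artifact_channel_count` channels (default 10 of
60) are replaced by either a flat trace or a high-variance in-band trace
with slow large excursions (a loose electrode), and high-amplitude
transients (peak 12x background RMS, ~0.3 s, ~2–8 Hz energy, random
scalp profile) arrive at `artifact_transient_rate` per minute (default
8). The transient rate was calibrated once so that, at the default
thresholds, the improbable-epoch step flags roughly a quarter of epochs
— the regime reported for real infant recordings. A ground-truth
manifest accompanies every contaminated recording so recovery can be
tested.

**SNR scale and calibration.** `snr` is the ratio of evoked RMS (over
the template's support) to background RMS, with per-subject log-normal
spread `subject_snr_spread` (default 0.3). The default `snr = 1.5` was
calibrated once, together with `class_sep`, so that the scaled default
subject operates where the study operated: SVM clean AUC ≈ 0.95, SVM
all-epochs AUC lower by ≈ 0.05–0.10, CNN near ceiling in both
conditions, chance at `snr = 0`, and AUC increasing monotonically in
SNR. These numbers describe the simulator's operating point, not a claim
about infant physiology: the template shapes and SNR scale are
calibration choices, since no quantitative description of the infant
evoked response was available to copy.

**Decoding validity.** Because each class is recorded in exactly one
continuous session, *any* persistent difference between the two sessions
is indistinguishable from a class difference. Three generator/pipeline
choices exist specifically to keep such session fingerprints out of the
nominally chance-level case:

1. Bad channels are drawn once per subject and shared by both sessions
   (electrode problems persist across a single recording visit). If each
   session drew its own, the interpolated-channel pattern would identify
   the session — and the decoders find it: zero-SNR AUC reaches 1.0.
2. `preprocess_subject()` interpolates the *union* of the two sessions'
   flagged channels in both sessions, so borderline detection
   differences cannot imprint the class label either.
3. The background spectrum saturates below 0.6 Hz; a diverging 1/f tail
   would give each session realization-specific ultra-slow structure
   that correlates epochs across minutes and leaks session identity.

With these in place, the zero-SNR cohort decodes at chance (mean AUC
0.50 across seeds). This is worth knowing when interpreting the real
study too: per-session preprocessing choices can create classifiable
structure with no neural origin.

# Preprocessing

`preprocess_subject()` applies the fixed chain per session: zero-phase
band-pass 0.5–45 Hz; drop channels 61–64; downsample to 100 Hz;
automated bad-channel detection; interpolation (harmonised within
subject); average re-reference; 2-s stimulus-locked epoching (each epoch
holds 4 beats); improbable-epoch masking. Numerical choices:

- **Filter realisation.** A 4th-order Butterworth high-pass at 0.5 Hz
  plus a 4th-order low-pass at 45 Hz applied twice, all forward-backward
  (`filtfilt`), i.e. zero phase. The doubled low-pass makes the stopband
  steep enough that a 50 Hz tone loses >90% of its RMS — a single
  8th-order-effective edge does not achieve that — while the passband
  (tested at 10 Hz) stays within 5%.
- **Downsampling.** Zero-phase 8th-order anti-alias low-pass at 0.8x the
  new Nyquist, then integer decimation (non-integer ratios fall back to
  polyphase resampling). Event indices are rescaled and rounded to the
  nearest sample.
- **Bad channels.** Per-channel excess kurtosis, and an improbability
  score: the negative mean log-density of the channel's samples under a
  kernel-density estimate pooled over all channels. Both are z-scored
  across channels; a channel is flagged when either |z| > 2. The
  absolute value matters: flat channels sit far *below* the mean on both
  statistics. Detection is a single simultaneous pass, and the threshold
  is an outlier rule over finitely many channels, so occasional false
  flags on clean data are expected by construction (~0–1 channels per
  clean session) — the interpolation of a genuinely clean channel by its
  neighbours is nearly lossless.
- **Interpolation.** Unweighted mean of the k = 4 nearest non-flagged
  channels by Euclidean distance on the sensor positions.
- **Epoching.** Half-open windows `[onset, onset + 200)` samples at
  100 Hz, non-overlapping, each starting at a stimulus onset; a trailing
  partial window is dropped.
- **Improbable epochs.** Per epoch and channel, the negative mean
  log-density of the epoch's samples under that channel's across-epoch
  amplitude KDE. Scores are standardised with median and scaled MAD
  rather than mean/SD: the scores are heavy-tailed by construction and a
  plain SD is inflated by the very artifacts being detected, which
  masks them (with 15% of epochs carrying 10x transients, the
  contaminated epochs reach only ~2.3 SD under plain scaling). An epoch
  is flagged when any channel's robust z exceeds `z_single = 5` or the
  channel-average's robust z exceeds `z_all = 5` (≈ 3.4 SD for Gaussian
  scores). These two thresholds are this package's calibration — chosen
  once so that clean data loses ≤5% of epochs while default
  contamination lands in the ~15–40% rejection regime — because the
  original improbability criterion was defined only by toolbox code that
  is not part of the published record. The mask is stored, never
  applied destructively: the clean and all-epochs views are both
  derivable from one `epoch_set`.

# The convolutional network

`cnn_spec()` fixes the architecture; for the standard 60 x 200 input:

| operation | activation | output shape | parameters |
|---|---|---|---|
| temporal convolution, 12 filters, 1x4 | none | 60 x 197 | 60 |
| spatio-temporal convolution, 12 filters, 60x4 | ELU | 1 x 194 | 34,572 |
| max-pool 1x4, stride 4 (floor) | | 1 x 48 | |
| flatten | | 576 | |
| dropout 30% | | 576 | |
| dense | ELU | 32 | 18,464 |
| dense | sigmoid | 1 | 33 |

Total: 53,129 trainable parameters. Convolutions are unpadded with
stride 1. The first convolution is deliberately linear (a learned
temporal filter bank); the second spans all channels, learning one
spatial pattern per temporal feature. The single sigmoid unit outputs
the probability of the syllable class; the two-digit one-hot codes
sometimes used to present such outputs are exactly equivalent and purely
presentational.

Training (`cnn_train_config()`): Adam with learning rate 0.001, beta1
0.9, beta2 0.999, epsilon 1e-7; weighted binary cross-entropy with
balanced class weights `N/(2*N_c)`; batch size 32; 25 passes through the
training data. Early stopping (validation AUC, patience 6, best weights
restored) is available behind `early_stopping = TRUE` for
model-development exploration — the figure-style training-history CSV is
the `$history` data frame — but the main protocol uses the fixed 25
passes. Inputs are min-max normalised to [-1, 1] using the global
min/max of the training data only; the frozen transform is applied to
test folds. Global (rather than per-epoch) scaling preserves inter-epoch
amplitude relations, which are informative.

No deep-learning framework is involved: the network is implemented in
compiled code (RcppArmadillo), with both convolutions cast as dense
matrix products over shift-stacked inputs so the linear algebra library
does the heavy lifting, and analytic gradients for every layer.
Max-pool routes gradients to the argmax; dropout is inverted (scaling by
1/keep at train time); weight initialisation is the uniform fan-in
(Glorot) scheme. All randomness — initialisation, shuffling, dropout
masks — flows from one dedicated counter-based RNG stream, so a seed
determines training exactly, to the last bit, independent of R's global
RNG state. A full training run on one subject is a few seconds per fold
on one CPU.

# The classical benchmark

`bandpower_features()` computes, per epoch and channel, a
Hann-windowed periodogram (0.5 Hz bins for 2-s epochs at 100 Hz) and
sums the bins in delta [1, 4), theta [4, 8) and alpha [8, 12) Hz —
half-open intervals so shared edges are never double-counted. Sixty
channels give 180 features. `pca_reduce()` centres on the training
folds only and keeps 30 components; `train_svm()` fits a linear-kernel
maximum-margin classifier (cost 1); decision values feed the AUC.

By default the features enter PCA raw (centred only), which is the
literal classical pipeline; band powers are heavy-tailed, and that is
the point — the SVM benchmark's sensitivity to retained noisy epochs is
part of what the comparison measures. A robust variant
(`svm_config(log_transform = TRUE)`: log then z-score on training
statistics) is available and visibly flattens the clean-vs-noisy
contrast. One global scalar (mean training band power) rescales the
feature matrix purely for solver conditioning. PCA is fit per training
fold, never globally, so no test information leaks into the projection.

# Evaluation

- **AUC** is the Mann–Whitney statistic (mid-ranks, ties counted ½) —
  exactly the trapezoidal area under the empirical ROC curve; the test
  suite verifies the equivalence to 1e-12 on random fixtures.
- **Cross-validation**: shuffle, split into k = 5 nearly equal groups,
  train on four and score the fifth, rotating; the subject's score is
  the mean of the five fold AUCs and the spread their sample SD. Splits
  are not stratified (the literal procedure); a fold whose test labels
  are single-class triggers a logged re-draw with a perturbed seed.
- **Significance thresholds**: `significance_threshold(n, alpha)` finds
  the smallest correct-count whose exact binomial upper tail under
  chance (p = ½) is below alpha, and reports the accuracy strictly above
  which a score is significant — 58% at alpha = 0.05 and 68% at
  alpha = 1e-4 for n = 100. No normal approximation; brute-force
  enumeration is the test oracle.
- **Site comparison**: `rank_sum_test()` is the two-sample rank-sum
  (Mann–Whitney) test, W reported for the smaller group, exact for
  small tie-free samples and normal-approximated with tie correction
  otherwise. (The test sometimes labelled "unpaired signed-rank" in
  applied reports is this test: signed-rank is inherently paired.)
- **Robustness experiment**: `robustness_experiment()` runs the
  identical fold policy twice per subject — clean and all-epochs — and
  reports the AUC difference. `run_experiment()` drives the whole
  design: cohort generation, preprocessing, one independent model per
  subject per fold per condition, and a cohort report with significance
  annotations and the site rank-sum comparison; a failing subject is
  excluded with its reason, mirroring participant dropout.

# Problem sizes

Sessions and cohorts in the examples, tests and acceptance script are
scaled down from the full 2000-repetition, 95-subject design: unit
tests use 8–16 channel sessions of 20–120 s; the acceptance runs use
full 64-channel geometry with 140–400 repetitions per session and
cohorts of 4–10 subjects. These sizes were chosen so the complete
battery runs comfortably on a single CPU while every statistical
property being asserted (chance-level nulls, high-SNR ceilings,
degradation directions, rejection regimes) remains stable at the
asserted tolerance; nothing about the implementation limits it to these
sizes, and `generator_config()` defaults reproduce the full design.

# What passing tests do and do not show

The generator produces stationary pink-noise backgrounds, deterministic
template-shaped evoked responses with simple amplitude/latency
variability, and stylised artifacts. Real infant EEG adds
non-stationarity (state changes, movement), spatially structured
artifacts, imperfect electrode geometry, and evoked responses that adapt
over the session. Passing the acceptance battery therefore certifies
the *pipeline* — its arithmetic, its contracts, its statistical
honesty (no leakage, chance where chance belongs) and the qualitative
robustness contrast between the two decoder families — not that the
specific AUC levels would transfer to real recordings.

# Known limitations

- Artifact *correction* (ICA, wavelet denoising) is out of scope by
  design; only detection, interpolation and masking are implemented.
- Cross-subject generalisation (training on some infants, testing on
  others) is not implemented; every model is within-subject.
- The EDF writer/reader covers the plain 16-bit, uniform-rate layout
  used by the generator (no annotations channel, no variable record
  sizes).
- With one session per class, session-level confounds are controlled by
  construction in the simulator (see *Decoding validity*) but cannot be
  ruled out for arbitrary imported data; treat near-perfect AUCs on
  imported single-session pairs with suspicion.
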