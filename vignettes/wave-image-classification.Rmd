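---
title: "Classifying EEG wave images with a Vision Transformer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying EEG wave images with a Vision Transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Delirium — an acute, fluctuating disturbance of attention and cognition —
affects a large fraction of critically ill patients and is badly
under-detected by bedside screening. Its classical electrophysiological
signature is *slowing* of the EEG: elevated delta (0.5–3 Hz) and theta
(4–7 Hz) activity with diminished alpha (8–12 Hz). `eegvit` implements an
image-based classification pipeline for limited-lead (8-channel,
250 Hz) EEG: recordings are cut into short multichannel windows, each
window is rendered as a square grayscale "wave image", and the images are
classified by a Vision Transformer (ViT) trained from scratch. Because
clinical recordings of this kind are rarely shareable, the package ships a
synthetic-cohort generator that reproduces the band structure and the
class contrast, so the whole pipeline is testable end to end.

## The window-length mechanism: f = 1/T

A data slice of `n` rows spans `T = n × 4 ms`. A frequency `f` contributes
a complete cycle to the slice only if `f ≥ 1/T`; slower components enter
only as incomplete trends. `min_detectable_frequency()` encodes this
identity: a 0.1 s slice (25 rows) resolves nothing below 10 Hz, a 5 s
slice (1250 rows) resolves down to 0.2 Hz. When the class difference
lives in the delta band, classification accuracy should therefore sit
near chance for 0.1 s windows and approach its ceiling once windows are
long enough to contain whole delta cycles. This monotone accuracy curve
is the package's headline property, produced by
`frequency_coverage_experiment()`.

## The synthetic cohort

`generate_recording()` builds each channel as a sum of five narrowband
components (delta, theta, alpha, beta, gamma with default edges 0.5–3,
4–7, 8–12, 15–30, 30–60 Hz), plus a `1/f` ("pink") broadband background,
white sensor noise, and optional artifacts (mains line at 60 Hz, muscle
bursts). Narrowband components are sinusoids with uniformly random phase
and a small per-channel frequency jitter around the band centre
(`freq_jitter = 0.2` of the half-bandwidth) — a deliberately tonal
synthesis that an independent periodogram oracle can verify bin by bin; a
band-pass-filtered-noise mode is available when a less tonal texture is
wanted. The default control amplitudes are delta 1, theta 0.8, alpha 1.2,
beta 0.6, gamma 0.3 (arbitrary units); the delirium template expresses
slowing as delta ×2, theta ×2, alpha ×0.5, and a delta-only contrast
(`effect = c(delta = 2)`) is used wherever a single localized class
difference is wanted.

Three nuisance processes make the task realistically non-trivial:

* **Per-subject gain** (log-normal, `gain_sdlog = 0.2`): electrode
  contact and amplifier differences scale whole recordings, so absolute
  amplitude is not a trustworthy feature across subjects.
* **Pink background** (`background_sd = 1` RMS relative to the band
  amplitudes): scalp EEG rides on `1/f` broadband activity. This is what
  makes *short* windows genuinely uninformative: within 0.1 s the
  background contributes essentially one random low-frequency trend
  (one to two spectral degrees of freedom below 10 Hz), which swamps the
  between-class difference in sub-cycle delta trends. A 5 s window
  contains ~25 delta-band degrees of freedom, so the ×2 amplitude
  difference becomes reliably estimable. Without this background the
  pipeline can read the class off the within-window trend even at 25
  rows, and the window-length mechanism would be invisible.
* **Optional band-power non-stationarity** (`env_sd`): a slowly varying
  log-normal amplitude envelope shared across channels. It is off by
  default because strong envelopes interact badly with per-slice min–max
  normalization (a single burst sets the range) and because the
  stationary regime is the one whose spectra the test oracles verify.

What the generator does **not** emulate: dipole/head-model topography,
inter-channel coherence structure, eye blinks, drifting electrode
impedance, medication effects, or any within-subject evolution of the
delirium state. Passing tests on this cohort show that the pipeline
recovers a band-localized contrast under gain and background nuisance —
not that it detects clinical delirium.

## Preprocessing

The cleaning chain is `bandpass_filter()` (4th-order Butterworth,
0.5–40 Hz, applied forward–backward so the phase response is zero and the
magnitude response is squared), `rereference()` (common average), an
optional `epoch_recording()`, and `ica_clean()`. ICA is a symmetric
fixed-point algorithm with the logcosh negentropy contrast, implemented
in the package; components are rejected when their excess kurtosis
exceeds 10 (spiky artifacts) or when more than half their spectral power
lies above 30 Hz (muscle/line activity), and the signal is rebuilt from
the remainder. Non-convergence within the iteration cap (500, with reseeded restarts) returns the
recording unmodified with a warning, never silently. The "uncleaned"
analysis arm skips only the ICA stage.

Two caveats are deliberate. First, the rejection thresholds and filter
cutoffs are this package's choices; nothing forces them on real data.
Second, the headline experiments run on artifact-free synthetic cohorts
with ICA disabled: with no artifact components to remove, unmixing noise
is all ICA could add, and near-coherent sinusoidal sources make the
fixed-point iteration ill-conditioned. ICA correctness is instead
established by unit tests with known ground-truth mixtures (source
recovery at |r| ≥ 0.95, ≥ 10-fold suppression of a high-kurtosis spike
source).

## Slicing, splitting, balancing

`make_slices()` cuts half-open windows `[origin, origin + n)` starting at
`0, s, 2s, …` with stride `s = round(n(1 − overlap))` (half away from
zero, floored at 1). Overlapping windows are an augmentation device; the
package treats 90% overlap as the reporting default and also offers 75%
and 95%. `split_by_subject()` assigns *subjects*, never slices, to the
train or test side (test fraction 0.25 by default, at least one subject
of each class per side): with 90% overlap, neighbouring slices are nearly
identical, so any slice-level split would leak test content into
training. `balance_classes()` down-samples the majority class to a 1:1
ratio independently on each side after splitting, so test-set composition
is never informed by training counts. Experiments cap windows at
`max_slices_per_recording = 40` per recording, evenly spaced, so every
slice length trains on a comparable number of examples.

## Imaging

`slice_to_image()` maps the 8 × n slice onto an S × S grid (default 224,
desk preset 64) by separable, corner-aligned bilinear interpolation —
source corner pixels map exactly onto destination corners, the dialect
fixed here because interpolation conventions differ between libraries and
this one admits a simple hand oracle. Pixels are then min–max normalized
to [0, 1] per slice; constant slices map to 0.5. Note two consequences:
per-slice normalization removes the subject gain (good) and any pure DC
offset, and point-sampling a 1250-column slice down to 64 columns aliases
the faster rhythms into high-frequency texture while leaving slow waves
legible — which is precisely the regime in which a vision model must find
band-structure differences. `slice_to_spectral_image()` renders the
comparison arm: per channel, the one-sided DFT magnitude, compressed as
`log(1 + |X|)`, stacked into an 8 × (⌊n/2⌋+1) array and then resized and
normalized identically, so both domains feed the model images of the same
shape and range and the comparison is fair. Slow-band structure ends up
in the leftmost sliver of a spectral image (delta occupies bins 2–15 of
626 at 5 s), one reason the frequency-domain arm tends to lose.

## The Vision Transformer

`vit_train()` implements the standard ViT recipe with no shortcuts:
non-overlapping patches (16 px at 224, 8 px at 64) are flattened,
linearly embedded, prepended with a learned class token, summed with
learned positional embeddings, and passed through pre-norm transformer
blocks (multi-head scaled-dot-product self-attention with residuals,
then a GELU MLP of width `mlp_ratio × embed_dim` with residuals); a final
layer norm and a linear head on the class token give two logits and a
softmax. Training minimises cross-entropy with Adam (0.9/0.999) at
learning rate 0.001 over shuffled mini-batches for a fixed number of
epochs (5 by default; no early stopping), fully reproducible from the
configuration seed. Forward, backward and the optimizer are written in
plain R matrix algebra; analytic gradients are verified against finite
differences in the test suite.

Two presets are provided. The full-scale preset (`vit_config_full()`: 224 px, patch 16,
embedding 512, depth 12, 8 heads, mlp ratio 4, batch 64) matches the
configuration used in clinical-scale work; the desk preset (64 px, patch
8, embedding 64, depth 2, 4 heads, mlp ratio 2, batch 32; 75,586
parameters) is the one the tests and experiments use so that a full
training run takes seconds on one CPU core.

Two implementation choices matter enough to record. Pixel intensities
are recentred from [0, 1] to [−1, 1] before the patch embedding — the
standard image-normalization step. Linear-layer weights are initialised
N(0, 1/fan_in) rather than with a single small constant scale: because
layer normalization hands each linear layer unit-variance inputs,
fan-in-scaled weights give order-one pre-activations and engage the GELU
nonlinearity from the first step. With a uniformly tiny initialisation
the desk-scale network starts in its linear regime, and a phase-random
spectral contrast — whose classes are indistinguishable to any linear
model in pixel space — produces vanishing expected gradients; training
then plateaus at chance regardless of data volume. Class-token and
positional embeddings keep the conventional small scale (sd 0.02).

## Experiments and problem sizes

`run_sweep()` executes the full factorial over slice lengths
{0.1, 0.5, 1, 1.6, 5} s × overlaps {0.75, 0.9, 0.95} × domains × arms,
emitting one `EvalReport` (confusion matrix with delirium positive,
slice-level train/test accuracy, per-epoch trace, split manifests) per
condition and a summary table; failures are caught per condition.
`frequency_coverage_experiment()` runs the headline study: per seed, a
fresh 12-subject cohort (60 s per recording, delta-only ×2 contrast),
desk preset, 90% overlap, slice lengths {25, 125, 250, 1250} rows;
5 seeds by default. `domain_contrast_experiment()` compares time against
frequency images at 5 s slices, 50% overlap, 4 training epochs. These
problem sizes — 12 subjects, 60 s recordings, ≤ 40 windows per recording,
desk preset — are the package's chosen desk-scale study conditions: large
enough for the mechanism to be measurable, small enough that the full
acceptance suite runs on a single CPU core in minutes.

Accuracy is reported at slice level, the natural unit of the pipeline,
but heavily overlapping slices from one subject are strongly correlated,
so slice-level accuracy can overstate subject-level performance; each
report therefore also carries a subject-level majority-vote accuracy,
labelled as an extension. With 12 subjects a test side holds 3, so
per-seed test accuracies are coarse; medians across seeds are the
quantities to read.

## Numerical conventions and edge cases

* Stride rounding: half away from zero, floored at 1; `overlap ≥ 1` is
  rejected rather than producing a zero stride.
* Origin rows are 0-based; windows half-open; trailing samples that do
  not fill a window (or epoch) are dropped.
* Constant slices normalize to 0.5 exactly; non-finite slice data is
  rejected, not propagated.
* Prediction ties (probability exactly 0.5) go to the control class and
  are flagged — a fixed, visible rule rather than an RNG draw.
* Layer-norm epsilon 1e-6; attention softmax is max-shifted per row;
  probabilities are floored at 1e-12 inside the loss.
* All randomness (generation, gains, splits, balancing, initialisation,
  shuffling, ICA restarts) flows from explicit integer seeds; reruns are
  bit-identical.
* EDF export quantizes to 16 bits per channel over the channel's own
  physical range; CSV export is lossless and self-describing.

## Known limitations

The generator's tonality (sinusoid components) makes spectra easy to
verify but gives each subject a faint tonal signature; the pink
background and frequency jitter blunt, but do not erase, memorization of
training subjects. Cohorts of 12 make subject-grouped accuracy estimates
coarse. The ICA stage assumes at most a handful of artifact components
and at least ~10 s of data. Nothing in the package addresses bad-channel
interpolation, impedance-aware weighting, or multi-session drift. The
frequency-domain arm uses one particular rendering (log-magnitude DFT
resized like the time-domain image); other spectral layouts could behave
differently and the comparison should be read as specific to this
rendering, which is labelled in all reports.
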