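---
title: "Modeling limb-position and contraction-intensity confounds in myoelectric control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling limb-position and contraction-intensity confounds in myoelectric control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgconfound)
```

## Why a synthetic test bed

Robustness claims in myoelectric control are usually demonstrated on
laboratory datasets whose confound structure (which limb positions, which
contraction intensities, how many repetitions) is fixed by the collection
protocol and often not publicly available. `emgconfound` takes the
opposite route: a generative model whose confound mechanisms are explicit,
parameterized and seeded, so that every number in an analysis can be
recomputed bit-exactly and every effect magnitude can be dialed. The price
is that the generator is a *statistical* emulation of surface EMG, not a
physiological one, and this vignette is explicit about what that buys and
what it does not.

## The generative model

A study is described by `generator_config()`: subjects, channels, motion
classes (exactly one flagged as the rest/no-motion class), a condition
axis (`position` or `intensity`), repetitions, sampling rate and trial
duration.

**Activation profiles.** Each subject gets a seeded matrix
`A[class, channel]` of activation envelopes, drawn uniformly on
0.2–1.2 mV and interpreted as the target mean rectified value (MAV) of
that channel during that motion. The rest-class row is pinned at the
sensor noise floor (default 0.01 mV RMS). A log-normal per-subject scale
(SD 0.15 on the log scale) models between-subject amplitude differences,
and a seeded half of the channels is marked as co-located with
limb-stabilization musculature.

**Trial synthesis.** Per channel, a white innovation sequence is drawn
from the mixture `(1 − w)·N(0,1) + w·Laplace(0, 1/√2)` (component
variances equal), shaped by a 4th-order Butterworth band-pass over the
conventional 20–450 Hz EMG analysis band, and summed with a resonant
narrowband component (2nd-order band-pass, ±3 Hz) centered at the
low-frequency firing-rate peak. The resonant component contributes a
fixed 0.5 relative mean-rectified share; concentrated in a ~6 Hz band it
dominates the spectral density below 60 Hz, which is what makes the peak
location estimable from short records. The composite is normalized so
its empirical MAV equals `gain × A[class, channel] × subject_scale`.
Normalizing MAV (rather than RMS) makes the amplitude law exact by
construction: the ratio of mean MAV between two intensity levels equals
the configured gain ratio regardless of the mixture weight, which changes
the shape of the amplitude distribution but not the calibrated level.

**Position confound.** Condition values are position indices; the first
is the reference. A position re-mixes channels with
`W = (1 − α)·I + α·M`, where `M` is a seeded row-stochastic perturbation
(diagonally dominant, unique per subject × position) modeling the shift
of muscle-fiber topography relative to the electrodes as a conservative
re-weighting — rows sum to one, so no energy is invented. Stabilization
baseline activity with MAV `β·|p − p_ref|` is added on the stabilization
channels only, reflecting that postural muscles share recording sites
with some, not all, electrodes.

**Intensity confound.** Condition values are MVC fractions in (0, 1].
Channels are left unmixed; the gain is `level^γ` with `γ = 1` by default
— the linear amplitude law is the testable default, and the exponent is
exposed for studying nonlinear amplitude–force relationships. The
firing-rate peak interpolates linearly across `peak_shift_range`
(default 10 → 40 Hz) and the Laplacian mixture weight across
`laplacian_weight_range` (default 0.1 → 0.5, i.e. more heavy-tailed at
higher force) as the level spans the configured range.

**Determinism.** Every draw is a function of the configuration seed and
the coordinates of the object being drawn (subject, position, class,
repetition), folded through a multiply-accumulate into 31-bit sub-seeds.
Identical configurations therefore reproduce identical datasets
bit-exactly, and single trials can be re-synthesized in isolation.

### Choosing the effect magnitudes

The literature quantifies the position effect in *accuracy* terms, not in
signal terms, so the mixing strength `α` and baseline gain `β` cannot be
read off a paper. They were calibrated once against the accuracy
degradations reported for 5-position protocols: with `α = 0.7`,
`β = 0.3` the default 5-position study yields intra-condition accuracy
near 100%, a ~15-point drop for single-condition training tested across
all positions, and a further few points for fully disjoint train/test
positions — the same ordering and comparable magnitudes to published
multi-position studies. Weaker settings (α ≲ 0.3) leave the class
geometry so far separated relative to the mixing shift that no classifier
degradation is measurable at all; the defaults are deliberately in the
regime where the confound matters.

## The analysis chain

**Conditioning.** Notch (2nd-order band-stop, default Q = 30 — the
literature gives only center frequencies), band-pass (4th-order
Butterworth, 20–450 Hz; some protocols use a 10 Hz high-pass edge, so
both cutoffs are configurable), and integer-ratio decimation with an
8th-order anti-alias low-pass. All filters run forward–backward
(zero-phase): the analysis is offline, so causality costs nothing and
group-delay distortion of short windows is avoided. Reflection padding of
512 samples covers the settling time of the narrowband notch; the
generator's own shaping filters use a 128-sample pad since per-trial MAV
normalization absorbs edge effects. The default stage order is notch →
band-pass → decimate → segment, each stage optional.

**Segmentation.** A recording of `n` samples yields
`floor((n − L)/I) + 1` windows of length `L` at increment `I` (150/50 ms
defaults; `I = L` gives adjacent segmentation). Windows never span trial
boundaries, and recordings shorter than one window are skipped with a
warning rather than an error, matching how ragged trial sets are handled
in practice.

**Features.** The per-channel catalog (19 features,
`list_features()`) follows the canonical definitions; the source
literature names these features without printing formulas, so the
conventions are fixed here and tested against independently coded
oracles. Notable choices:

* Thresholds for ZC/SSC default to 0 (maximizing determinism on
  synthetic data) and WAMP to 0.02 mV; all are configurable.
* `LS` is the L-scale (second L-moment) of the raw signal; whether the
  low-sampling-frequency sets intend the raw or rectified signal is not
  derivable from the secondary literature, so raw is the default and the
  convention is isolated in one kernel.
* The six spectral-moment descriptors (`TDPSD`) form
  `m0, m2, m4` as root sums of squares of the window and its first two
  differences, power-rescale each as `m ← m^0.1/0.1`, build six
  log-domain descriptors, repeat the construction on a log-power
  transform of the window, and fuse the two vectors elementwise by
  `−2ab/(a² + b²)`. The cited construction admits variants; both the
  fused and raw-descriptor modes are exposed (`fused = FALSE`) rather
  than guessing a citation's intent.
* Degenerate (zero-variance) windows return 0 for SampEn and the Hjorth
  mobility/complexity, and log arguments are clamped at `1e-12` with a
  package-level counter (`tdpsd_clamp_count()`), so silent rest windows
  can never poison a feature matrix with non-finite values.
* `AR4` solves the Yule–Walker equations on demeaned, biased
  autocovariances — the same convention as `stats::ar.yw`, which serves
  as the independent cross-check in the tests, not as the
  implementation.

**Classifiers.** LDA, QDA, kNN, linear SVM and random forest behind one
surface (`fit_predict()`). Features are z-scored with training-split
statistics only — required for kNN/SVM comparability and harmless for the
rest — and constant training columns are dropped from both splits. kNN is
implemented in-package because deterministic tie-breaking (smallest class
index) is part of the evaluation contract and reference implementations
break ties randomly. The forest is the only stochastic learner and is
seeded from the classifier spec. Grid-search tuning
(`tune_hyperparameters()`) optimizes intra-condition accuracy on a
designated tuning subject, and the evaluation guard refuses to run if
that subject's rows are still present downstream.

**Frameworks and splits.** `make_splits()` enumerates the four
frameworks. Leave-one-trial-out is applied uniformly: training always
excludes the held-out repetition, testing uses only it. Only the
same-condition framework strictly requires this, but the one-vs-all and
multi-vs-all frameworks test on *all* conditions — without the uniform
rule the very windows under test would sit in the training set. For the
disjoint framework the rule costs one training repetition and buys
consistency: every framework differs from the others only in its
condition sets. The multi-vs-all enumeration is exhaustive up to a cap
(default 1000 training sets), beyond which a seeded uniform subsample is
taken.

**Metrics.** The Davies–Bouldin computation uses the mean-*squared*
dispersion and *squared* Euclidean separation — the forms printed in the
defining equations — even though prose descriptions often say "standard
deviation" and "distance"; the root-form variant sits behind
`squared = FALSE`. The index averages each cluster's worst overlap over
the number of clusters: an average over all pairs would make every
summand identical to the maximum and is noted, not implemented.
The active error rate's denominator is defined by the explicit no-motion
label carried in every `prediction_record`, never positionally; the
positional reading ("predictions different from class 1") is available
as `convention = "printed"` for comparability. A split in which every
prediction is no-motion has an undefined AER and is reported as missing
— never as 0, which would reward a classifier for total inactivity.
Accuracy is defined as `100 − TER` and the identity is exact by
construction, not by rounding.

## What passing tests do and do not show

The generator reproduces, by construction, the *mechanisms* the
literature attributes to the two confounds: conservative channel
re-mixing, additive stabilization activity, linear amplitude gain,
firing-rate peak migration, Gaussian-to-Laplacian distribution drift. It
does **not** model motor-unit recruitment or firing trains, electrode
lift-off, skin-impedance drift, fatigue, force transients within a trial,
or trial-to-trial amplitude variability (within-class variability comes
from the stochastic innovations alone, which is why intra-condition
accuracies saturate near 100% — real studies report 95–97% with similarly
tight spreads). Consequently the framework-ordering results
(intra > single-vs-all > inter, diversity helps but never beats matched
training) are qualitative reproductions under controlled conditions, not
predictions of absolute accuracies on any real dataset.

## Problem sizes and budgets

The acceptance analyses use a 5-position study of 2 subjects, 8 channels,
8 motions, 10 repetitions and 1 s trials at 1000 Hz (800 recordings,
14 400 windows, 32 TD features per subject-condition grid), repeated over
10 seeds, and an intensity calibration of 5 MVC levels with ≥ 1000
windows per level. Two subjects are the minimum that makes
subject-averaged accuracy meaningful, and 1 s trials give 18 windows per
trial at the 150/50 ms defaults — enough for stable per-split error
rates while keeping a full 10-seed study in the minutes range on one
CPU. Metric and feature oracles run on hundreds of small random
instances (≤ 100 observations, ≤ 10 classes, ≤ 8 dimensions) where
brute-force enumeration is exact.

## Known limitations

* Intensity and position confounds are modeled separately; a combined
  two-axis condition grid is not implemented.
* The HDF5 container mentioned alongside the CSV+JSON layout is not
  provided; CSV+JSON is the only serialization surface.
* The positional ("printed") AER denominator and the root-form DBI exist
  for comparability but are not used by the pipeline defaults.
* Loaders for the published multi-position/multi-intensity datasets are
  out of scope; the generator's study shapes mirror their published
  geometry (channels, motions, repetitions, rates) instead.
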