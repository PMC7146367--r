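# emgconfound

Surface-EMG pattern recognition works remarkably well in the laboratory and
then degrades in daily use. Two well-documented culprits are the **limb
position effect** — a classifier trained with the arm in one posture
misreads the same gestures in another, because the muscle-fiber topography
under the electrodes shifts and stabilization muscles co-activate — and the
**contraction intensity effect** — a classifier trained at one force level
misreads gestures produced harder or softer, because EMG amplitude, its
low-frequency spectral peak, and its amplitude distribution all change with
force. `emgconfound` is a toolkit for studying both effects end to end:
it generates synthetic multi-subject EMG whose statistical structure
carries the two confounds, runs the standard conditioning and windowing
chain, extracts the literature's named time-domain feature sets, and
quantifies the degradation with the field's evaluation statistics under
the four canonical cross-validation frameworks. It is aimed at
myoelectric-control researchers who need a controlled, fully reproducible
test bed for robustness claims.

## The model in brief

**Generator.** Each motion class `c` and channel `k` gets a seeded
activation envelope `A[c,k]` (mV, mean rectified value). A trial is built
per channel from a white innovation sequence drawn from the mixture
`(1 − w)·Gaussian + w·Laplacian`, shaped by a 4th-order 20–450 Hz
band-pass plus a resonant low-frequency component at the firing-rate peak
`f_p`, and normalized so its mean rectified value equals `g·A[c,k]`.
Confounds enter through a condition transform:

* *position* `p`: channels are re-mixed with the row-stochastic
  `W = (1 − α)·I + α·M(subject, p)`, and stabilization baseline activity
  `β·|p − p_ref|` is added to a seeded half of the channels;
* *intensity* `m` (fraction of maximal voluntary contraction): gain
  `g = m^γ` (default `γ = 1`, the linear amplitude law), with `f_p`
  interpolating 10 → 40 Hz and the Laplacian weight `w` interpolating
  across its configured range as `m` spans the level range.

**Evaluation.** Windows (150/50 ms by default) are scored with
per-channel features (MAV, ZC, SSC, WL, AR4, SampEn, Hjorth parameters,
spectral-moment descriptors, …) bundled into the named sets TD, TDAR,
TSTD, LSF4, LSF9, TDPSD and Hjorth; classified with LDA, QDA, kNN, linear
SVM or random forest under leave-one-trial-out cross-validation in four
frameworks — *x vs x* (train and test in the same condition, the upper
bound), *x vs y* (disjoint conditions, the lower bound), *x vs all*, and
*N vs all* (growing training diversity); and summarized with

* `TER = 100·(1 − Σ[p_n = l_n]/N)` — total error rate,
* `AER = 100·#{p_n ≠ l_n, p_n ≠ NM} / #{p_n ≠ NM}` — active error rate,
  which ignores false predictions of the no-motion class `NM`,
* `DBI` — the Davies–Bouldin index with mean-squared dispersions
  `S_i = (1/N_i)Σ(x_j − μ_i)ᵀ(x_j − μ_i)` and squared separations
  `D_ij = (μ_i − μ_j)ᵀ(μ_i − μ_j)`, averaging each cluster's worst
  overlap `R_ij = (S_i + S_j)/D_ij` (a root-form variant is available via
  `squared = FALSE`).

## Worked example

A small 3-position study — 1 subject, 4 channels, 4 motions (one rest
class), 3 repetitions per position:

```r
library(emgconfound)

cfg <- generator_config(n_subjects = 1, n_channels = 4,
                        motion_classes = c("no-motion", "power", "pinch", "wrist-flex"),
                        conditions = 1:3, reps_per_condition = 3,
                        trial_duration = 0.5, seed = 42)
ds <- lapply(generate_dataset(cfg), bandpass_filter)
ws <- segment(ds)                      # 150/50 ms windows
fm <- extract_set(ws, "TD")            # Hudgins' set: MAV, ZC, SSC, WL
spec <- classifier_spec("lda")
res <- lapply(c("intra", "single_vs_all", "inter"), function(fw)
  run_experiment(fm, fw, spec, no_motion = cfg$no_motion))
format_results_table(res)
```

```
  feature_set classifier     framework                 accuracy
1          TD        lda         intra 100.0±0.0 (100.0, 100.0)
2          TD        lda single_vs_all    90.9±5.6 (81.2, 96.9)
3          TD        lda         inter  86.3±17.4 (43.8, 100.0)
```

The framework ordering is the point: training and testing in the same
position is (here) perfect; training in one position and testing across
all positions loses ~9 points; testing only in unseen positions loses ~14
and becomes erratic (the min accuracy drops to 43.8%). The same shift is
visible before any classifier is involved:

```r
active <- fm$meta$motion_label != "no-motion"
dbi(fm$values[active, ], fm$meta$motion_label[active])   # 0.878 pooled over positions
p1 <- active & fm$meta$condition_value == 1
dbi(fm$values[p1, ], fm$meta$motion_label[p1])           # 0.089 within one position
```

Class clusters that are crisply separated within a single position
(DBI 0.089) overlap an order of magnitude more once positions are pooled
(DBI 0.878).

The same analysis runs unattended from a YAML configuration:

```sh
Rscript inst/cli/emgpipe.R --config inst/extdata/d1_like.yaml --out run1
```

which writes `dataset/`, `features/`, `results.csv`,
`results_summary.json`, `report.md` and a reproducibility
`manifest.json` into `run1/`.

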