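---
title: "Multimodal activity recognition: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal activity recognition: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actifuse)
```

# The recognition problem

Activities of daily living are short, object-centred actions — drinking,
eating, medicine intake, wiping — whose arm kinematics overlap heavily.
`actifuse` treats recognition as window classification on a unified
timeline: two wrist accelerometers contribute motion evidence, an
egocentric camera contributes hand–object interaction evidence, and a
fused classifier decides per window. This vignette records the modelling
conventions the package commits to, why each default is what it is, and
what the synthetic test bed does and does not demonstrate.

# Windowing

Windows are **timespan-defined, half-open intervals** `[start, end)` laid
out with constant step `S = length × (1 − overlap)`. Every boundary in the
code base — windows, annotation intervals, frame spans, sample assignment —
uses the same half-open convention, so a sample or frame on a boundary
belongs to exactly one adjacent non-overlapping cell. Timestamps are
integer milliseconds throughout: the finest grain a 50 Hz / 25 fps source
pair needs.

Defaults: 1000 ms inertial windows (long enough to capture a reach-or-lift
motion, short enough not to span two of these brief activities) with 75%
overlap on the inertial grid; vision windows of 10 frames with stride 5
(400 ms / 50% at 25 fps). Windows are defined by time, not by sample
count, so a dropped sensor reading shrinks a window instead of shifting
the whole grid; windows with fewer than `min_samples = 4` samples in either
wrist stream are invalid and dropped rather than interpolated.

# The inertial feature vector

Per window and axis (x, y, z), 11 statistics; plus 3 cross-axis
correlations, a 3-vector gravity estimate and 3 orientation angles: 42 per
device, 84 for the left-then-right pair. The named conventions, each
chosen to be unit-testable against a from-definition oracle and to keep
every entry finite:

* variance and standard deviation use population normalization (divide by
  *n*);
* the inter-quartile range interpolates order statistics linearly;
* MAD is the raw `median(|a − median(a)|)` (no consistency constant);
* kurtosis is Fisher excess kurtosis, defined as 0 for a constant signal;
* time-domain entropy is the Shannon entropy (natural log) of a
  10-equal-width-bin histogram over the window's own range, 0 when the
  range collapses;
* correlations involving a constant axis are 0;
* gravity is the final state of the first-order low-pass
  `g ← α g + (1 − α) a` with `α = 0.9`, initialized at the first sample —
  at 50 Hz this passes ≈0.8 Hz and below, the usual body/gravity split;
* orientation is reported per axis as `acos(g_i / ‖g‖) ∈ [0, π]` (whether
  gravity and orientation are scalars or per-axis is a genuinely open
  representation choice; per-axis is strictly more informative and the
  axis set is configurable downstream by column selection);
* with `X_k` the DFT of one axis, `mean_dc = X_0 / N` (identical to the
  arithmetic mean), spectral energy is `(1/N) Σ_{k≥1} |X_k|²` with the DC
  bin excluded (otherwise a constant offset of 9.81 m/s² dominates every
  window), and spectral entropy is the Shannon entropy of the normalized
  non-DC power spectrum. Non-DC power at round-off level relative to the
  total spectrum (relative threshold 1e−20) is treated as exactly zero, so
  constant signals report energy and spectral entropy 0 instead of
  amplified floating-point noise. These conventions satisfy the Parseval
  identity `Σ a² = N·mean_dc² + energy`, which the test suite asserts.

No resampling is performed before the DFT: windows are short and the
nominal rate is stable, so the spectrum of the raw samples is used as-is.

# The vision feature vector

Per frame, the hand is the highest-confidence detection of the hand class
(ties: larger area, then smaller `x_min`); detections below
`min_conf = 0.5` are ignored (detectors emit many low-confidence boxes; 0.5
is the customary operating point and it is configurable). Interaction with
an object is quantified as **intersection over object area** — a hand
fully covering a small object scores 1 regardless of hand-box size — which
matches the "is the hand on the object" reading better than IoU; IoU is
available as an option. Multiple instances of one class contribute their
maximum overlap, which is deterministic and order-independent.

Hand-less frames carry the sentinel vector of −1, deliberately distinct
from "hand present but touching nothing" (a zero vector). Window averaging
**includes** the sentinels by default: a window with few hand detections is
thereby pulled toward −1, encoding detection sparsity as evidence. The
alternative (`sentinel_mode = "exclude"`, averaging only hand-positive
frames) is implemented for sensitivity analyses since either reading of
"average the frame vectors" is defensible.

# Alignment, matching, fusion

Recordings begin with a deliberate stillness period. The motion onset —
first acceleration-magnitude deviation beyond `still_threshold` (default
1 m/s², compared against the median magnitude of the first
`min_still_ms = 1000` ms) sustained for 3 consecutive samples — is a
landmark visible on every inertial device, and differences between
per-device onsets give the clock offsets. Three consecutive samples
(60 ms) suppress single-sample glitches while costing at most two sample
periods of latency; cameras cannot use this detector, so their offset is
supplied (in practice it is read off manually annotated video).

All modalities are trimmed to the latest common start and earliest common
end. Each vision window with start `t_s` is matched to the inertial window
with the **smallest start `t_s' ≥ t_s`**; the matched pair always
satisfies `0 ≤ t_s' − t_s < S`. Vision windows at the session tail with no
later inertial window are dropped, never matched backwards.

Late fusion follows the stacked-generalization pattern: random forest
(100 trees) on the inertial block, L2 logistic regression (`C = 1`) on the
vision block, per-class probabilities appended to their own blocks, and a
meta classifier on the concatenation. Training-time probabilities default
to `in_sample` (the base models predict their own training data — the
literal pipeline description); `out_of_fold` computes them by an internal
stratified 5-fold cross-fit and is the right choice when stacking leakage
is a concern. Logistic models standardize features internally so the L2
penalty treats the heterogeneous feature scales (m/s², radians, overlap
fractions) comparably; the "newton" optimizer is the quasi-Newton fit of
`nnet::multinom`, the "simple" one the first-order coordinate fit of
`glmnet` (`alpha = 0`, `λ = 1/(C·n)`). The forest grid maps "maximum
depth" to a `2^depth` leaf cap and "minimum samples per leaf" to
`nodesize`; the forest implementation exposes no separate
minimum-samples-per-split control, so that grid dimension collapses into
the leaf size.

# Labeling and leakage control

Annotation intervals are mapped to windows by **majority intersection with
a cover threshold**: the window takes the class of the interval with the
largest temporal intersection provided it covers at least
`min_cover = 0.5` of the window, and is `none` (background) otherwise;
ties go to the earlier-starting interval. Compound kitchen-style labels
(`verb-object1-preposition-object2`) reduce to their first token, the
verb.

Overlapping windows share raw samples, so instance sets are de-overlapped
before any protocol: every other window on the 50% vision grid, every
fourth on the 75% inertial grid, leaving retained windows pairwise
disjoint. Cross-validation uses stratified folds by default (the rare
short activities must reach every fold) redrawn fresh for every repeat;
balancing oversampling, when requested, touches the training split only.
Macro averages include the `none` class (it is a real decision the
classifier must make); a caller can exclude it by passing an explicit
`class_set`. Tie-breaking is deterministic everywhere: first grid point,
earlier interval, earlier class.

# The synthetic scenario generator

The generator emulates the *structure* of a two-subject ADL recording
campaign: six sessions per subject, two interleaved activity sequences,
a stillness lead-in, 50 Hz two-wrist inertial traces, 25 fps detection
records, per-device clock offsets, and short interruptions between
activities. Motion is a per-class, per-wrist sum of sinusoids plus white
noise — enough to make the windowed features class-discriminative and
fully controllable, with no claim of biomechanical realism. Templates
default to cosine-phase onsets (motion after a deliberate pause starts
abruptly) with a z-amplitude ≥ 2.5 m/s² so onsets are visible in the
acceleration magnitude. Object interaction is drawn per frame from a
per-class Beta law and realized geometrically: the object box is slid
relative to a fixed hand box so that intersection-over-object-area equals
the drawn value exactly, then jittered; a zero Beta shape degenerates to a
point mass so noise-free scenarios are exactly deterministic. Detector
imperfection is modelled as per-frame hand misses, false-positive boxes,
box jitter and a confidence spread. Frame images are never generated —
only detection records, the pipeline's actual input boundary.

Two canonical study conditions are exported:

* `confusable_noise_free_config()` — every nuisance off, overlaps
  degenerate at 1, and the stillness lead (3200 ms), durations (4000 ms)
  and pauses (1600 ms) fixed to multiples of the 400 ms vision window span.
  Boundaries then coincide with even-index window starts, so after
  de-overlapping no retained window straddles an activity boundary and the
  session-to-feature map is deterministic: an end-to-end run must recover
  the labels with macro F1 exactly 1. This validates the plumbing; it says
  nothing about noise robustness.
* `confusable_moderate_noise_config()` — the confusable four-class design
  (two classes share a motion template with disjoint objects; two share an
  object with distinct templates) under accelerometer noise of 1 m/s²,
  20% missed hands, 10% false positives and 15 px jitter. Here neither
  single modality can separate its confusable pair, and the fusion-gain
  property (late fusion beats each single modality by a clear margin) is
  asserted over five generator seeds.

What passing these tests does **not** show: robustness to real detector
failure modes (systematic misses under motion blur, correlated false
positives), to non-stationary sensor noise, egomotion, posture variation,
or to annotation disagreement. The generator's subjects are statistically
identical by default (no subject effect), so cross-subject transfer on
synthetic data is easier than on real cohorts; the fixed-split protocol is
validated for correctness (leakage, balancing), not for realistic transfer
difficulty.

# Problem sizes and runtime choices

Validation workloads use the 2 × 6-session cohorts (≈ 750 retained
instances, five classes), repeated cross-validation with 2 repeats for the
deterministic condition and 1 repeat per seed across 5 seeds for the
fusion-gain condition, and 20 sessions for offset recovery. These sizes
give stable estimates for the properties asserted (exact recovery, gains
an order of magnitude above the assertion margin, zero-tolerance leakage
counts) while keeping a full validation run in the minutes range; the
`repeats` default of 100 remains the recommended setting for substantive
stability analyses on real data.

# Known limitations

* The overlap feature is 2-D: without depth, a hand in front of an object
  is indistinguishable from a hand on it.
* The stillness detector requires a genuine motionless lead-in; recordings
  without one need manual offsets.
* Only the accelerometer channel is modelled; gyroscope/magnetometer
  channels and body positions beyond the two wrists are out of scope.
* `in_sample` stacking probabilities are optimistic on training data;
  use `prob_mode = "out_of_fold"` when the meta model's calibration
  matters.
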