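# actifuse

Multimodal recognition of activities of daily living (ADL) from two
wrist-worn accelerometers and an egocentric (head-mounted) camera.

Many ADL classes that matter for digital-health monitoring — eating,
drinking, taking medicine — involve nearly identical arm motions, so a
wrist inertial sensor alone confuses them; conversely, an egocentric camera
sees *which* object the hand touches but not *how* the arm moves, and it
confuses activities performed on the same objects. `actifuse` implements a
window-based fusion pipeline that combines both sensor families and the
leakage-aware evaluation protocols needed to assess it honestly, together
with a fully seed-controlled synthetic scenario generator so that every
stage — and the claim that fusion beats each single modality — can be
validated without access to wearable recordings.

## Method

**Inertial features.** Each 50 Hz wrist stream is cut into timespan-defined
sliding windows (length 1000 ms, overlap 50% or 75%; windows are defined by
`[t_s, t_e)` rather than by sample count, so dropped readings do not shift
the grid). Per window and axis the package computes mean, median, standard
deviation, population variance, inter-quartile range, median absolute
deviation, Fisher excess kurtosis and a 10-bin value entropy, plus spectral
energy `(1/N) Σ_{k≥1} |X_k|²`, spectral entropy of the normalized non-DC
power spectrum, and the DC mean `X_0/N`; cross-axis Pearson correlations, a
low-pass gravity estimate `g ← 0.9 g + 0.1 a` and the gravity-to-axis
orientation angles complete a 42-vector per device, concatenated
left-then-right into 84 features.

**Vision features.** Per video frame, detections of the hand (the `person`
class of common pre-trained detectors) and of the object classes are
reduced to an interaction vector: for every catalog class, the fraction of
that object's bounding box covered by the hand box, `area(hand ∩ obj) /
area(obj)`; frames without a hand detection carry a sentinel vector of −1.
Frame vectors are averaged over windows of 10 frames with stride 5, so
sustained interaction scores higher than a hand passing over an object.

**Alignment and fusion.** Devices are synchronized by the stillness
landmark: recordings start motionless, and the first magnitude deviation
from the resting baseline marks a common event from which per-device clock
offsets are computed. After trimming all modalities to their common
timespan, each vision window `[t_s, t_e)` is matched to the inertial window
with the smallest start `t_s' ≥ t_s`. *Early fusion* concatenates the 84
inertial and the interaction features into one model; *late fusion*
(probability stacking) fits a random forest on the inertial block and a
logistic model on the vision block, appends each model's class
probabilities to its own block, and fits a meta classifier on the
concatenation.

**Evaluation.** Because consecutive windows overlap, instances are first
de-overlapped (every other vision window; every fourth inertial window) so
that train and test never share raw samples. Protocols: repeated stratified
k-fold cross-validation (fresh folds per repeat), cross-subject fixed
splits with optional class-balancing oversampling of the training set, and
an 80/20 grid search with an inner 5-fold CV. Reports carry per-class and
macro precision/recall/F1, with the `none` background class included in the
macro average.

## Worked example

The confusable design is the acid test for fusion: two classes share the
same motion template but touch different objects, two share the object but
move differently.

```r
library(actifuse)

cfg       <- confusable_moderate_noise_config(seed = 1)
cohort    <- generate_cohort(cfg)
instances <- cohort_instances(cohort)   # align, window, featurize, de-overlap
instances
#> <fused_instances> 750 instances, 5 classes (imu: 84, vision: 10)

report <- repeated_cv(instances, mode = "late", k = 5, repeats = 2, seed = 1)
report
#> <eval_report> 5-fold CV x 2 repeats (late) (n = 750)
#>        class precision recall    f1
#>  drink_water     0.984  0.984 0.984
#>         none     0.971  0.978 0.974
#>    take_meds     0.979  0.975 0.977
#>   take_snack     1.000  0.979 0.989
#>   wipe_mouth     0.975  0.983 0.979
#> macro: precision 0.982, recall 0.980, F1 0.981

imu_only <- repeated_cv(instances, mode = "imu", k = 5, repeats = 2, seed = 1)
sprintf("late-fusion macro F1 %.3f vs inertial-only %.3f",
        report$macro["f1"], imu_only$macro["f1"])
#> "late-fusion macro F1 0.981 vs inertial-only 0.750"
```

The inertial-only model cannot separate the motion-sharing pair (its macro
F1 saturates near 0.75 on five classes), while the stacked model uses the
object evidence to resolve it.

A thin command-line front end is installed with the package
(`system.file("cli", "actifuse", package = "actifuse")`) with `simulate`
and `run` subcommands over YAML configurations; see `?run_pipeline`.

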