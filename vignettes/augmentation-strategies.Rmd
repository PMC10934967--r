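---
title: "Augmentation strategies for stroke-patient activity recognition: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmentation strategies for stroke-patient activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(strokehar)
```

## The problem

Stroke survivors with hemiparesis produce movement data that are sparse
(few patients, few repetitions) and heterogeneous (attenuated amplitudes,
idiosyncratic kinematics, large inter-subject variability).  Classifiers of
activities of daily living (ADL) trained on such data generalize poorly to
unseen patients.  `strokehar` implements the experimental machinery for
studying remedies: time-series augmentation (rotation, permutation,
time-warping), joint training with non-disabled (ND) data, transfer
learning, and a stronger architecture (InceptionTime), all evaluated under
leave-one-subject-out cross-validation (LOSOCV) with macro-F1 scoring.

Because clinical recordings cannot ship with a package, the cohorts used by
the tests and the acceptance script are synthetic, produced by a generator
whose statistical structure mirrors what is reported for real ND/stroke ADL
recordings.  Everything downstream (preprocessing, augmentation, models,
protocols) is agnostic to whether segments come from the generator or from
a real segment table read with `read_cohort()`.

## The synthetic cohort model

Each movement class has a latent template: per channel, a sum of 3–6
Gaussian bumps with random centres, widths and signed amplitudes
(band-limited, multi-peaked — a structural stand-in for real ADL traces,
not a biomechanical model).  Channels are organised as five IMU sensors ×
(tri-axial accelerometer + tri-axial gyroscope); gyroscope channels are
scaled time-derivatives of the accelerometer channels so the two modalities
live on visibly different scales, which is what the modality-scaling stage
of preprocessing must correct.

A subject's rendering of template $T$ is a variance-preserving mix

$$x = a \odot \big(w_T\,T + w_S\,S + w_J\,J_r\big) + \varepsilon,$$

where $S$ is a subject-level smooth perturbation (fixed across repetitions
of a class), $J_r$ a repetition-level jitter, $\varepsilon$ white noise,
and $a$ the per-channel amplitude scale.  The weights satisfy
$w_T^2 + w_S^2 + w_J^2 = 1$ and are solved analytically from the target
inter-subject coherence $\kappa$ so that the mean pairwise Pearson
correlation of repetition-averaged signals equals $\kappa$:

$$\kappa = \frac{w_T^2}{w_T^2 + w_S^2 + w_J^2/R},$$

with $R$ the number of repetitions.  The defaults target the group
coherences reported for real cohorts (ND ≈ 0.226, stroke ≈ 0.048);
`measure_coherence()` recovers them within the tolerance of the acceptance
suite without any empirical tuning constant.  The variance-preserving form
matters: adding perturbations *on top of* the template would make
low-coherence (stroke) signals several times more energetic than ND
signals, inverting the observed amplitude contrast.  With the mix, signal
energy is governed by the amplitude scale alone, and stroke segments show
the expected smaller peaks.

Two further structural choices:

* **Style vs. class-specific perturbation.**  The subject-level
  perturbation splits into a *style* component shared by all of a
  subject's classes (65% of its variance by default) and a class-specific
  component (35%, `class_specific_frac`).  Both lower inter-subject
  coherence identically, but only the class-specific part erodes the class
  signal itself.  This mirrors real movement data, where inter-subject
  variability is largely subject-wide (posture, habit, compensation)
  rather than independent noise per movement.  With a purely
  class-specific perturbation at stroke-level coherence, held-out-subject
  classification collapses to chance and no strategy comparison has
  signal; the split restores a learnable—but still hard—problem.
* **Severity coupling.**  Stroke subjects draw a severity score uniformly
  over 33–66 (an FMA-like scale, ND carries the maximum 66).  The
  normalised deficit scales (i) affected-side amplitude attenuation
  (down to `amplitude_ratio_stroke` = 0.6 at worst severity, with weight
  0.3 on unaffected-side and trunk sensors), (ii) a tempo stretch,
  (iii) the subject's individual coherence, linear around the group target
  (`severity_coherence_slope` = 1), and (iv) the subject's orientation
  offset sd, affine in the deficit with mean factor 1 (more impaired
  subjects deviate more in compensatory posture).  Every difficulty channel
  therefore worsens with severity, which is what produces the positive
  severity–F1 correlation and the negative gain–baseline correlation that
  the report stage measures.

Per-sensor orientation offsets (rotations of sd 5° for ND, 45° for stroke
subjects, applied identically to the accelerometer and gyroscope triads of
a sensor) model mounting variability and compensatory posture — for
hemiparetic users, sensor pose on the affected arm varies far more than
for ND wearers.  Orientation offsets are themselves a source of measured
per-channel incoherence, so the calibration divides the coherence target
by the expected correlation attenuation of the composed random rotations,
$\rho(\sigma) \approx (1 + 2e^{-\sigma^2})/3$, before solving for the mix
weights; with this correction the measured stroke coherence lands on the
target almost exactly.  Attributing a substantial share of stroke
inter-subject incoherence to orientation rather than to additive
perturbation is also what gives rotational augmentation its mechanism: a
held-out subject arrives with unseen sensor orientations, and training on
rotated copies teaches orientation robustness — the standard
interpretation of why rotation is the most effective transform on
hemiparetic movement data.  The stroke orientation sd was calibrated once
so that this directional property is expressed, then frozen.  Raw segment
lengths vary by ±20% around the nominal length and by the subject's tempo,
exercising the resampling stage nontrivially.

What the generator does **not** emulate: sensor noise physics, gravity
components, realistic kinematic constraints, or the long-tailed class
confusability structure of real ADL sets.  Passing desk-scale tests
therefore demonstrates that the *machinery* behaves and that the *relative*
orderings of training strategies are recoverable under the assumed
statistical structure — not that absolute F1 levels transfer to real
recordings.

## Preprocessing

The chain follows the order: linear resampling of every segment to a fixed
length (reference 3700 samples), per-segment per-channel mean subtraction,
modality scaling (all accelerometer channels divided by one constant, all
gyroscope channels by another; the reference constants 2.537 and 0.478 are
pooled standard deviations, and `divisor_mode = "estimate"` re-derives them
from the data at hand), a trailing moving average of the last 10 samples,
and sliding windows of 740 with stride 150 — exactly 20 windows per
segment.  Centering and scaling commute; smoothing is applied after
scaling so the smoothed signals keep the unit-variance interpretation.
The trailing average uses a shorter window during the first $m-1$ samples
rather than zero padding, which would manufacture onset transients.
Windows never cross segment boundaries, and test windows always belong to
the held-out subject only — leakage is excluded structurally and asserted
on every protocol run.

## Augmentation transforms

* **Rotation**: each (sensor, modality) triad is treated as a 3-vector per
  time point and rotated by a random axis (uniform on the cube, normalised)
  and angle (uniform over ±90°), constant over the window.  By default both
  triads of a sensor share one rotation (`mode = "sensor"`): that is the
  physically consistent model of a re-oriented device, and it keeps the
  accelerometer–gyroscope coupling of a sensor intact — rotating the two
  modalities independently (`mode = "independent"`, also available, as is a
  per-modality `"shared"` mode) produces accel/gyro combinations no
  physical mounting can generate, which pushes augmented data off the data
  manifold.  Rotation is an exact isometry per triad (Rodrigues form,
  right-handed).
* **Permutation**: the window is cut into 4 pieces of different random
  lengths (each at least `max(2, W/20)`) and the pieces are reordered; the
  multiset of rows is preserved exactly.
* **Time-warping**: a smooth positive speed curve (cubic spline through 4
  knot multipliers ~ N(1, 0.2), clipped below) is accumulated and
  renormalised into a monotone warp with fixed endpoints; the window is
  linearly interpolated at the warped positions.

All transforms are label- and shape-preserving and fully seed-controlled;
dataset-level augmentation (`augment_dataset()`) transforms stroke windows
only, adding one copy ("single") or two copies from disjoint seed streams
("double").  `balance_by_augmentation()` implements the class-balancing
strategy used for imbalanced datasets: classes below a target count gain
transformed copies (sources cycled, fresh seeds) until the target is met.

## Models and optimization

The Conv1D baseline stacks four valid (unpadded) temporal convolutions of
kernel 5, stride 2 and 32/64/128/256 filters, flattens, and applies dense
layers of 800/200/52 with ReLU and dropout 0.7 after the first two.  The
740×30 reference input propagates to temporal lengths 368/182/89/43 and a
flatten width of 11008.  Dropout is applied to the *outputs* of the first
two dense layers.  The 200-unit activation is the penultimate feature used
for embedding export.

InceptionTime stacks six Inception modules (bottleneck 1-convolution to 32
channels; parallel same-padded convolutions of kernels 10/20/40 with 32
filters each; a max-pool-3 branch projected by a 1-convolution; channel
concatenation to 128, batch norm, ReLU), with a residual shortcut
(1-convolution + batch norm on the block input) every third module, global
average pooling and a dense softmax head.  Convolutions that feed a batch
norm carry no bias.  Both models are trained with AdamW (lr 0.001, betas
0.9/0.999, eps 1e-8, decoupled weight decay 0.01 on weight matrices only)
on cross-entropy, batch size 256, ~5200 iterations at full scale, and are
scored by the median validation macro-F1 over iterations 5000–5009.  The
iteration budget is held fixed when augmentation enlarges the training set,
so every condition sees the same number of updates.

Because no deep-learning framework is available to R in this environment,
the forward/backward passes and the optimizer are implemented in the
package (the im2col convolution kernels in compiled code); all backward
passes are verified against finite differences in the test suite, and
training is bit-reproducible given the config seed.

Macro-F1 (unweighted mean of per-class F1, classes absent from both sides
excluded) is used at window level; the class-balanced design (equal
repetitions × windows per class) makes macro and weighted averages nearly
identical, and per-window scoring matches the role of windows as the unit
of classification.

## Evaluation protocols

`run_losocv()` makes one fold per stroke subject; the training set is the
other stroke subjects (plus all ND subjects in joint conditions), plus
transformed stroke copies per the augment plan; the fold's test set is
every window of the held-out subject.  `run_tstr()` trains on transformed
copies only and tests on originals — with the transform forced to the
identity it reproduces the baseline exactly, which the test suite asserts.
`run_transfer()` pretrains once on ND windows, then per fold re-instantiates
the final dense layer and fine-tunes everything on stroke data.
`run_subsets()` trains on random subsets of n stroke subjects and evaluates
all excluded subjects, reporting means, sds and percent increases; the
draw counts per n are configurable (smaller subsets deserve more draws).
LOSOCV repetition counts per augmentation condition are likewise
configurable (full-scale studies use three to nine).

## Desk-scale profile and problem sizes

`desk_profile()` fixes the scaled configuration used by the acceptance
suite: 6 ND + 6 stroke subjects, 8 classes, 3 repetitions, segments ≈ 640
samples resampled to 640, windows 128 / stride 128 (5 per segment), a
narrower Conv1D (12/24/48/48 kernels, dense 96/64/8, dropout 0.3 — lighter
regularization for the smaller capacity), batch 48, 600 iterations, scoring
window 550–559, estimated divisors, three seeds.  Under this profile a
four-condition LOSOCV comparison (stroke-only, ND+stroke, stroke + single
rotation, TSTR rotation) runs in minutes per seed on one CPU.  Desk-scale
results are read *directionally* (orderings of conditions, signs of
correlations), never as estimates of full-scale F1 levels.

## Numerical choices and degenerate inputs

* Divisors of zero (zero-variance modality) and empty training sets are
  errors, not silent passes; non-finite training loss aborts with a
  diagnostic.
* `measure_coherence()` aligns repetitions by linear interpolation to a
  common length, excludes zero-variance pairs with a warning, and requires
  at least two contributing subjects.
* The permutation sampler redraws until all pieces respect the minimum
  length; the probability-zero degenerate rotation axis draw is redrawn.
* Tie-breaks in max pooling take the earliest position, matching the
  backward pass routing.
* All derived seeds go through a 31-bit mixing hash (`mix_seed()`), so
  every stochastic stage has an independent, reproducible stream.

## Known limitations

* Synthetic cohorts cannot validate absolute classification levels, only
  orderings under the assumed structure; with six stroke subjects per seed
  the per-seed correlation estimates are noisy, which is why the report
  stage pools subjects across seeds.
* At this cohort size, stroke-only LOSOCV confounds a held-out subject's
  own difficulty with the severity mix left in its training folds (holding
  out a mild subject leaves the severe subjects as training data), which
  can cancel or invert the severity–F1 correlation.  The joint ND+stroke
  baseline, whose training sets are dominated by the constant ND pool, is
  the reliable condition for that correlation at desk scale — consistent
  with full-scale reports, where the joint baseline also yields the
  stronger severity correlation.
* The PCA projection in `embed_features()` is a linear stand-in for the
  nonlinear 2-D embeddings (e.g. UMAP) typically used to visualise
  penultimate features; exported CSVs can be fed to any such tool.
* The generator's severity coupling is linear and its perturbations are
  Gaussian smooth curves; real severity effects are richer (spasticity,
  synergy patterns) and not modelled.
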