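# strokehar

Tools for studying how time-series data augmentation and training strategy
affect deep classification of activities of daily living (ADL) from
body-worn IMU sensors in people with hemiparetic stroke — a regime where
labelled data are sparse and patient movement is heterogeneous.

Stroke survivors benefit from home rehabilitation systems that recognise
which everyday movement is being performed from wrist/arm/trunk inertial
sensors (5 sensors × tri-axial accelerometer + gyroscope = 30 channels).
Classifiers trained on such cohorts degrade badly on unseen patients.  The
package implements the full experimental pipeline for comparing remedies:

* **Synthetic cohort generator** emulating non-disabled (ND) vs. stroke
  movement statistics: per-class latent templates; a variance-preserving
  mix of template, subject style and class-specific perturbation solved
  analytically from target inter-subject coherences (ND ≈ 0.226, stroke
  ≈ 0.048); severity scores (FMA-like, 33–66) coupled to amplitude
  attenuation and distance-from-template; per-sensor orientation offsets;
  hemiparesis-side asymmetry.
* **Preprocessing** exactly as used for the reference recordings: linear
  resampling to 3700 samples, per-channel centering, modality scaling
  (accelerometer ÷ 2.537, gyroscope ÷ 0.478, or re-estimated pooled SDs),
  trailing 10-point moving average, sliding windows 740/150 (20 windows
  per segment).
* **Augmentation**: seed-controlled rotation (random axis, ±90°, per
  sensor–modality triad), 4-piece permutation, and smooth time-warping;
  single/double dataset augmentation of stroke data; class balancing.
* **Models**: the Conv1D baseline (conv 32/64/128/256, kernel 5, stride 2;
  dense 800/200/52; dropout 0.7) and InceptionTime (6 modules, bottleneck,
  kernels 10/20/40, residuals, GAP head), implemented natively with
  verified backpropagation and AdamW (lr 0.001, batch 256, ~5200
  iterations, median F1 over iterations 5000–5009).
* **Protocols**: leave-one-subject-out cross-validation (LOSOCV), single /
  double augmentation conditions, train-on-synthetic-test-on-real (TSTR),
  transfer learning from ND-pretrained weights (final dense layer
  re-instantiated), stroke-subset sweeps, severity–F1 and gain–baseline
  correlation reports, penultimate-feature export for 2-D embedding.

The score throughout is the macro-averaged F1 over classes, per held-out
subject, summarised as the median over a fixed late-training iteration
window.

## Worked example

A desk-scale experiment (6 ND + 6 stroke synthetic subjects, 8 classes,
windows of 128 samples, 600 training iterations — minutes on one CPU):

```r
library(strokehar)

prof <- desk_profile(seed = 1)
ws <- desk_windows(prof)          # generate + preprocess
ws
#> <window_set> 2400 windows of 128 x 30 (12 subjects, 8 classes)

base <- run_losocv(ws, condition("stroke", "Stroke"),
                   prof$train, prof$model)
joint <- run_losocv(ws, condition("ndstroke", c("ND", "Stroke")),
                    prof$train, prof$model)
rot <- run_losocv(ws, condition("stroke_rot", "Stroke",
                                augment_plan("rotation", n_copies = 1,
                                             base_seed = mix_seed(1, 7))),
                  prof$train, prof$model)

round(c(stroke = base$mean_f1, nd_stroke = joint$mean_f1,
        stroke_rot = rot$mean_f1), 3)
#>     stroke  nd_stroke stroke_rot
#>      0.180      0.245      0.188
```

Each number is the mean over the six LOSOCV folds of the held-out
subject's median-window macro-F1.  The orderings are the point: pooling ND
data with stroke data helps (0.245 > 0.180), and adding one rotated copy
of the stroke training data helps (0.188 > 0.180) — the same directional
conclusions reached at full scale on real recordings, where joint training
lifts the stroke baseline from 47.3% to 54.0% and rotational augmentation
to ~60%.  Absolute desk-scale values are much lower than full-scale ones
(tiny cohort, short windows, small model) and are only read directionally.

Severity coupling is probed at the individual level:

```r
rep <- correlate_severity_f1(
  data.frame(subject_id = joint$per_subject$subject_id,
             severity = joint$per_subject$severity), joint)
rep
#> <correlation_report> r = -0.009 (p = 0.9863, n = 6)
```

A single six-subject cohort is far too small for a stable estimate — this
seed happens to land near zero.  The acceptance suite pools subjects
across three independent cohorts before asserting the positive direction;
the vignette discusses why the joint (ND + stroke) baseline is the right
condition for this correlation at desk scale.

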