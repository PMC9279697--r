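# kinedep

Skeleton-based recognition of depression and of its severity from
Kinect-V2-style motion recordings of a scripted stimulus task.

Depression leaves measurable traces in body kinematics — psychomotor
retardation shows as slower, smaller movements, delayed and more variable
reactions, a head-down posture and increased body sway. `kinedep` implements
an end-to-end pipeline for detecting these signatures in 25-joint skeleton
streams (3-D position plus orientation quaternion per joint, 30 Hz) recorded
while a standing subject follows six audio cues: lift both hands, lift the
left hand, lift the right hand, turn right, turn left, reset.

The package provides:

* **IO** — long-format CSV and JSONL dialects for skeleton recordings with
  schema validation (`read_recording()`, `write_recording()`,
  `validate_schema()`), plus subject metadata tables.
* **Preprocessing** — Euler→quaternion conversion validated against
  rotation matrices, capture-volume checks, assembly of `[T × 175]` feature
  tensors with missingness masks, cue segmentation, min-max normalization
  (training-split bounds, clipped elsewhere), and length regularization
  (`as_feature_tensor()`, `minmax_normalize()`, `regularize_length()`).
* **Cohorts** — HDRS-24 severity banding (NONE [0,8], PROBABLE (8,20],
  MEDIUM (20,35], SEVERE >35), binary-task screening, dataset assembly and
  reproducible stratified splits (`band_score()`, `screen_binary()`,
  `build_dataset()`, `split_dataset()`).
* **Model** — a TCN-ResNet18: three dilated causal temporal convolution
  blocks (kernel 3, dilations 1/2/4, end-to-end skip connections),

      F(s) = (x ⊗_d f)(s) = Σ_{i=0}^{k−1} f(i) · x_{s−d·i},

  a linear projection to 768 dimensions reshaped to (3, 16, 16), a standard
  ResNet-18 trunk, and a residual log-softmax output
  `C = LogSoftmax(W_s Y + F(Y))`. The network and its backpropagation are
  implemented in-package on BLAS matrix algebra; no deep-learning framework
  is required.
* **Training / evaluation** — Adam (lr 0.0025, batch 32, dropout 0.2),
  negative log-likelihood loss, confusion-matrix reports with accuracy,
  sensitivity (recall on the depressed class) and specificity (recall on
  the non-depressed class), broom-style `tidy()`/`glance()` and
  `autoplot()` methods, and a one-call `run_pipeline()`.
* **Synthetic data** — a seeded simulator of the stimulus task with
  severity-dependent kinematic effects (amplitude, velocity, reaction
  delay, head pitch, sway), minimum-jerk trajectories and exact bone-length
  conservation, so the whole pipeline is exercisable without clinical
  recordings (`generate_recording()`, `generate_cohort()`,
  `simulate_cohort()`).

## Worked example

Simulate a strongly separable binary cohort (40 subjects per class, 10 s
recordings), preprocess, split 70/30, train 30 epochs, evaluate:

```r
library(kinedep)

res <- run_pipeline(list(
  task = "binary",
  simulate = list(n_per_band = c(NONE = 40, PROBABLE = 0, MEDIUM = 40, SEVERE = 0),
                  duration = 10, effect_multiplier = 2, seed = 11),
  split = list(test_fraction = 0.3, seed = 5, stratified = TRUE),
  train = list(epochs = 30, seed = 9)
))
res$report
```

```
<eval_report> binary task, n = 24
                predicted
true             NON_DEPRESSION DEPRESSION
  NON_DEPRESSION             12          0
  DEPRESSION                  0         12
accuracy 100.0%, sensitivity 100.0%, specificity 100.0%
```

The 24 held-out subjects (12 per class under the stratified split) are all
classified correctly: with exaggerated effect sizes (`effect_multiplier = 2`)
the severity signatures — halved movement amplitude and speed, ~0.5 rad head
pitch, larger sway — are easily separable. With `effect_multiplier = 0` the
classes are distributionally identical and the same pipeline lands at chance
(50% here), the package's negative control. Artifacts (metadata, split
manifest, checkpoint, history, JSON report, confusion CSV, run log) are
written to the run directory.

At clinical effect sizes, on real recordings, this task is far harder;
reported accuracies there are in the 60–80% range. See the methods vignette
(`vignettes/kinedep-methods.Rmd`) for the model, the severity-to-kinematics
mapping, and what the synthetic studies do and do not demonstrate.

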