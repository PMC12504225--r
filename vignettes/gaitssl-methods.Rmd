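---
title: "Self-supervised joint-moment estimation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised joint-moment estimation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Net joint moments (N·m/kg) are the standard surrogate for lower-limb joint
loading, but computing them requires synchronized motion capture and force
plates followed by inverse dynamics — expensive, lab-bound, and therefore
scarce. Joint *angles*, by contrast, are cheap to collect at scale.
`gaitssl` implements a two-stage estimator that exploits this asymmetry:

1. **Masked-reconstruction pre-training.** A Transformer auto-encoder is
   trained on unlabeled multichannel joint-angle windows. A fraction of the
   time-step tokens is replaced by a learnable mask embedding, and the model
   minimizes the MSE between its reconstruction and the original content of
   the masked positions. This forces the encoder to internalize the temporal
   continuity and inter-joint coordination of gait.
2. **Layer-frozen supervised fine-tuning.** The pre-trained encoder is
   adapted to map a joint's left/right angle channels to its left/right
   moments, with leading blocks optionally frozen, a reduce-on-plateau
   schedule, and early stopping on validation loss. A from-scratch baseline
   with the identical architecture quantifies what pre-training buys.

## Model

Windows of `W` samples across `C` channels are tokenized per time step
(patch length 1), mapped by a shared affine embedding to `d_model`
dimensions, summed with sinusoidal positional encodings
(`PE(pos, 2i) = sin(pos/10000^{2i/d})`, cosine for odd columns), and passed
through `n_blocks` post-norm attention blocks (multi-head self-attention,
then a ReLU feed-forward layer, each wrapped in residual + LayerNorm, with
dropout on both sublayer outputs). An affine head maps final tokens back to
channel space — reconstruction (`C` outputs) during pre-training, moments
(2 outputs, N·m/kg) during fine-tuning. The reference configuration is
`W = 64`, `d_model = 24`, 8 blocks, 12 heads, 2048 feed-forward units,
dropout 0.1, LayerNorm epsilon 1e-5.

Forward and backward passes are written out explicitly in R, with the
multi-head attention kernels in compiled code (RcppArmadillo); gradients are
verified against numerical differentiation in the test suite. Optimization
is Adam with L2 weight decay (1e-5), cosine annealing for pre-training and
the baseline, reduce-on-plateau (factor 0.5) for fine-tuning.

Design points the architecture left open, and how they were fixed:

* **Mask token before positional encoding.** Masked tokens are replaced
  first and positions added afterwards, so the model knows *where* a masked
  patch sits but nothing of *what* it contained (BERT-style). A consequence
  verified in the tests: perturbing masked-out input values changes neither
  predictions nor the loss.
* **Fixed masked count per window.** `round(ratio × n_patches)` positions
  per window (6 of 64 at the default 10%) rather than independent Bernoulli
  draws, keeping the pretext-loss support stable across windows.
* **Masked-only reconstruction loss.** The pretext loss is averaged over
  masked positions only (an `loss_on = "all"` mode exists). Pre-training
  rejects a mask ratio of zero, which would leave the loss undefined.
* **Post-norm block ordering** with ReLU and the stated epsilon.

## Channel transitions between the stages

Pre-training reads 18 channels; fine-tuning reads 2 (or 1, in cross-joint
cells). The transition is the largest gap the two-stage recipe leaves open,
and the package fills it as follows:

* a **fresh input projection** for the smaller channel set is warm-started
  from the pre-trained embedding rows of the matching channels;
* the **regression head** is warm-started from the reconstruction readout of
  each target's same-joint angle channel, then calibrated per output channel
  by the closed-form least-squares affine map from its warm predictions to
  the training moments. Moments are roughly proportional to same-joint
  angles, so this readout is an informative starting point; the calibration
  fixes its scale and offset from labels alone. The scratch baseline, which
  has no readout to transfer, receives the analogous output-bias
  initialization at the training-target mean, so neither arm spends its
  step budget learning the moment offset.

## The synthetic gait generator

The generator emulates the structure of a pediatric treadmill cohort: 55
subjects in five age strata (11:10:15:11:8), three speed conditions per
subject, cycles time-normalized to a 100-sample 0–99% grid, 18 kinematic
channels with the standard naming (`Lankleflex` … `Trunktilt`).

* **Waveforms.** Each channel is a mean offset plus `K = 4` cosine
  harmonics with geometrically decaying amplitudes (base amplitudes 5–60°,
  typical of sagittal gait curves); right-side channels are the left-side
  template shifted half a cycle, giving bilateral symmetry. Waveforms are
  exactly periodic before noise.
* **Subjects.** Per-channel log-amplitude factors (s.d. 0.25) and phase
  offsets (s.d. 0.5 rad) perturb the template per subject, scaled up ~1.5×
  for the youngest stratum and down for the oldest — gait variability
  shrinks as gait matures. Body mass and leg length come from
  stratum-specific distributions calibrated to cohort-level means
  (~35.7 kg, ~0.73 m). All draws derive from `(seed, subject_id)`, so any
  subject regenerates independently.
* **Speeds.** Amplitude scaling 0.85 / 1.00 / 1.15 for slow / comfortable /
  fast.
* **Noise.** Angle noise 1.0° (marker-level measurement error); moment
  noise 0.05 N·m/kg (inverse-dynamics uncertainty).
* **Moments.** The six sagittal moments follow
  `m_j = clamp(a_j θ_j + b_j Δθ_j + Σ_{k≠j} c_jk θ_k, ±s_j) + ε`, with the
  velocity term a first central difference. The coupling matrix is
  diagonally dominant (`|a_j| > Σ|c_jk|`), so same-joint angles are always
  the strongest predictors — the property behind the cross-joint matrix
  structure. Saturation (`s_j = 2` N·m/kg) adds a mild, controllable
  nonlinearity.

What the generator does *not* emulate: inverse-dynamics labels (moments are
a known forward model, not Newton–Euler mechanics), ground reaction forces,
pathological gait, non-stationarity within a session, or soft-tissue
artifact structure. Passing the desk-scale benchmarks therefore shows that
the pipeline behaves as designed under controlled conditions; it does not
certify error magnitudes on measured data.

## Desk-scale study design

All property benchmarks run on one CPU in minutes. Problem sizes were fixed
once as part of the study design:

* dataset: 12 subjects × 3 speeds × 3 cycles (100-sample grid), giving
  2,160 windows of 24 samples at stride 4;
* model: `d_model = 16`, 2 blocks, 2 heads, 32 feed-forward units;
* pre-training: Adam 1e-3, batch 64, 100 epochs; fine-tuning and baseline:
  Adam 1e-3, batch 16, 30 epochs (batch 16 keeps the per-epoch update count
  meaningful even at a 5% label fraction);
* label scarcity: moments are labeled for **2 of 12 subjects** only; their
  cycles split ~75/25 into train/validation, and the 10 unlabeled subjects
  form the test set. Pre-training still sees every subject's unlabeled
  windows — exactly the asymmetry the method is designed to exploit. Label
  fractions {5%, 20%, 100%} subsample the labeled training windows through
  a nested permutation prefix, so smaller fractions are subsets of larger
  ones under the same seed.
* seeds: one shared pre-trained checkpoint; five fine-tune/baseline seeds.
  Reported values are means across seeds, with per-seed values retained.

Two desk-protocol deviations from the full-scale recipe deserve note. At
two blocks, freezing granularity is too coarse: freezing one of two blocks
(or the fresh input projection) measurably handicaps the fine-tuned arm, so
the desk protocol trains all blocks (`n_frozen_blocks = 0`) and the frozen
projection option stays off. The 6-of-8 freezing contract — bit-identical
frozen parameters after fine-tuning, ~75% frozen encoder fraction — is
validated separately on the full 8-block architecture. Learning rates are
likewise desk-scale choices (1e-3 instead of 1e-4/1e-6): with two orders of
magnitude fewer optimization steps, the full-scale rates would leave both
arms frozen near initialization.

The cross-joint matrix is produced by fine-tuning a single-channel model
per (input angle, target moment) cell from the shared pre-trained
checkpoint (12 epochs at a 20% label fraction, cycle-grouped splits); the
parameter-recovery check uses a pure linear moment model (no damping,
coupling, saturation or noise) and verifies that fine-tuned predictions
reach below 5% of target variance.

## Numerical and procedural details

* **Determinism.** A single master seed fans out through named substreams
  (subjects, noise, init, shuffle, mask, dropout, splits), so every stage is
  bit-reproducible in isolation; training twice with one seed gives
  identical weights.
* **Filtering.** The low-pass step is a zero-phase 4th-order Butterworth
  (`signal::filtfilt`) at a 15 Hz cutoff, applied to whole cycles before
  any windowing; cutoffs at or above Nyquist are rejected.
* **Time normalization** is linear interpolation onto an equally spaced
  grid whose endpoints coincide with the input's; affine signals resample
  exactly.
* **Standardization** is per-channel z-scoring with training-partition
  statistics; zero-variance channels clamp their scale to 1 with a warning.
  Targets are never standardized — moments stay in N·m/kg end to end.
* **Splits** shuffle groups (windows, cycles or subjects) under the seed
  and cut by cumulative counts; realized sizes deviate from the requested
  fractions by less than one group, and no group spans partitions. With
  stride-1 windows, window-level splits leak overlapping content between
  partitions; grouped splits exist for exactly that reason, and the desk
  benchmarks use cycle- or subject-grouped labeling throughout.
* **Peak/valley tables** locate strict local extrema of the *observed*
  cycle-averaged curve within a ±5%-of-cycle half-window and report
  absolute and relative errors there; flat curves return an empty table
  with a warning.
* **Ties and degenerate inputs.** `round()` half-to-even conventions decide
  masked counts and subsample sizes; a mask ratio that would leave nothing
  visible is an error, as is a label fraction that yields zero windows.

## Known limitations

* The moment model is a deliberately simple stiffness–damping–coupling
  surrogate; absolute MSE values on synthetic data are not comparable to
  inverse-dynamics benchmarks.
* Fine-tuning transfers representations through a fresh input projection;
  when the fine-tuning channels were never part of pre-training, the warm
  start degrades to a column-mean initialization.
* The desk-scale Transformer is two blocks wide; conclusions about freezing
  strategies at eight blocks rest on the freezing-contract tests, not on
  the desk benchmark.
* Training runs on a single CPU; no mini-batch parallelism or GPU path is
  provided.
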