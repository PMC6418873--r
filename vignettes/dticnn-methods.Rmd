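---
title: "Methods: 3D convolutional classification of diffusion-tensor scalar maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D convolutional classification of diffusion-tensor scalar maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Group differences in brain microstructure are often probed with diffusion
tensor imaging (DTI): each voxel carries a symmetric positive-semidefinite
3×3 tensor describing local water diffusion, summarized by scalar maps —
fractional anisotropy (FA), mean/axial/radial diffusivity (MD, AD, RD).
`dticnn` implements a two-group (e.g. male/female) classification pipeline
over whole-brain scalar maps with a deliberately small 3D convolutional
network, and the analyses that surround it: which first-layer features
separate the groups (in mean activation and in histogram entropy), and which
atlas regions are most discriminable when the classifier is retrained on each
region alone.

Because the package is developed and tested without access to a real cohort,
it ships a first-class synthetic-data module that generates diffusion-tensor
phantoms with *known, injected* group differences. All quantitative claims in
the test suite are about recovering those known differences, or about
chance-level calibration when no difference exists.

## The classifier

The network has exactly three hidden layers, each
`conv(3×3×3, stride 1, SAME) → batch norm → ReLU → max-pool(2×2×2, stride 2,
ceil mode)`, with 32, 64 and 128 feature maps respectively; the final 128
maps are flattened into a single linear map to 2 logits and a softmax. There
are no intermediate fully connected layers — the linear readout keeps the
parameter count small for cohort-scale sample sizes. For the published input
grid 58×70×58 the pooled shapes are 29×35×29 → 15×18×15 → 8×9×8, so the
linear layer sees 8·9·8·128 = 73 728 features (147 458 parameters including
biases).

Training minimizes the *summed* softmax cross-entropy over each mini-batch
(probabilities clipped at 1e−12) with Adam at α = 0.001, β₁ = 0.9,
β₂ = 0.999, ε = 1e−8, batch size 45, per-epoch seeded reshuffling, and the
last partial batch kept. Weights start from a truncated normal (SD 0.1, cut
at ±2 SD), biases at zero, batch-norm scale/shift at 1/0. After every epoch
the model is scored on the fold's validation block; the returned model is the
snapshot with the highest validation accuracy (earliest epoch wins ties).

Numerical/design choices the source material leaves open:

* **Pooling geometry.** 2×2×2 windows with stride 2 in ceil mode is the only
  configuration that makes the documented 58→29→15→8 arithmetic work.
* **Sum vs mean cost.** The cost is the batch *sum*. Adam's per-parameter
  normalization makes the optimizer nearly invariant to this constant, so the
  choice is cosmetic for training but matches the cost definition used in the
  tests.
* **Batch-norm inference moments.** Inference uses the *cumulative mean* of
  the batch moments over all training batches (the estimate the original
  batch-normalization algorithm prescribes), rather than an exponential
  moving average. At desk scale a fold sees only tens of update steps, and an
  EMA with any conventional momentum would still be dominated by its (0, 1)
  initialization, corrupting every inference-mode prediction. With the
  cumulative mean, inference output is independent of batch composition and
  stable for short schedules.
* **Epochs.** No stopping rule is inherited; the demo configuration uses 10
  epochs and snapshot selection, bounded-compute choices, not convergence
  claims.
* **Conv bias gradients** are analytically zero through batch normalization
  (the mean subtraction absorbs any channel-constant shift); they are kept
  only for structural fidelity to the published architecture.

The heavy numerics (convolution via shifted-column patch matrices and BLAS
GEMM, pooling, batch norm) run in single precision in C++; a slower
double-precision implementation of every operation is kept in the package and
the test suite asserts the two paths agree, so the fast path never defines
its own semantics.

## Evaluation protocol

`make_fold_plan()` shuffles subjects once (seeded) and cuts them into 10
near-equal blocks; fold *i* tests on block *i*, validates on block *i*+1 (mod
10), and trains on the remaining eight — realizing simultaneously the
80%/10%/10% split and 10-fold averaging, with test sets disjoint and jointly
covering the cohort. The reported figure is the mean of the 10 test
accuracies (the package also reports the SD across folds). The SVM baseline
flattens each volume to a voxel vector, standardizes per voxel on the fold's
training portion (train+validation, which is what the SVM is fit on — the
source is silent on this; recorded here), and fits a linear L2-regularized
hinge-loss SVM with C = 1 by dual coordinate descent. No SVM library exists
in the supported R stack, so the solver is implemented in the package and
tested against scikit-learn's hinge-loss optimum on a fixture.

## Feature statistics

For each of the 32 first-hidden-layer feature maps (post-activation,
post-pooling; the source does not say which stage was analyzed — this choice
is recorded in the output metadata) and each subject, the package computes
the mean voxel value and the Shannon entropy H = −Σ pᵢ ln pᵢ of the map
quantized to the 0..255 alphabet. Quantization is per-map min–max scaling
(constant maps quantize to all zeros); the log base is natural — any fixed
base rescales both groups identically. Groups are compared per feature with
two-sided Welch t-tests (robust to the unequal group sizes and variances
expected here), flagged at the Bonferroni threshold 0.05/32 ≈ 1.56e−3.
Degenerate features (constant statistic across subjects, e.g. a dead ReLU
channel) report t = 0, p = 1 rather than an error, so one dead channel cannot
poison the 32-row table.

One caveat the package inherits from the original workflow: the model whose
features are analyzed was trained on (most of) the same subjects, so feature
statistics are not perfectly null-calibrated even on label-randomized
cohorts — training can memorize group labels into the features. The null
expectation of "zero significant features" therefore holds only
approximately; the acceptance suite allows a small number of spurious flags.

## The synthetic cohorts

Each subject is a 3D grid of axially symmetric tensors (λ₂ = λ₃) with unit
mean diffusivity inside a central ellipsoidal "brain" (semi-axes at 30% of
each grid dimension; zero tensors outside, mimicking skull-stripped maps).
Given a per-voxel FA target *f*, the anisotropy parameter is the closed-form
inverse a = f/√(3−2f²), so the noiseless FA hits its target exactly —
this is what makes the generator contract testable to 1e−10. Principal axes
are seeded-random unit vectors; eigenvalue noise is additive Gaussian
(`noise_sd`, default 0.1) clipped at zero.

The atlas partitions the brain mask into connected gray-matter ROIs (outer
shell) and white-matter ROIs (core) by multi-source breadth-first region
growth from seeded random voxels; the demo scale is 6 gray + 4 white ROIs.
Tissue FA baselines default to 0.25 (gray) and 0.55 (white) — mid-range
values for cortical gray and coherent white matter. Every subject also
receives a global FA offset drawn from N(0, `subject_sd` = 0.02): this is
the between-subject biological variability against which mean-shift effect
sizes are expressed, and without which any constant group shift would be
trivially separable.

Two effect kinds create ground truth:

* **mean_shift** adds a constant to FA inside target ROIs with opposite signs
  per group. The constant is `d × s`, where `s` is the pooled within-group SD
  of per-subject ROI-mean FA estimated from the rendered cohort, so the
  realized Cohen's d equals the requested one by construction. (A design
  sketch of injecting at the eigenvalue level pre-noise was considered and
  rejected: FA is a nonlinear function of the eigenvalues, so the realized d
  would need empirical re-calibration anyway; injecting on the rendered maps
  makes the contract exact.)
* **texture_complexity** smooths one group's maps inside the target region
  (whole brain mask if no ROIs are given) with a Gaussian kernel of width
  `magnitude` voxels, using *mask-normalized* smoothing — the kernel weights
  are renormalized over the region so tissue values never mix with the zero
  background. Plain smoothing would drag boundary voxels toward zero,
  creating an edge ramp that *spreads* the intensity histogram and raises
  quantized entropy; normalized smoothing only narrows the within-tissue
  peaks, which is what lowers entropy, matching the intended direction
  (smoothed group = lower complexity). Group A ↔ "man" has the larger value
  when `direction = +1`.

What the generator does **not** emulate: anatomy (ROIs are random blobs),
raw diffusion-weighted acquisition (no gradient tables, eddy currents,
motion), spatial autocorrelation of real FA noise, and site/scanner effects.
A green signal-recovery test therefore establishes that the pipeline can
recover *stylized* effects of stated size at desk scale — not that it
reproduces the published accuracies on real data, which are explicitly out
of scope.

## Per-region discriminability

Each ROI is cut to its tight bounding box with out-of-mask voxels zeroed,
zero-padded symmetrically to at least 8 voxels per dimension (the
architecture's minimum), and the full nested-CV classification is rerun from
scratch on the crops — with the *same* fold plan for every ROI so the
accuracies are paired. For crops with any dimension below 16 the third
pooling stage is dropped (small inputs would otherwise collapse to single
voxels before the linear layer). The source is silent on whether ROI
classifiers reused whole-brain weights; training from scratch was chosen as
the cleaner reading of "repeated the same classification on each region".
The atlas recolored by per-ROI mean accuracy is written as a NIfTI map, and
ROIs are ranked per tissue class (ties broken by ascending id).

## Desk-scale stated world and what the tests assert

The demo configuration (also the acceptance setting) is a 200-subject cohort
on a 24×28×24 grid, 10 training epochs per fold: small enough for one CPU,
large enough for the binomial error bars around chance (±6.9 percentage
points at n = 200) to be meaningful. The acceptance suite asserts: the
analytic closed forms; the architecture and fold-plan structure; chance-level
calibration of both classifiers on a null cohort (within the 95% binomial
band); and recovery of injected effects — a d = 1.2 ROI mean shift plus a
1.5-voxel texture effect in a second ROI — by whole-brain accuracy, entropy
significance and direction (on a brain-wide texture cohort, where whole-map
entropy can actually move), and top-2 per-tissue ROI ranking over 5 seeds
(on a compute-scaled 16-cube ranking world). Signal-recovery training uses
12 epochs at batch 16 — about 120 optimizer steps, where the validation
curve plateaus; the published batch of 45 on a 160-subject training block
would yield only 4 steps per epoch, an optimization regime nothing like the
published ~19 steps/epoch, so desk-scale runs scale the batch proportionally.
Null-calibration runs use the stated 10 epochs (the null outcome is
insensitive to the protocol). The published
whole-cohort accuracies (from a thousand-subject cohort with GPU training)
are not reproducible at this scale and are not asserted anywhere.

## Known limitations

* Single-precision training: two runs agree bitwise only on the same BLAS;
  determinism contracts in the tests are within-machine.
* The record store keeps volumes as float64 HDF5 datasets — simple and
  portable, but larger than a float32 store would be.
* The CLI is a thin wrapper over the R API; it does not manage long-running
  jobs or partial restarts beyond retaining completed stage outputs.
* At n = 200 the CNN generalizes from strong injected effects but is far from
  the published real-data regime; nothing in this package should be read as
  a replication of those figures.
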