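---
title: "Synthesizing MR fingerprinting maps from magnitude T1-weighted MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing MR fingerprinting maps from magnitude T1-weighted MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MR fingerprinting (MRF) estimates voxelwise T1 and T2 relaxation times by
deliberately varying acquisition parameters (flip angle, TR) so that every
tissue traces a distinctive transient signal, then matching each measured
signal evolution against a precomputed dictionary of Bloch-simulated
candidates. The method needs a dedicated pulse sequence and reconstruction
chain, which most archived clinical examinations lack. `mrfsynth`
implements a pipeline that learns to *synthesize* the compressed MRF signal
from an ordinary magnitude T1-weighted (MPRAGE) volume: a bank of seven
parallel U-Net regressors maps each 2D MPRAGE slice to the seven real-valued
channels of the rank-4 SVD compression of the MRF signal, after which
standard dictionary matching turns the synthesized signal into T1, T2 and
proton-density maps. The package also ships the statistical machinery used
to assess agreement between acquired and synthesized relaxometry (Lin's
concordance correlation coefficient with clustered bootstrap intervals,
regional mean differences and coefficients of variation) and a digital
brain phantom generator so that the entire pipeline can be exercised and
tested without access to scanner data.

## Forward model

### Bloch simulation

`simulate_fingerprint()` integrates the Bloch equations for a single
isochromat with no off-resonance term. Each excitation applies a rotation
by the scheduled flip angle about a transverse axis at the scheduled RF
phase; the complex transverse signal is read at TE with `exp(-te/T2)`
decay; the magnetization then relaxes exponentially over the TR
(longitudinal toward equilibrium with T1, transverse toward zero with T2).
The sequence is balanced (no spoiling) by default because the emulated
acquisition is an SSFP train; `spoil = TRUE` provides ideal spoiling for
experimentation. This per-TR operator formulation was chosen because every
step is a closed-form affine map, which makes exact independent oracles
possible: the test suite checks the vectorized recursion against a
brute-force matrix-by-matrix stepping implementation (agreement to 1e-10)
and against the analytic fixed point of the constant-schedule recursion.

### Acquisition schedule

The acquisitions this package emulates publish their repetition time
(9.3 ms, 70° flip cap) but not the full flip-angle history, so
`default_schedule()` is an explicit configuration artifact: 500
inversion-prepared excitations at TR 9.3 ms, TE 2 ms, with flip angles
following five half-sine segments peaking at 70°, 35°, 55°, 25° and 60°
(capped at 70°). The segment structure gives the transient both strong
T1 sensitivity (inversion recovery across lobes) and T2 sensitivity
(SSFP behaviour within lobes). Every parameter is overridable; no claim is
made that this reproduces any scanner's exact fingerprints — only the
method is reproduced, which is all the desk-scale tests require.

### Dictionary, compression, matching

`build_dictionary()` simulates unit-proton-density fingerprints over a
(T1, T2) grid — default T1 100–3000 ms step 20 ms, T2 10–300 ms step 5 ms,
physically constrained to T2 ≤ T1 — and L2-normalizes each atom.
`compress_dictionary()` takes the SVD of the atom matrix and keeps the
first `k = 4` temporal singular vectors; on the default dictionary this
retains ≈ 99.4 % of the atoms' energy. Matching maximizes the magnitude of
the complex inner product between a voxel's SV vector and the unit-norm
compressed atoms; proton density is recovered as the winning inner-product
magnitude. Ties are broken by the lowest grid index so results are
deterministic; zero voxels get a sentinel value 0 and a flag rather than an
error. `phase_normalize()` rotates each voxel's SV vector so that SV1 is
real and non-negative — the step that reduces four complex channels to
seven real ones and makes Re(SV1) a proton-density-like image. Voxels with
|SV1| below 1e-12 of the volume maximum have no meaningful phase reference
and pass through flagged.

## The seven-channel U-Net regressor

Each of the seven networks (one per channel: Re SV1, Re/Im SV2, Re/Im SV3,
Re/Im SV4) is an image-regression U-Net:

* encoder: `n_levels + 1` double-convolution blocks (3×3 kernels,
  zero-padded "same"), each convolution followed by ReLU then batch
  normalization, with 2×2 max pooling between blocks and channel counts
  doubling from `base_filters`;
* bottleneck: one more double convolution at the deepest width (batch
  normalization retained there by default — the architecture description
  is ambiguous on this point, so it is an explicit `bottleneck_batchnorm`
  flag), followed by bilinear 2× upsampling;
* decoder: at each level the upsampled features are concatenated with the
  matching encoder block — growing the channel count by exactly 50 % —
  then passed through a double convolution *without* batch normalization;
* head: 1×1 convolution to one channel and `tanh`, so raw outputs live in
  [-1, 1] and are mapped through `(y + 1) / 2` to the [0, 1] target space.

Dropout (rate 0.1) is applied after every encoder double convolution; the
placement and rate are not pinned down by the source description, so the
package follows common U-Net practice and treats them as configuration.
Weights are He-uniform initialized from a seed; batch normalization uses
per-batch statistics during training and running averages (momentum 0.1)
at inference.

The whole network — forward pass, backpropagation through every layer, and
ADAM — is implemented in this package (RcppArmadillo for the convolution,
pooling and upsampling kernels; R for orchestration), because no deep
learning framework is part of the package's dependency set and the
regressor is the core of the method. Correctness of the backward pass is
established by finite-difference gradient checks across all layer types,
which the test suite runs on a small configuration.

A note on parameter counting: `count_parameters()` sums trainable scalars
(convolution weights/biases, batch-norm scale/shift) and is verified
against an independent analytic summation over the `network_structure()`
layer dump. At the reference configuration (input 256, base 16, 4 levels)
the described architecture implies 3,145,505 parameters per network
(22,018,535 for the seven-network composite), which is inconsistent with
the published total of 1,940,902 under any standard per-layer accounting;
the discrepancy could not be resolved from the architecture walk-through,
so the operation reports what the described architecture implies and the
published total is not treated as a check.

## Training procedure

Training pairs are (MPRAGE slice, 7-channel SV slice). The MPRAGE slice is
divided by its parent volume's maximum; each SV channel is min-max scaled
to [0, 1] *per slice* (the per-slice ranges are returned so the scaling is
invertible, and zero-range channels flag the slice for exclusion). Each
epoch draws `floor(total_slices / batch_size)` batches of (subject, slice)
pairs uniformly at random; every channel network is updated independently
against the MSE of its own channel (ADAM, learning rate 1e-4 by default).
After each epoch the composite MSE is evaluated in inference mode on
verification subjects that never contribute gradients, and the weights
with the lowest verification MSE so far are checkpointed, making the best-
MSE curve non-increasing by construction.

At inference, `mrf_predict()` treats a volume as an ordered stack of
independent 2D slices and maps outputs to SV units through a *global*
per-channel (min, max) rescale table. `default_rescale_table()` carries the
published global ranges of a 30-subject acquired-MRF training cohort;
`rescale_table_from_subjects()` computes the analogous table from any
training set, which is the route phantom experiments use. The mismatch
between per-slice training normalization and global inference rescaling is
inherited from the procedure this package reproduces; it is benign for
slices whose channel ranges resemble the global ones (interior slices) and
is a recognized source of error near the volume edges.

## Digital phantom

`generate_subject()` builds a schematic brain: concentric ellipsoidal
shells of CSF, gray matter and white matter (semi-axes 0.42/0.36/0.33 of
the grid), split into `n_regions` angular parcels that stand in for
anatomical regions. Parcels cover only the parenchymal shells (GM and
WM), mirroring anatomical parcellations whose regions of interest exclude
the CSF spaces; this also matters quantitatively because CSF sits at the
MPRAGE inversion null and is nearly invisible (≈ 3 % of WM brightness) in
the network's input, so no image-based method can report it reliably. Geometry is deliberately schematic rather than
anatomical: the pipeline's mathematics is geometry-agnostic, and
piecewise-constant truth enables exact per-voxel assertions (noiseless
matching must recover the ground-truth grid point at every voxel — a test
that anatomical phantoms with partial-volume voxels cannot support).

Default conditions, chosen once to emulate the study design at desk scale:
grid 64³ (1 mm isotropic convention), 6 subjects (4 train / 1 verification
/ 1 test, mirroring a 30/2/5 split at 1/7 scale), 8 parcels, three tissue
classes with means CSF 3000/1500, GM 1300/80, WM 850/60 ms (PD 1.0 / 0.8 /
0.7) and inter-subject SDs of 5 % of the means, truncated to positive
values with T2 ≤ T1. Additive noise is Gaussian at 2 % of the signal
maximum on both the magnitude MPRAGE and the complex SV channels — at this
level the voxelwise scatter of matched T1 resembles the regional SDs
reported for real acquisitions. Per-subject tissue draws are snapped to
the dictionary grid before simulation so ground truth is exactly
representable. The MPRAGE side uses the long-TR inversion-recovery
approximation `S = pd · |1 − 2 e^(−TI/T1) + e^(−TR/T1)| · sin(α)` at
TI 900 / TR 2130 / TE 2.6 ms / α 8°; the small T2* term at 2.6 ms echo
time is deliberately neglected.

What the phantom does *not* emulate: anatomy, partial-volume mixing,
Rician noise statistics (Gaussian is used; at 2 % noise the difference is
negligible away from the background, and background voxels are masked),
B0/B1 inhomogeneity, and slice-to-slice acquisition correlations. Tests
passing on the phantom therefore demonstrate the correctness of the
pipeline's computations and the learnability of the intensity-to-SV
mapping, not clinical image quality.

## Agreement statistics

`ccc()` implements Lin's concordance correlation coefficient with
population (1/n) moments — the convention under which the estimator is
usually stated, fixed here and pinned by a hand-computed example
(x = (1,2,3), y = (2,3,4) gives exactly 4/7). `region_summaries()` uses the
sample (n−1) SD, matching how regional SDs are commonly reported. The
clustered bootstrap resamples whole subject clusters with replacement
(10,000 replicates by default) and reports percentile intervals; percentile
rather than BCa because no refinement is named in the procedure being
reproduced. With all clusters of size one the replicate stream is verified
to coincide exactly with an ordinary iid bootstrap.

One caveat the test suite documents explicitly: with only five clusters —
the study design this mirrors — percentile cluster-bootstrap intervals
undercover substantially (about 82 % empirical coverage for a nominal
95 % interval in a two-level Gaussian simulation; this is the classic
few-cluster bootstrap problem, not an implementation artifact, and no
choice of variance components repairs it). The nominal-coverage property
is therefore asserted where it can actually hold, at a 40-cluster × 6-unit
design (empirical coverage ≈ 95 % over 500 seeded repetitions), while a
separate test pins the 5 × 47 undercoverage to the 70–90 % band so the
phenomenon is visible rather than hidden.

The packaged 47-region table of acquired-vs-synthesized T1/T2 means and
SDs reproduces exactly the derived statistics asserted in the tests:
region-averaged mean differences of 48.23 ms (T1) and 2.02 ms (T2) and the
CoV (SD/mean) extremes of the four columns. Two published CoV summaries do
*not* equal plain SD/mean on the table (the four column means and the
synthesized-T2 maximum); whatever resampling produced them was not
specified, so they are excluded from assertions rather than approximated.

## Numerical choices and desk-scale problem sizes

* Dictionary SVD: LAPACK via base `svd()` on the complex atom matrix;
  compressed atoms are re-normalized to unit norm before matching because
  rank truncation shrinks them slightly.
* Matching memory: voxels are processed in blocks of 2048 so the score
  matrix never materializes for a full volume.
* Matching tie-break: first (lowest) grid index; grid order is row-major,
  T1 outer.
* Degenerate-voxel floor in phase normalization: |SV1| ≤ 1e-12 × volume
  maximum.
* Batch norm epsilon 1e-5, momentum 0.1; ADAM β = (0.9, 0.999), ε = 1e-8.
* Seeds: every stochastic operation takes an explicit seed; phantom
  subjects derive a 32-bit sub-seed from (cohort seed, subject index).

The test and acceptance workloads run the real pipeline at reduced size,
chosen as the package's own desk-scale study conditions: a coarsened
dictionary (every second grid value, i.e. 40/10 ms steps) for
pipeline-level tests; networks at input 64, base 4 filters, 2 levels; an
overfit probe on 4 noiseless slices; and a short seeded training run on
the 6-subject phantom (central 32 slices of each training subject) whose
held-out region-mean T1/T2 tolerances were frozen from a pilot run of that
exact configuration. The 64-slice prediction, full-volume matching and
regional statistics run at full phantom scale.

## Known limitations

* The flip-angle/TR history and dictionary grid of the emulated
  acquisition are unpublished; absolute fingerprints are therefore not
  comparable to any scanner's, only the pipeline is.
* The network trained at desk scale is a scaled-down configuration; no
  attempt is made to reproduce trained weights or paper-scale accuracy.
* Registration is consumed, not estimated: `resample_volume()` applies a
  user-supplied rigid affine (identity for phantoms). Mutual-information
  optimization is out of scope.
* Gaussian (not Rician) magnitude noise; no partial voluming; schematic
  geometry.
* Five-cluster bootstrap intervals undercover (see above) — a property of
  the study design that users analyzing 5-subject cohorts should weigh.
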