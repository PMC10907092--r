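---
title: "Cross-modality tau-PET synthesis: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality tau-PET synthesis: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Tau-PET quantifies neurofibrillary-tangle burden and supports staging and
differential diagnosis of Alzheimer's disease, but the tracer is expensive
and far less available than FDG-PET, amyloid-PET or structural T1w MRI.
`tausynth` implements a cross-modality imputation pipeline: a 3D
Dense-U-Net is trained to map a template-space source volume (an FDG-like,
amyloid-like or T1w-like image) to a tau-PET-like target volume, and the
imputed volume is then evaluated exactly the way a real tau scan would be —
through regional SUVR, tau-positivity thresholds and diagnostic-group ROC
analysis. An ROI-occlusion analysis quantifies which input regions the
trained network actually uses, locally and remotely.

Real clinical cohorts of paired scans are access-restricted, so the package
ships a synthetic phantom generator with *known* ground-truth structure.
Every claim the pipeline makes — that training recovers the source-target
mapping, that occlusion finds remote couplings, that group contrasts
separate — is tested against structure planted by the generator.

# The network

The model is a U-Net-style encoder-decoder whose blocks use dense
(concatenative) connectivity: inside a block, each 3x3x3 convolution +
ReLU output is concatenated to everything the block has produced so far,
so layer $j$ of a block with growth $g$ sees $c_{in} + (j-1)g$ channels and
the block emits $c_{in} + Lg$ channels. Four encoder levels (the default;
`depth` is configurable) halve the spatial grid by 2x2x2 max-pooling while
the growth doubles per level; a bridge block sits at the bottom; decoder
levels upsample (nearest-neighbour followed by a convolution, chosen over
transposed convolution to avoid checkerboard artefacts), concatenate the
encoder skip at the same level, and run another dense block with halving
growth. A linear 1x1x1 convolution head regresses the SUVR target — no
output nonlinearity, because SUVR is an unbounded positive continuous
quantity and the loss is per-voxel mean squared error.

The filter counts per block are not architectural invariants but
configuration (`base_filters`, `layers_per_block`); batch normalization is
not used. Weights are He-uniform initialized under a seed, so builds are
exactly reproducible. `count_parameters()` is a pure function of the
specification and is tested against a hand count of the concatenative
graph.

The forward and backward passes are implemented in compiled code
(RcppArmadillo). Feature maps are stored as voxels x channels matrices and
each 3D convolution is evaluated as one large GEMM against a permuted
weight matrix plus 27 shifted contiguous scatter/gather passes; the
backward pass reuses the same structure (one gathered gradient matrix, two
GEMMs). Gradients are verified against central finite differences in the
test suite. Optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) with
mini-batches of 2 scans and per-voxel mean MSE.

## Learning-rate schedule

The training protocol states both a fixed halving of the learning rate
every 10 epochs and a plateau rule ("updated when validation error fails
to improve for 7 epochs"). These are reconciled as: *plateau-triggered*
halving with patience 7, with a minimum of 10 epochs between consecutive
decays. A pure `schedule = "fixed"` mode (halve every 10 epochs
unconditionally) is also available, and is what the schedule unit test
exercises (learning rate at epoch 21 equals lr0/4). Model selection keeps
the best-validation-epoch weights; there is no early stopping.

## Subject-grouped folds

Scans of one participant are never split across partitions. Subjects are
shuffled under a seed and divided into $k$ near-equal groups; fold $i$
takes group $i$ as test, the cyclically next group as validation and the
rest as training — the 60/20/20 layout for $k = 5$. The test sets of the
five folds partition the subjects exactly, and a property test checks zero
leakage and full coverage over 1000 seeded splits.

# Preprocessing

Template space is 121x145x121 voxels; network space is 128x128x128. The
resize is deterministic: 8 slices are cropped at the anterior end and 9 at
the posterior end of the AP axis (axis 2; 145 - 8 - 9 = 128), and 7 zero
slices are padded at the low-index end of axes 1 and 3 (121 + 7 = 128).
The source protocol says only "left and bottom" for the pad placement
without naming array axes; this package fixes low-index padding on both
121-length axes, documents it, and keeps every amount configurable in
`crop_pad_spec()`. The inverse reconstruction restores template shape with
the retained region bit-identical and the cropped slices zero.

Intensity normalization follows the two modality conventions: PET volumes
are divided by the *median* uptake in a reference region (pons/cerebellar
crus anatomically; the atlas's `reference_label` at phantom scale), which
makes the reference median exactly 1; T1w volumes are divided by the
*mean* intensity inside a white-matter mask. Both are scale-equivariant —
a global multiplicative nuisance cancels exactly — and that property is
tested. Bias-field correction and registration are upstream concerns, out
of scope here.

# The phantom generator

The generator emulates the statistical skeleton of a paired-modality
neuroimaging cohort while remaining fully transparent:

- **Geometry.** ROIs are axis-aligned blocks centred in the cells of a
  regular lattice partition of the grid, so ROIs are never adjacent and
  physically remote pairs exist by construction (occlusion analysis needs
  them). Default desk scale: 32^3 voxels, 12 ROIs, a 6-member meta-ROI
  (labels 1-6) and a reference region (label 12).
- **Disease stage.** Each subject carries a latent stage $s \sim U(0,1)$.
  Group labels (CU-, CU+, MCI, DLB-spec, FTD-spec, AD-spec) are fixed
  quantile-style bins of stage (cut points 0.30/0.45/0.60/0.70/0.80) and
  amyloid status flips positive at the first cut. These labels give
  separable classes for ROC tests; no clinical semantics are claimed — in
  particular the non-AD dementia groups are *not* modelled as having
  AD-discordant tau patterns.
- **Source means.** ROI $r$ of a scan has source mean
  $u_r = b_r + a_r s + \varepsilon$, with per-ROI baselines
  $b_r \sim U(0.9, 1.4)$ and stage slopes $a_r \sim U(-0.4, 0.4)$ drawn
  once per cohort, and per-scan jitter $\varepsilon \sim N(0, 0.05)$.
  Scans of one subject share $s$ but have independent jitter and voxel
  noise. The jitter is what makes a planted cross-ROI coupling
  *identifiable*: it is the only source-ROI variance not shared through
  the latent stage, so with negligible jitter no method — regression or
  network — could attribute a target ROI's variance to a specific remote
  source ROI.
- **Target means.** $m = W^\top u + \beta s$, where `coupling[s, t]` is
  the influence of source ROI $s$ on target ROI $t$. The default is the
  identity (local coupling) plus one planted remote link, ROI 7 to ROI 2
  with weight 0.6 — two non-adjacent lattice cells. The pair was chosen
  with the network's receptive field in mind: the most distant cell pairs
  on a 32^3 grid (~25 voxels between centres) lie *outside* the theoretical
  receptive field of a desk-scale depth-2 network (~23 voxels), which would
  make the planted link structurally unlearnable; ROI 7 and ROI 2 are
  clearly non-adjacent (~19 voxels between centres, two gaps away) yet
  within reach. The stage effect $\beta$ is 0.8 for meta-ROI members and
  0.2 elsewhere, so the meta-ROI SUVR spans roughly 1.0-2.4 across the
  stage range and straddles the four positivity cutoffs
  (1.11/1.21/1.33/1.46).
- **Reference region.** Its target mean is pinned to 1.0 and its source
  mean to 1.0, so SUVR normalization is always well defined; the generator
  refuses configurations that would make any target ROI mean non-positive
  (regional MAPE would be undefined).
- **Noise.** Additive Gaussian voxel noise, default SD 0.06 (about 5% of
  the typical signal of ~1.2). An optional log-normal per-scan global
  scale (`scale_sd`, off by default) exercises what SUVR division removes.
- **Background.** Constant 0.3 plus noise — nonzero, like off-target
  tracer uptake, but carrying no signal.

Noiseless configurations reproduce $W^\top u + \beta s$ at machine
precision, and the planted coupling is recoverable by ordinary least
squares on ROI means — both are tests. What the phantom does **not**
emulate: anatomical shapes, partial-volume effects, off-target binding
structure, scanner effects, spatially correlated noise. Passing the
recovery tests therefore demonstrates that the pipeline's machinery is
correct, not that the network reaches any particular accuracy on real
brains.

# Evaluation

Regional SUVR is the median uptake within each ROI; the meta-ROI value is
the arithmetic mean of its members' medians (the temporal composite:
amygdala, entorhinal, fusiform, parahippocampal, inferior/middle temporal
in the real anatomy). Across test scans the package reports per-ROI
Pearson r and MAPE ($100 \cdot \mathrm{mean}(|pred - truth|/truth)$,
aggregated across scans within ROI), per-scan MS-SSIM and a voxel-wise
RMSE map. All four metrics are validated against independent brute-force
oracles (loop summation, covariance formula, O(n^2) pair counting, direct
windowed sums) on hundreds of random instances at 1e-10 relative
tolerance.

MS-SSIM uses a 3D Gaussian window (sigma 1.5, radius 5 by default) with
border-corrected window mass, 2x average-pool downsampling between scales,
and the standard five-scale exponents renormalized over the scales that
fit the volume (desk-scale grids fit 2-3 scales; the function refuses
impossible scale counts and names the maximum that fits). Scale means are
clamped at zero before fractional exponentiation in the multi-scale case;
with `scales = 1` the value is exactly plain SSIM, which is how it is
checked against the direct implementation.

Tau positivity is `meta_roi > cutoff`, strictly: a value exactly at the
cutoff is negative (the convention had to be fixed; the strict inequality
is documented and tested). ROC curves sweep every distinct score; the
trapezoidal AUROC equals the Mann-Whitney pair-ordering probability with
ties counted 1/2, which the pair-counting oracle confirms. Group contrasts
(e.g. CU vs AD-spectrum, with "CU" matching CU- and CU+) run the same ROC
on a chosen SUVR column; a `flip_sign` flag supports predictors where
*lower* values indicate disease (hypometabolism), rather than guessing a
direction silently.

# Occlusion analysis

For each ROI $R_1$: zero its voxels in every test-scan source, re-impute,
recompute per-ROI MAPE against the ground-truth regional SUVR, and
subtract the un-occluded baseline:
$\Delta\mathrm{MAPE}_{R_1 \to R_2} = \mathrm{MAPE}_{R_1 \to R_2} -
\mathrm{MAPE}_{R_2}$. Entries may be negative and are never clamped. Row
sums summarize each ROI's total influence. Occlusion is applied *after*
intensity normalization (in network space): occluding before SUVR division
would corrupt the reference median and entangle a global scale change with
the local information removal; the choice is deliberate and documented
here because the source protocol is ambiguous on the ordering.

Two properties anchor the analysis. First, a copy model (prediction =
input) on a noiseless identity phantom has exactly zero off-diagonal
influence and a collapsed diagonal. Second, planted-structure recovery: a
trained network's row for the planted remote source ROI ranks the true
target ROI first among off-diagonal entries in at least 4 of 5 seeded
replicates. The recovery experiment uses a *coupling-isolation* phantom —
stage effects and source stage slopes set to zero, per-scan jitter 0.1,
voxel noise 0.03, a 16^3 grid with 40 subjects — so that the planted link
is the only cross-ROI dependence, and trains each replicate to convergence
(100 epochs). The isolation matters: in the full stage-driven phantom a
partially-trained network infers the latent stage from *every* informative
region, so occluding any ROI perturbs predictions diffusely everywhere,
and the planted link's specific signal (whose unique variance is only the
jitter term) drowns in that diffuse response unless training runs far past
the desk-scale budget. Isolating the coupling turns the experiment into
what it should be: does occlusion attribution find the one remote
dependence that actually exists?

# Problem sizes and numerical choices

The shipped demonstrations use sizes a laptop CPU handles in minutes,
chosen as the package's desk scale: 32^3 grids, 12 ROIs, 50 subjects with
two scans each for the training demonstration (a depth-2 Dense-U-Net with
`base_filters = 4` trained 30 epochs), 1000 seeded splits of a 50-subject
two-scan cohort for the grouping guarantees, and 5 occlusion replicates on
16^3 coupling-isolation phantoms trained 100 epochs. The
full-scale defaults (`network_spec()` depth 4 with 16 base filters,
`train_config()` lr 1e-4 over 150 epochs) reflect the protocol for
121x145x121 cohorts of hundreds of scans. For the desk-scale phantom runs
the Adam learning rate is 1e-3 — the canonical Adam default, appropriate
for the much smaller network and volume — fixed a priori alongside the
phantom defaults.

Other numerical choices: He-uniform initialization (ReLU gain) under an
explicit seed; single-threaded deterministic primitives so that identical
seeds give bitwise-identical training histories; zero padding in
convolutions ("same" shape); max-pooling argmax ties broken by first
occurrence in x-fastest order; Adam epsilon 1e-8; validation loss is the
per-voxel (not per-scan) mean MSE.

# Known limitations

- The phantom's piecewise-constant ROIs make regional medians nearly
  noise-free, so desk-scale MAPE is dominated by model error rather than
  measurement noise — flattering relative to real PET.
- The network is trained and evaluated on one grid; no resampling or
  registration is provided, volumes must already share the template grid.
- The imputation head is linear and the loss unweighted MSE; strongly
  non-Gaussian targets or region-weighted objectives are out of scope.
- Comparison architectures (VAE, adversarial image translation) and
  external-cohort validation are out of scope.
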