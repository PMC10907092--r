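# tausynth

Cross-modality synthesis of tau-PET-like brain volumes with a 3D
Dense-U-Net, in R.

Tau-PET measures neurofibrillary-tangle burden — the pathology that tracks
clinical severity in Alzheimer's disease — but the tracer is scarce
compared with FDG-PET, amyloid-PET and structural MRI. `tausynth`
implements the full pipeline for *imputing* a tau-PET-like volume from a
more accessible modality and for judging whether the imputation is good
enough to stand in for the real scan:

- **`phantom`** — a synthetic paired-modality cohort generator with known
  ground truth: block ROIs on a template grid, a latent disease stage per
  subject, configurable source-to-target cross-ROI coupling
  `m = t(W) u + beta * s`, additive noise, multiple scans per subject.
- **`volio` / `prep`** — NIfTI volume and atlas I/O on a shared grid;
  SUVR normalization (divide by reference-region *median*), T1w
  white-matter-mean normalization, and the exact crop/pad between template
  space (121x145x121) and network space (128x128x128): crop 8 anterior + 9
  posterior AP slices, pad 7 zeros on the two 121-axes, with a bit-exact
  inverse.
- **`net` / `train`** — the 3D Dense-U-Net (dense concatenative blocks,
  filter doubling/halving, max-pool down / nearest+conv up, linear 1x1x1
  regression head) with forward, backpropagation and Adam implemented via
  GEMM-based compiled 3D convolutions; subject-grouped 5-fold 60/20/20
  splitting; MSE loss, mini-batch 2, plateau-triggered learning-rate
  halving with best-validation checkpointing.
- **`eval`** — regional SUVR (per-ROI median; meta-ROI = mean of member
  medians), Pearson r and MAPE per ROI across scans, voxel-wise RMSE maps,
  3D MS-SSIM, tau-positivity at the standard meta-ROI cutoffs
  (1.11/1.21/1.33/1.46) and ROC/AUROC for positivity and diagnostic-group
  contrasts (AUROC = Mann-Whitney pair-ordering probability).
- **`occl`** — ROI-occlusion interpretability: zero one ROI in the input,
  re-impute, and chart dMAPE(R1 -> R2) = MAPE_{R1->R2} - MAPE_{R2} as an
  R x R adjacency matrix of local and remote influence.

## Worked example

Generate a phantom cohort, train one fold, and evaluate the held-out
subjects (about nine minutes on one CPU core):

```r
library(tausynth)

cfg    <- phantom_config(n_subjects = 60, seed = 101)   # 32^3, 12 ROIs, 2 scans/subject
atlas  <- make_atlas(cfg)
cohort <- prepare_cohort(generate_cohort(cfg, atlas), atlas)  # SUVR-normalized

split <- make_folds(cohort, k = 5, seed = 1)                  # subject-grouped
model <- build_dense_unet(
  network_spec(depth = 2, base_filters = 4, layers_per_block = 2), seed = 1)
fitres <- fit(model, cohort, split, fold = 1,
              train_config(lr0 = 1e-3, epochs = 30, seed = 1))

test  <- cohort_scans(cohort, fold_partitions(split, 1)$test)
preds <- lapply(test, function(sc) impute(fitres$model, sc$source))
tp <- regional_suvr_table(preds, atlas)
tt <- regional_suvr_table(lapply(test, function(sc) sc$target), atlas)

pearson_r(tp$meta_roi, tt$meta_roi)
#> [1] 0.9506187
mape(tp$meta_roi, tt$meta_roi)
#> [1] 7.492303
```

The two numbers are the headline evaluation: the correlation between
imputed and ground-truth meta-ROI SUVR across held-out scans, and the mean
absolute percentage error of the same quantity. On this phantom the
network recovers the planted source-to-target mapping almost exactly;
real-brain accuracy is a separate question the phantom cannot answer.

Tau positivity and a diagnostic contrast from the same table:

```r
sum(positivity_labels(tt, 1.46))   # scans above the strictest cutoff
#> [1] 15
grp <- cohort$table$group_label[match(rownames(tt), cohort$table$scan_id)]
group_classification(tt, grp, contrast = c("CU", "AD-spec"))
#> <roc_result> predictor 'meta_roi: CU vs AD-spec': AUROC = 1.0000
```

The meta-ROI SUVR of this phantom spans ~1.26-1.99 across disease stages,
so the four standard cutoffs split the cohort and the stage-driven group
contrast separates perfectly. Occlusion analysis on the trained model
charts which input ROI matters for which output region:

```r
om <- occlusion_matrix(fitres$model, test, atlas)
om$delta      # rows = occluded ROI, columns = evaluated ROI (dMAPE, %)
om$row_sums   # total influence of occluding each ROI
```

A thin command-line interface over the same functions is installed at
`inst/cli/tausynth.R` (subcommands `simulate`, `prep`, `train`, `impute`,
`evaluate`, `occlude`).

## Scope

Registration/warping of real scans, partial-volume correction, comparison
generative architectures and clinical interpretation are out of scope. The
phantom is a statistical testbed, not an anatomical simulation; see the
methods vignette (`vignettes/tausynth-methods.Rmd`) for the model,
parameter and design-decision details.
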