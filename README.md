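# prlnet

Classification of multiple-sclerosis lesions as **paramagnetic-rim-positive
(rim+)** or **rim-negative (rim-)** from co-registered multimodal 3D MRI.

Chronic active MS lesions keep a ring of iron-laden microglia and
macrophages at their edge; on susceptibility-based MRI this appears as a
thin hypointense rim on the unwrapped phase image (with attenuated
T2\*-magnitude signal) at the border of a FLAIR-visible white-matter
lesion. Patients with ≥ 4 such lesions are considered "chronic active", so
automated, reproducible rim counting is a useful decision-support tool for
neuroradiologists and MS researchers.

`prlnet` provides the full lesion-to-patient pipeline:

* **Candidate extraction** — maximal 6-connected components of a binary
  segmentation; labelled rim+ by any-voxel overlap with a rim+ annotation
  map; exclusion rules (volume < 12.3 mm³, > 10,000 voxels, artefact
  windows, rim-contaminated rim- windows) with per-reason reports.
* **Patches** — 28³-voxel (configurable) multimodal blocks centred on each
  lesion's centre of mass, per-patch min-max normalized to [-1, 1].
* **3D augmentation** — offline right-angle rotations (tenfold rim+
  increase) and elastic deformations; online flips and ±2-voxel
  translations (a 108-element transform space).
* **The network** — a two-branch VGG-style 3D CNN (three blocks of two
  3×3×3 convolutions + batch norm + tanh + max-pooling per branch) with
  *early fusion* (secondary-branch block-1 features concatenated into the
  main branch) and *late fusion* (flattened features joined before the
  fully-connected softmax head), plus a single-branch unimodal baseline.
  Implemented from scratch in RcppArmadillo (im2col + GEMM, exact
  backprop), trained with Adam, Xavier initialization, a decaying
  learning-rate ladder (1e-4 … 1e-5) with patience-3 early stopping, and
  patient-grouped per-site stratified 4-fold cross-validation with inner
  3-fold epoch-budget selection.
* **Evaluation** — fold-averaged ROC/PR curves (step interpolation; AUC =
  mean of fold AUCs), DeLong and continuity-corrected McNemar tests,
  95%-specificity operating points, lesion metrics
  (sensitivity/specificity/PPV/NPV/F1), patient-level chronic-active
  categorization at count thresholds 1–6, and anatomical location reports
  (periventricular / juxtacortical / deep white matter / other, with 2 mm
  cortex and 3 mm ventricle dilation).
* **A synthetic phantom** — ellipsoidal lesions with erosion-based phase
  rims, rim-like artefacts, confluence, noise and bias fields, with exact
  ground truth, so every stage is testable without patient data.

Inputs are NIfTI volumes (phase, T2*-magnitude, FLAIR) on one grid plus a
lesion mask; registration, segmentation, phase unwrapping and parcellation
are upstream and out of scope.

## Worked example

```r
library(prlnet)

# a ~300-lesion synthetic cohort: 24 patients, 2 sites, 25% rim+
cohort <- phantom_cohort(n_patients = 24, lesions_per_patient = 12.5,
                         rim_pos_fraction = 0.25, patch_size = 16,
                         seed = 11)
length(cohort$patches)                      # 305 lesion patches
sum(patch_labels(cohort$patches))           # 83 rim+

# bimodal network: phase-like main branch, FLAIR-like secondary
arch <- arch_config(modalities = 2, patch_size = 16,
                    filters = c(8, 16, 32), fc = c(64, 16))
net  <- build_bimodal_net(arch)
cfg  <- train_config(learning_rates = 1e-3, epoch_budget = 6)

res <- cv_train_eval(cohort$patches, cohort$patients, net, cfg,
                     n_folds = 4, modalities = c(2, 1), seed = 3)
curves <- averaged_curves(res$scores_by_fold, res$labels_by_fold)
curves$auc_roc
#> [1] 0.988676
curves$auc_roc_by_fold
#> [1] 1.0000000 1.0000000 0.9547038 1.0000000

op <- operating_point(unlist(res$scores_by_fold),
                      unlist(res$labels_by_fold), 0.95)
op$sensitivity   # lesion-level sensitivity at >= 95% specificity
```

The mean fold-averaged ROC-AUC of 0.989 says the bimodal model recovers
the rim signal on the phantom almost perfectly; the same protocol with a
FLAIR-only unimodal baseline yields an AUC near 0.5 (the phantom puts no
rim information on the FLAIR-like channel), reproducing the expected
modality ordering. The operating point is the smallest threshold whose
specificity reaches 95%; patient-level categorization
(`patient_categorize`) then counts predicted rim+ lesions per patient.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/rimpipe.R phantom --config cfg.yaml --out phantom_dir/ --seed 7
Rscript inst/cli/rimpipe.R run     --config run.yaml --out runs/demo/   --seed 7
```

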