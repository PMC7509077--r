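---
title: "Classifying paramagnetic rim lesions with multimodal 3D CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying paramagnetic rim lesions with multimodal 3D CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronic active multiple-sclerosis lesions — lesions whose edge keeps a ring
of iron-laden microglia and macrophages after the acute inflammation
subsides — appear on susceptibility-based MRI as *paramagnetic rim lesions*:
a thin hypointense rim on the unwrapped phase image at the border of a
white-matter lesion. Counting rim+ lesions per patient is clinically
meaningful (patients with roughly four or more are considered "chronic
active"), but visual rating is slow and shows substantial inter-rater
variability.

`prlnet` implements a complete, testable pipeline that classifies
segmented lesions as rim+ or rim- from three co-registered 3D contrasts:
the unwrapped **phase** of a T2\*-weighted acquisition (the rim-bearing
contrast), the matching **T2\*-magnitude**, and **FLAIR** (the
lesion-detection contrast). Lesion segmentation, registration, phase
unwrapping and anatomical parcellation are upstream of this package: it
consumes their outputs (NIfTI volumes on one grid).

## Pipeline and model

1. **Candidates** (`extract_components`, `label_candidates`,
   `apply_exclusions`). Each maximal 6-connected component of the binary
   segmentation is one candidate; a candidate is rim+ if it overlaps the
   rim+ annotation map in at least one voxel. Exclusion rules run in a
   fixed order: volume < 12.3 mm^3 ("too_small"), more than 10,000 voxels
   ("too_big"), an artefact voxel inside the candidate's patch window
   ("artefact"), and rim- candidates with more than 900 voxels of other
   rim+ lesions inside their window ("rim_contaminated"). The rule order is
   a package choice made for reproducible reports. The 900-voxel
   contamination threshold is used as a voxel count; the companion
   millimetre figure sometimes quoted alongside it does not correspond to
   any isotropic voxel size, so the voxel count is authoritative here.

2. **Patches** (`extract_patch`). A cubic window (default 28^3 voxels) is
   centred on the rounded (half-up) centre of mass of the candidate's
   binary voxel set; out-of-volume voxels are zero-filled. Each modality is
   linearly rescaled per patch so its minimum maps to -1 and its maximum to
   +1; a constant window maps to 0. Normalizing per patch (rather than per
   volume) is a package choice; the upstream convention was unspecified.

3. **Augmentation** (`offline_rotations`, `elastic_deform`,
   `online_augment`). Offline: each rim+ patch is rotated by 90/180/270
   degrees about each array axis — nine interpolation-free rotations, a
   tenfold rim+ increase — and, optionally, three elastically deformed
   copies of every patch (both classes) quadruple the data. The elastic
   family is a coarse Gaussian displacement grid (default 4^3 control
   points) upsampled trilinearly and scaled so the largest displacement
   equals the configured amplitude (default 2 voxels) — mild enough to keep
   the rim topologically intact. Online, per training draw: one flip (none/
   X/Y/Z) then a translation of -2/0/+2 voxels per axis, a 108-element
   transform space sampled uniformly; transform tags are logged so repeats
   are detectable.

4. **Model** (`build_bimodal_net`, `build_unimodal_net`). VGG-style 3D
   CNNs: per branch three blocks of two 3x3x3 'same' convolutions (batch
   normalization then tanh after each) followed by 2x2x2 max-pooling; with
   28^3 input the spatial trace is 28 -> 14 -> 7 -> 3. The bimodal network
   fuses early — the secondary branch's block-1 output is channel-
   concatenated onto the main branch's block-1 output (concatenation, not
   addition, mirroring standard VGG-style fusion) — and late: both final
   feature blocks are flattened, concatenated and passed through two tanh
   fully-connected layers (defaults 256, 64) into a 2-way softmax. Filter
   counts (32/64/128) and head widths are package defaults chosen VGG-like;
   both are configurable. Padding is 'same' so three pools give 28 -> 3.
   Each branch keeps its own full stream after fusion (one
   cross-connection), which we read as the natural two-parallel-branch
   layout.

   The network engine is written in RcppArmadillo (single-precision im2col
   + GEMM convolutions, exact analytic backprop verified against central
   finite differences in the test suite). Batch statistics are computed
   over batch x spatial per channel; inference uses running statistics. The
   conv activations use a rational tanh approximation accurate to about
   one single-precision ulp.

5. **Training** (`make_folds`, `train_model`, `inner_cv_epochs`,
   `ensemble_predict`). Patients are assigned to four folds per site by a
   greedy largest-rim+-load-first balancing rule (the original
   stratification algorithm is unspecified; greedy balancing matches its
   stated goals: class counts balanced per site, all of a patient's lesions
   in one fold). Training uses Adam, Xavier initialization, batch size 32,
   softmax cross-entropy, and a learning-rate ladder (1e-4, 5e-5, 2.5e-5,
   1e-5): a decay fires after three consecutive epochs without a
   validation-loss improvement over the best so far, and the decay that
   would pass the last rate stops training. A three-fold inner CV
   determines per-rate epoch budgets (averaged, rounded half up — the
   aggregation rule is a package choice) for retraining without a
   validation set. Ensembles average per-model rim+ probabilities (the
   combination rule is a package choice; "ensemble" alone does not fix
   one).

   One scheduler subtlety: "epochs without improvement" compares against
   the best loss seen so far, starting from an optional baseline
   (default infinity). With the default, the first finite validation loss
   always counts as an improvement; supplying a pre-training baseline
   makes the first epoch count against it. Both behaviours are exercised
   in the tests.

6. **Evaluation** (`averaged_curves`, `delong_test`, `mcnemar_discordant`,
   `operating_point`, `lesion_metrics`, `patient_categorize`,
   `assign_regions`, `location_report`). Per-fold ROC and PR curves are
   step-interpolated onto a fixed 1001-point abscissa grid (the grid size
   is a recorded package choice) and averaged pointwise; the reported AUC
   is the mean of per-fold AUCs, not the AUC of the mean curve (the pooled
   AUC is logged separately for diagnostics). DeLong's midrank/covariance
   test compares correlated AUCs; McNemar's test with continuity
   correction compares paired classifications. The operating point is the
   smallest score threshold achieving at least 95% specificity
   (prediction rule: rim+ iff probability >= threshold). Patients are
   "chronic active" when their predicted rim+ count reaches a threshold
   (1-6 reported; 4 is the headline). For the location analysis the cortex
   is dilated 2 mm and the ventricles 3 mm (spherical elements, radius
   rounded to voxels); precedence is periventricular (any overlap) >
   juxtacortical (>= 50%) > deep gray/brainstem/cerebellum (>= 50%) > deep
   white matter. Periventricular-first is the package's reading of the
   any-overlap exception being the weakest criterion; the categories are
   reported as exclusive. All tests are two-sided at 0.05.

## The synthetic phantom

Patient MRI from the source cohorts is not publicly available, so the
package ships a phantom generator (`generate_phantom`, `phantom_cohort`)
that emulates exactly the image features the classifier uses:

* ellipsoidal lesions with random orientation, hyperintense on the
  FLAIR-like channel;
* for rim+ lesions only, an erosion-based boundary shell (default 0.8 mm)
  that is hypointense on the phase-like channel (polarity configurable)
  and attenuated on the T2\*-like channel;
* rim-shaped phase artefacts with no FLAIR lesion (the classic false
  positive);
* optional confluent lesion pairs (both identities recorded);
* additive Gaussian noise and a smooth second-order polynomial
  multiplicative bias field (typical MRI shading).

Defaults: 0.65 mm isotropic voxels, semi-axes 1.8-4.5 mm (the minimum
keeps every rim+ above the 12.3 mm^3 filter), noise SD 0.02 against
contrasts of order 0.5, bias amplitude 0.1. Contrast magnitudes are free
parameters — the generator makes no claim of quantitative MR realism (no
Bloch simulation, no k-space, no anatomy), and rim intensity profiles in
real data are not quantitatively characterised. Passing tests on the
phantom therefore demonstrate that the pipeline machinery is correct
(geometry, bookkeeping, learning dynamics, statistics), not that the
trained weights transfer to patient data.

## Problem sizes and numerical choices

The shipped end-to-end study uses a 24-patient, ~300-lesion cohort (25%
rim+, two synthetic sites), 16^3 patches, a reduced network (filters
8/16/32, head 64/16), a single Adam rate of 1e-3 with a fixed six-epoch
budget, and patient-grouped 4-fold CV; these sizes were chosen as the
smallest configuration that cleanly separates the bimodal
(phase-like + FLAIR-like) model from the FLAIR-only baseline. On the
phantom, FLAIR carries no rim information by construction, so the
FLAIR-only baseline hovers near chance while the bimodal model reaches a
mean fold-averaged ROC-AUC around 0.99 — reproducing the qualitative
modality ordering (phase-bearing input >> FLAIR-only) rather than any
particular number.

Numerical details worth knowing: batch-norm epsilon 1e-5 and momentum 0.1;
degenerate (constant) patches normalize to 0; max-pooling on odd edges
drops the trailing plane (7 -> 3); ties in fold balancing are broken by
rim- load, then fold index, with the seed only shuffling exact ties;
centre-of-mass rounding is half-up per axis; all voxel coordinates in
tables are 0-based in header (x, y, z) order; the affine tolerance for
co-registration checks is 1e-3. The phantom placement loop rejects
overlapping or face-adjacent lesions and reports a placement failure after
400 consecutive rejected draws.

## Known limitations

* The CNN engine is CPU-only and single-threaded by design; training the
  full-size network on thousands of patches is out of its intended scope
  (the reduced configuration trains in minutes).
* Confluent rim+ lesions are an input contract: masks must arrive already
  split (as in the source protocol, where a technician separated them).
* The phantom's regions (central ellipsoidal ventricles, outer cortex
  shell) are geometric stand-ins; the location analysis is exercised
  against voxel-count oracles, not anatomy.
* Patch-based classification inherits the fixed-window limitation: very
  large lesions do not fit and are excluded by the 10,000-voxel rule.

## Reproducing the numbers

`scripts/acceptance.R` recomputes, from scratch: the exclusion bookkeeping
on the reference dataset inventory (4857 rim- / 462 rim+ in, 4687 / 457
kept), the augmentation arithmetic (tenfold rim+ rotation increase and the
resulting ~1.03:1 class ratio), the anatomical location percentages from
the reference per-region counts, and the phantom cross-validation AUCs.
See the README for the exact invocation.
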