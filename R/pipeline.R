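#' Load a co-registered multimodal volume set from NIfTI files
#'
#' All files must share one grid; the affines must agree within tolerance.
#' Spacing is read from the header. Anisotropic spacing triggers a warning
#' (the pipeline assumes isotropic voxels) but the volumes are accepted.
#'
#' @param paths named character vector/list of NIfTI paths (names become
#'   modality names; conventional names: flair, phase, t2s).
#' @param expected_spacing_mm optional check on the header spacing.
#' @param affine_tol maximum absolute affine element difference (default
#'   1e-3).
#' @return List with \code{volumes} (named list of 3D arrays) and
#'   \code{spacing_mm}.
#' @export
load_volume_set <- function(paths, expected_spacing_mm = NULL,
                            affine_tol = 1e-3) {
  paths <- as.list(paths)
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing))
    stop("missing input files: ", paste(unlist(paths[missing]), collapse = ", "))
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("grid mismatch across files: ",
         paste(names(paths), vapply(dims, paste, character(1), collapse = "x"),
               collapse = "; "))
  affines <- lapply(imgs, function(i) unclass(RNifti::xform(i)))
  for (k in seq_along(affines)[-1]) {
    if (max(abs(affines[[k]] - affines[[1]])) > affine_tol)
      stop(sprintf("affine mismatch beyond tolerance between %s and %s",
                   names(paths)[1], names(paths)[k]))
  }
  pix <- RNifti::pixdim(imgs[[1]])[1:3]
  if (max(pix) - min(pix) > 1e-6)
    warning(sprintf("anisotropic spacing (%s); proceeding, but the pipeline assumes isotropic voxels",
                    paste(signif(pix, 4), collapse = " x ")))
  sp <- pix[1]
  if (!is.null(expected_spacing_mm) && abs(sp - expected_spacing_mm) > 1e-3)
    warning(sprintf("header spacing %.4f mm differs from expected %.4f mm",
                    sp, expected_spacing_mm))
  list(volumes = lapply(imgs, function(i) array(as.double(i), dim(i))),
       spacing_mm = as.double(sp))
}

#' Write a phantom to disk (NIfTI volumes and masks, CSV truth, YAML config)
#'
#' @param phantom result of \code{generate_phantom}.
#' @param dir output directory.
#' @param config the \code{phantom_config} used (stored as YAML alongside).
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom <- function(phantom, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$spacing_mm
  wr <- function(arr, name) {
    img <- RNifti::asNifti(array(as.double(arr), dim(arr)[1:3]))
    RNifti::pixdim(img) <- c(sp, sp, sp)
    path <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(
    vapply(names(phantom$volumes),
           function(m) wr(phantom$volumes[[m]], m), character(1)),
    lesion_mask = wr(phantom$lesion_mask, "lesion_mask"),
    rim_pos_mask = wr(phantom$rim_pos_mask, "rim_pos_mask"),
    artefact_mask = wr(phantom$artefact_mask, "artefact_mask"))
  for (r in names(phantom$region_masks))
    paths[[paste0("region_", r)]] <- wr(phantom$region_masks[[r]],
                                        paste0("region_", r))
  write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "phantom_config.yaml"))
  invisible(paths)
}

#' Generate a multi-patient phantom cohort
#'
#' One phantom volume per patient, with per-patient lesion counts drawn
#' around the cohort's rim+ fraction, split across two synthetic sites.
#' Candidates are extracted, labelled against the ground-truth rim+ mask and
#' turned into patches, giving a complete labelled dataset for fold
#' construction and training.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient mean lesions per patient (each patient gets
#'   a Poisson draw, minimum 1).
#' @param rim_pos_fraction fraction of lesions that are rim+.
#' @param patch_size patch edge length.
#' @param config_fn function(n_rim_pos, n_rim_neg, seed) returning a
#'   \code{phantom_config}; override to change contrast/noise.
#' @param sites character vector of site names cycled over patients.
#' @param seed cohort seed.
#' @return List: \code{patches} (list of \code{lesion_patch}),
#'   \code{patients} (data frame for \code{make_folds}), \code{truth}
#'   (per-lesion table across patients).
#' @export
phantom_cohort <- function(n_patients = 24L, lesions_per_patient = 12,
                           rim_pos_fraction = 0.25, patch_size = 16L,
                           config_fn = NULL, sites = c("siteA", "siteB"),
                           seed = 1L) {
  if (is.null(config_fn)) {
    config_fn <- function(n_rim_pos, n_rim_neg, seed) {
      phantom_config(grid_shape = c(64L, 64L, 64L), n_rim_pos = n_rim_pos,
                     n_rim_neg = n_rim_neg, n_artefacts = 0L,
                     noise_sd = 0.02, bias_field_amplitude = 0.05,
                     seed = seed)
    }
  }
  counts <- with_seed(derive_seed(seed, "cohort"), {
    n_les <- pmax(1L, stats::rpois(n_patients, lesions_per_patient))
    n_pos <- stats::rbinom(n_patients, n_les, rim_pos_fraction)
    list(n_les = n_les, n_pos = n_pos)
  })
  patches <- list()
  truth_all <- NULL
  patients <- NULL
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    site <- sites[(i - 1L) %% length(sites) + 1L]
    cfg <- config_fn(counts$n_pos[i], counts$n_les[i] - counts$n_pos[i],
                     derive_seed(seed, paste0("patient", i)))
    ph <- generate_phantom(cfg)
    cands <- extract_components(ph$lesion_mask != 0, ph$spacing_mm,
                                patient_id = pid, site_id = site)
    cands <- label_candidates(cands, ph$rim_pos_mask)
    for (cc in cands)
      patches <- c(patches, list(extract_patch(ph$volumes, cc, patch_size)))
    tr <- ph$truth
    tr$patient_id <- pid
    tr$site_id <- site
    truth_all <- rbind(truth_all, tr)
    patients <- rbind(patients,
                      data.frame(patient_id = pid, site_id = site,
                                 n_rim_pos = sum(vapply(cands, function(cc)
                                   cc$label == "rim+", logical(1))),
                                 n_rim_neg = sum(vapply(cands, function(cc)
                                   cc$label == "rim-", logical(1))),
                                 stringsAsFactors = FALSE))
  }
  list(patches = patches, patients = patients, truth = truth_all)
}

#' Cross-validated training and evaluation on a labelled patch set
#'
#' Runs patient-grouped k-fold cross-validation: for each fold, trains on
#' the remaining folds and scores the held-out fold. Offline augmentation
#' (when enabled) is computed from training-fold patches only.
#'
#' @param patches list of labelled \code{lesion_patch}.
#' @param patients data frame for \code{make_folds}.
#' @param net a \code{prl_net_spec}.
#' @param config a \code{train_config}.
#' @param n_folds folds (default 4).
#' @param modalities integer indices of the patch modalities fed to the
#'   network (length must equal \code{net$n_mod}).
#' @param offline_augment_rim_pos apply tenfold rotations to training rim+
#'   patches.
#' @param val_fraction fraction of training patients held out as the
#'   validation set when the ladder protocol is used (ignored with a fixed
#'   \code{epoch_budget}).
#' @param seed seed.
#' @return List: per-fold scores/labels/patient ids, per-fold models and the
#'   fold split.
#' @export
cv_train_eval <- function(patches, patients, net, config = train_config(),
                          n_folds = 4L, modalities = seq_len(net$n_mod),
                          offline_augment_rim_pos = FALSE,
                          val_fraction = 0.2, seed = 1L) {
  stopifnot(length(modalities) == net$n_mod)
  folds <- make_folds(patients, n_folds, seed = derive_seed(seed, "folds"))
  fold_of <- setNames(folds$fold, folds$patient_id)
  pids <- vapply(patches, function(p) p$patient_id, character(1))
  labels <- patch_labels(patches)
  scores_by_fold <- vector("list", n_folds)
  labels_by_fold <- vector("list", n_folds)
  pids_by_fold <- vector("list", n_folds)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold_of[pids] == f
    tr_patches <- patches[!te]
    if (offline_augment_rim_pos) {
      aug <- list()
      for (p in tr_patches) {
        if (identical(p$label, "rim+")) aug <- c(aug, offline_rotations(p))
        else aug <- c(aug, list(p))
      }
      tr_patches <- aug
    }
    tr_y <- patch_labels(tr_patches)
    tr_x <- patches_to_array(tr_patches, modalities = modalities)
    fixed_budget <- !is.null(config$epoch_budget)
    if (fixed_budget) {
      val_x <- NULL; val_y <- NULL
    } else {
      tr_pids <- vapply(tr_patches, function(p) p$patient_id, character(1))
      up <- unique(tr_pids)
      n_val <- max(1L, round(length(up) * val_fraction))
      val_p <- with_seed(derive_seed(seed, paste0("val", f)),
                         sample(up, n_val))
      vi <- tr_pids %in% val_p
      if (length(unique(tr_y[vi])) < 2L || length(unique(tr_y[!vi])) < 2L) {
        # degenerate split: fall back to a stratified lesion-level split
        vi <- with_seed(derive_seed(seed, paste0("vals", f)), {
          idx <- c(sample(which(tr_y == 1L), max(1L, sum(tr_y == 1L) %/% 5L)),
                   sample(which(tr_y == 0L), max(1L, sum(tr_y == 0L) %/% 5L)))
          seq_along(tr_y) %in% idx
        })
      }
      val_x <- tr_x[, , , , vi, drop = FALSE]
      val_y <- tr_y[vi]
      tr_x <- tr_x[, , , , !vi, drop = FALSE]
      tr_y <- tr_y[!vi]
    }
    models[[f]] <- train_model(tr_x, tr_y, net, config, val_x, val_y,
                               seed = derive_seed(seed, paste0("fold", f)))
    te_x <- patches_to_array(patches[te], modalities = modalities)
    scores_by_fold[[f]] <- predict_proba(models[[f]], te_x)
    labels_by_fold[[f]] <- labels[te]
    pids_by_fold[[f]] <- pids[te]
  }
  list(scores_by_fold = scores_by_fold, labels_by_fold = labels_by_fold,
       patient_ids_by_fold = pids_by_fold, models = models, folds = folds)
}

#' Run the full pipeline from a configuration list
#'
#' Stages: phantom generation (or volume loading) -> candidate extraction
#' and labelling -> exclusions -> patches -> folds -> training -> lesion-
#' and patient-level evaluation. Every stage writes its manifest into the
#' run directory; rerunning with the same config and seed reproduces the
#' manifests.
#'
#' @param config list (or YAML path) with elements \code{phantom} (counts
#'   etc. for the synthetic cohort) or \code{inputs} (NIfTI paths),
#'   \code{exclusion}, \code{patch_size}, \code{arch}, \code{train},
#'   \code{n_folds}, \code{seed}.
#' @param out_dir run directory (created; must not already contain a run).
#' @return The evaluation report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  patch_size <- config$patch_size %||% 16L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config_snapshot.yaml"))

  ph_cfg <- config$phantom %||% list()
  cohort <- phantom_cohort(
    n_patients = ph_cfg$n_patients %||% 8L,
    lesions_per_patient = ph_cfg$lesions_per_patient %||% 8,
    rim_pos_fraction = ph_cfg$rim_pos_fraction %||% 0.25,
    patch_size = patch_size,
    seed = derive_seed(seed, "phantom"))
  write.csv(cohort$truth, file.path(out_dir, "lesions.csv"),
            row.names = FALSE)
  write.csv(cohort$patients, file.path(out_dir, "patients.csv"),
            row.names = FALSE)

  arch_args <- config$arch %||% list()
  arch <- arch_config(modalities = arch_args$modalities %||% 2L,
                      patch_size = patch_size,
                      filters = as.integer(arch_args$filters %||% c(8L, 16L, 32L)),
                      fc = as.integer(arch_args$fc %||% c(64L, 16L)))
  net <- if (arch$modalities == 2L) build_bimodal_net(arch) else
    build_unimodal_net(arch)
  tr_args <- config$train %||% list()
  tcfg <- train_config(
    learning_rates = tr_args$learning_rates %||% 1e-3,
    patience = tr_args$patience %||% 3L,
    batch_size = tr_args$batch_size %||% 32L,
    max_epochs = tr_args$max_epochs %||% 6L,
    online_augment = tr_args$online_augment %||% TRUE,
    epoch_budget = tr_args$epoch_budget)
  modalities <- as.integer(config$modalities %||%
                             (if (arch$modalities == 2L) c(2L, 1L) else 2L))
  res <- cv_train_eval(cohort$patches, cohort$patients, net, tcfg,
                       n_folds = config$n_folds %||% 4L,
                       modalities = modalities,
                       seed = derive_seed(seed, "cv"))
  write.csv(res$folds, file.path(out_dir, "folds.csv"), row.names = FALSE)
  rep <- eval_report(res$scores_by_fold, res$labels_by_fold,
                     res$patient_ids_by_fold)
  jsonlite::write_json(
    list(auc_roc = rep$curves$auc_roc, auc_pr = rep$curves$auc_pr,
         auc_roc_by_fold = rep$curves$auc_roc_by_fold,
         operating_point = rep$operating_point, confusion = rep$confusion,
         metrics = rep$metrics),
    file.path(out_dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  scores <- data.frame(
    fold = rep(seq_along(res$scores_by_fold),
               vapply(res$scores_by_fold, length, integer(1))),
    patient_id = unlist(res$patient_ids_by_fold),
    score = unlist(res$scores_by_fold),
    label = unlist(res$labels_by_fold))
  write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  invisible(rep)
}
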