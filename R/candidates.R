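#' Extract lesion candidates as 6-connected components
#'
#' Every maximal 6-connected component (face adjacency only) of the binary
#' segmentation mask becomes one lesion candidate. Components are numbered in
#' the order of their first voxel in a linear (x-fastest) scan, so the
#' ordering is deterministic.
#'
#' @param mask binary 3D array (lesion segmentation).
#' @param spacing_mm isotropic voxel size in mm.
#' @param patient_id,site_id optional provenance attached to every candidate.
#' @return A list of \code{lesion_candidate} objects, each with fields
#'   \code{id}, \code{voxels} (linear indices), \code{voxel_count},
#'   \code{volume_mm3} (= voxel_count x spacing^3), \code{center_of_mass}
#'   (continuous 0-based voxel coordinates), \code{label} (NA until
#'   labelled), \code{patient_id}, \code{site_id}.
#' @export
extract_components <- function(mask, spacing_mm, patient_id = NA_character_,
                               site_id = NA_character_) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")
  stopifnot_binary(mask)
  dims <- dim(mask)
  lab <- cc_label6_cpp(as.integer(mask != 0), as.integer(dims))
  n <- attr(lab, "n_components")
  if (n == 0L) return(list())
  vox_by_comp <- split(which(lab != 0L), lab[lab != 0L])
  lapply(seq_len(n), function(i) {
    vox <- vox_by_comp[[as.character(i)]]
    com <- colMeans(arrayInd(vox, dims)) - 1  # 0-based
    structure(list(id = i, voxels = vox, voxel_count = length(vox),
                   volume_mm3 = length(vox) * spacing_mm^3,
                   center_of_mass = com, label = NA_character_,
                   exclusion_reason = NA_character_,
                   patient_id = patient_id, site_id = site_id,
                   dims = dims, spacing_mm = spacing_mm),
              class = "lesion_candidate")
  })
}

#' Label candidates rim+/rim- by overlap with the rim+ annotation mask
#'
#' A candidate is rim+ if at least one of its voxels lies in the rim+ map;
#' every candidate with no overlap is rim-.
#'
#' @param candidates list from \code{extract_components}.
#' @param rim_pos_mask binary 3D array on the same grid (may be all-FALSE).
#' @return The candidates with \code{label} set to "rim+" or "rim-".
#' @export
label_candidates <- function(candidates, rim_pos_mask) {
  if (length(candidates) == 0L) return(candidates)
  dims <- candidates[[1]]$dims
  if (!identical(as.integer(dim(rim_pos_mask)), as.integer(dims)))
    stop("rim_pos_mask grid does not match the candidates' grid")
  stopifnot_binary(rim_pos_mask)
  rp <- rim_pos_mask != 0
  lapply(candidates, function(cc) {
    cc$label <- if (any(rp[cc$voxels])) "rim+" else "rim-"
    cc
  })
}

#' Exclusion rule configuration
#'
#' @param min_volume_mm3 candidates smaller than this are excluded
#'   ("too_small"; default 12.3 mm^3).
#' @param max_voxels candidates with more voxels are excluded ("too_big";
#'   default 10000).
#' @param rim_contamination_voxels a rim- candidate whose patch window
#'   contains more than this many voxels of rim+ lesions (other than itself)
#'   is excluded ("rim_contaminated"; default 900).
#' @param exclude_artefacts apply the artefact-window rule.
#' @return An \code{exclusion_config} list.
#' @export
exclusion_config <- function(min_volume_mm3 = 12.3, max_voxels = 10000L,
                             rim_contamination_voxels = 900L,
                             exclude_artefacts = TRUE) {
  if (min_volume_mm3 < 0) stop("min_volume_mm3 must be >= 0")
  if (max_voxels <= rim_contamination_voxels)
    stop("max_voxels must exceed rim_contamination_voxels")
  structure(list(min_volume_mm3 = min_volume_mm3,
                 max_voxels = as.double(max_voxels),
                 rim_contamination_voxels = as.double(rim_contamination_voxels),
                 exclude_artefacts = isTRUE(exclude_artefacts)),
            class = "exclusion_config")
}

# patch window (0-based inclusive voxel ranges per axis) centred on the
# rounded centre of mass; may extend beyond the volume
patch_window <- function(candidate, patch_size) {
  ctr <- round_half_up(candidate$center_of_mass)
  half_lo <- (patch_size - 1L) %/% 2L
  lo <- ctr - half_lo
  cbind(lo = lo, hi = lo + patch_size - 1L)
}

# indices of in-volume voxels inside the candidate's patch window
window_voxels <- function(candidate, patch_size) {
  w <- patch_window(candidate, patch_size)
  dims <- candidate$dims
  xs <- max(0L, w[1, "lo"]):min(dims[1] - 1L, w[1, "hi"])
  ys <- max(0L, w[2, "lo"]):min(dims[2] - 1L, w[2, "hi"])
  zs <- max(0L, w[3, "lo"]):min(dims[3] - 1L, w[3, "hi"])
  lx <- length(xs); ly <- length(ys); lz <- length(zs)
  rep.int(xs + 1L, ly * lz) +
    rep.int(rep(dims[1] * ys, each = lx), lz) +
    rep(dims[1] * dims[2] * zs, each = lx * ly)
}

#' Apply the candidate exclusion rules
#'
#' Rules are applied in a fixed order; the first rule that fires records the
#' exclusion reason: (1) volume below \code{min_volume_mm3} ("too_small");
#' (2) voxel count above \code{max_voxels} ("too_big"); (3) patch window
#' intersects the artefact mask ("artefact"); (4) a rim- candidate whose
#' patch window contains more than \code{rim_contamination_voxels} voxels of
#' rim+ lesions ("rim_contaminated").
#'
#' @param candidates labelled candidates (see \code{label_candidates}).
#' @param rim_pos_mask binary rim+ annotation mask (for rule 4).
#' @param artefact_mask binary mask of air/susceptibility artefacts, or NULL.
#' @param config an \code{exclusion_config}.
#' @param patch_size patch edge length in voxels (window for rules 3-4).
#' @return A list with \code{kept} and \code{excluded} candidate lists and
#'   \code{report}, a data frame of per-reason, per-class exclusion counts
#'   plus kept totals.
#' @export
apply_exclusions <- function(candidates, rim_pos_mask = NULL,
                             artefact_mask = NULL,
                             config = exclusion_config(), patch_size = 28L) {
  stopifnot(inherits(config, "exclusion_config"))
  if (length(candidates) > 0 &&
      any(vapply(candidates, function(cc) is.na(cc$label), logical(1))))
    stop("candidates must be labelled before exclusion")
  rp <- if (!is.null(rim_pos_mask)) rim_pos_mask != 0 else NULL
  art <- if (!is.null(artefact_mask)) artefact_mask != 0 else NULL

  # rim+ voxels not belonging to the candidate itself (rule 4) need the
  # candidate's own voxels removed from the count
  kept <- list()
  excluded <- list()
  for (cc in candidates) {
    reason <- NA_character_
    wv <- NULL
    if (cc$volume_mm3 < config$min_volume_mm3) {
      reason <- "too_small"
    } else if (cc$voxel_count > config$max_voxels) {
      reason <- "too_big"
    } else if (config$exclude_artefacts && !is.null(art)) {
      wv <- window_voxels(cc, patch_size)
      if (any(art[wv])) reason <- "artefact"
    }
    if (is.na(reason) && cc$label == "rim-" && !is.null(rp)) {
      if (is.null(wv)) wv <- window_voxels(cc, patch_size)
      n_rim <- sum(rp[wv]) - sum(rp[cc$voxels])
      if (n_rim > config$rim_contamination_voxels) reason <- "rim_contaminated"
    }
    if (is.na(reason)) {
      kept <- c(kept, list(cc))
    } else {
      cc$exclusion_reason <- reason
      excluded <- c(excluded, list(cc))
    }
  }

  reasons <- c("too_small", "too_big", "artefact", "rim_contaminated")
  tab <- function(lst, lab, why) {
    sum(vapply(lst, function(cc) {
      cc$label == lab && (is.na(why) || identical(cc$exclusion_reason, why))
    }, logical(1)))
  }
  report <- data.frame(
    reason = c(reasons, "kept"),
    rim_neg = c(vapply(reasons, function(r) tab(excluded, "rim-", r), numeric(1)),
                tab(kept, "rim-", NA)),
    rim_pos = c(vapply(reasons, function(r) tab(excluded, "rim+", r), numeric(1)),
                tab(kept, "rim+", NA)),
    row.names = NULL, stringsAsFactors = FALSE)

  list(kept = kept, excluded = excluded, report = report)
}

#' Summarize candidates as a data frame
#'
#' @param candidates a list of \code{lesion_candidate} objects.
#' @return A data frame (id, patient, site, label, voxel_count, volume_mm3,
#'   center of mass, exclusion_reason).
#' @export
candidate_table <- function(candidates) {
  if (length(candidates) == 0L)
    return(data.frame(id = integer(), patient_id = character(),
                      site_id = character(), label = character(),
                      voxel_count = integer(), volume_mm3 = numeric(),
                      com_x = numeric(), com_y = numeric(), com_z = numeric(),
                      exclusion_reason = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(candidates, function(cc) {
    data.frame(id = cc$id, patient_id = cc$patient_id, site_id = cc$site_id,
               label = cc$label, voxel_count = cc$voxel_count,
               volume_mm3 = cc$volume_mm3, com_x = cc$center_of_mass[1],
               com_y = cc$center_of_mass[2], com_z = cc$center_of_mass[3],
               exclusion_reason = cc$exclusion_reason,
               stringsAsFactors = FALSE)
  }))
}
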