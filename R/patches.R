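#' Extract a fixed-size multimodal patch centred on a lesion candidate
#'
#' The cubic window is centred on the candidate's rounded (half-up) centre of
#' mass; voxels outside the volume are zero-filled before normalization.
#' Each modality is independently linearly mapped so that its patch minimum
#' becomes -1 and its maximum +1; a constant window maps to all zeros.
#'
#' @param volumes named list of 3D arrays (co-registered modalities), or a
#'   single 3D array.
#' @param candidate a \code{lesion_candidate}.
#' @param patch_size cubic edge length in voxels (default 28).
#' @param normalize linearly rescale each modality to [-1, 1] (default TRUE).
#' @return A \code{lesion_patch}: list with \code{data} (array
#'   patch_size^3 x modalities), \code{label}, \code{candidate_id},
#'   \code{patient_id}, \code{site_id} and \code{transforms} (character log
#'   of augmentations applied, empty here).
#' @export
extract_patch <- function(volumes, candidate, patch_size = 28L,
                          normalize = TRUE) {
  if (is.array(volumes) && length(dim(volumes)) == 3L)
    volumes <- list(volumes)
  dims <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), dims), logical(1))))
    stop("all modalities must share one grid")
  if (!identical(as.integer(dims), as.integer(candidate$dims)))
    stop("candidate grid does not match the volumes")
  if (any(patch_size > dims)) stop("patch_size larger than the volume")
  w <- patch_window(candidate, patch_size)
  P <- as.integer(patch_size)
  out <- array(0, c(P, P, P, length(volumes)))
  # in-volume source range (0-based) and its destination offset in the patch
  src_lo <- pmax(w[, "lo"], 0L)
  src_hi <- pmin(w[, "hi"], dims - 1L)
  if (all(src_lo <= src_hi)) {
    dst <- lapply(1:3, function(a) (src_lo[a]:src_hi[a]) - w[a, "lo"] + 1L)
    for (m in seq_along(volumes)) {
      block <- volumes[[m]][(src_lo[1]:src_hi[1]) + 1L,
                            (src_lo[2]:src_hi[2]) + 1L,
                            (src_lo[3]:src_hi[3]) + 1L, drop = FALSE]
      out[dst[[1]], dst[[2]], dst[[3]], m] <- block
    }
  }
  if (normalize) {
    for (m in seq_along(volumes)) {
      v <- out[, , , m]
      rng <- range(v)
      if (rng[2] > rng[1]) {
        out[, , , m] <- 2 * (v - rng[1]) / (rng[2] - rng[1]) - 1
      } else {
        out[, , , m] <- 0
      }
    }
  }
  structure(list(data = out, label = candidate$label,
                 candidate_id = candidate$id,
                 patient_id = candidate$patient_id,
                 site_id = candidate$site_id,
                 transforms = character(0)),
            class = "lesion_patch")
}

#' Normalize a patch array to [-1, 1] per modality
#'
#' Idempotent (up to floating tolerance) on already-normalized data.
#'
#' @param data array (P, P, P, modalities).
#' @return The rescaled array.
#' @export
normalize_patch <- function(data) {
  stopifnot(length(dim(data)) == 4L)
  for (m in seq_len(dim(data)[4])) {
    v <- data[, , , m]
    rng <- range(v)
    data[, , , m] <- if (rng[2] > rng[1])
      2 * (v - rng[1]) / (rng[2] - rng[1]) - 1 else 0
  }
  data
}

#' Stack patches into a network input array
#'
#' @param patches list of \code{lesion_patch}.
#' @param n_mod how many (leading) modalities to keep; defaults to all.
#' @param modalities optional integer indices selecting and ordering
#'   modalities (e.g. \code{c(2, 1)} to make the second modality the main
#'   branch input).
#' @return Array of dimension (P, P, P, n_mod, N).
#' @export
patches_to_array <- function(patches, n_mod = NULL, modalities = NULL) {
  stopifnot(length(patches) > 0)
  d <- dim(patches[[1]]$data)
  if (is.null(modalities)) modalities <- seq_len(n_mod %||% d[4])
  out <- array(0, c(d[1:3], length(modalities), length(patches)))
  for (i in seq_along(patches))
    out[, , , , i] <- patches[[i]]$data[, , , modalities, drop = FALSE]
  out
}

#' Binary labels (rim+ = 1) of a patch list
#' @param patches list of \code{lesion_patch}.
#' @return Integer vector, 1 for rim+, 0 for rim-.
#' @export
patch_labels <- function(patches) {
  vapply(patches, function(p) as.integer(identical(p$label, "rim+")), integer(1))
}

#' Write patches and a manifest to a directory
#'
#' Patches are stored as one compressed NIfTI per patch
#' (P x P x P x modalities) plus a CSV manifest (id, label, patient, site,
#' transforms, file).
#'
#' @param patches list of \code{lesion_patch}.
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_patches <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    file <- sprintf("patch_%05d.nii.gz", i)
    RNifti::writeNifti(p$data, file.path(dir, file))
    data.frame(index = i, candidate_id = p$candidate_id, label = p$label,
               patient_id = p$patient_id, site_id = p$site_id,
               transforms = paste(p$transforms, collapse = ";"),
               file = file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
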