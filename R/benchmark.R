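#' Synthetic exclusion-bookkeeping cohort
#'
#' Builds, fully in code, a synthetic segmentation whose candidate
#' composition matches a configurable dataset inventory: plain small
#' lesions of both classes, oversized lesions (> \code{max_voxels} voxels),
#' lesions adjacent to artefact voxels, and rim- lesions placed next to a
#' large rim+ lesion so that their patch window contains more than the
#' contamination threshold of rim+ voxels. Defaults reproduce the reference
#' dataset inventory: 4857 rim- / 462 rim+ candidates of which 32 + 25 + 113
#' rim- and 4 + 1 rim+ are removed by the size/artefact/contamination rules,
#' leaving 4687 rim- and 457 rim+.
#'
#' Lesions are laid out on a regular lattice in disjoint regions (one per
#' category) separated by more than a patch half-width, so each exclusion
#' rule fires exactly where intended. Voxel spacing is 1 mm, so the
#' 13-voxel small lesions (13 mm^3) pass the 12.3 mm^3 size filter.
#'
#' @param n_neg_plain,n_pos_plain small kept lesions per class.
#' @param n_neg_big,n_pos_big oversized (22^3 = 10648 voxel) lesions.
#' @param n_neg_artefact,n_pos_artefact lesions with an artefact voxel
#'   inside their patch window.
#' @param n_neg_contaminated rim- lesions paired with a 1000-voxel rim+
#'   neighbour inside their patch window (the neighbours are kept rim+
#'   lesions and are included in \code{n_pos_plain}'s complement).
#' @param patch_size patch edge (default 28) used for the window rules.
#' @return List: \code{lesion_mask}, \code{rim_pos_mask},
#'   \code{artefact_mask} (3D arrays), \code{spacing_mm}, \code{patch_size}
#'   and the expected per-category counts.
#' @export
exclusion_benchmark_cohort <- function(n_neg_plain = 4687L,
                                       n_pos_plain = 344L,
                                       n_neg_big = 32L, n_pos_big = 4L,
                                       n_neg_artefact = 25L,
                                       n_pos_artefact = 1L,
                                       n_neg_contaminated = 113L,
                                       patch_size = 28L) {
  W <- 240L
  # 13-voxel blob: 3x3 slab plus 2x2 cap; 6-connected, fits 3x3x2
  blob13 <- rbind(as.matrix(expand.grid(0:2, 0:2, 0)),
                  as.matrix(expand.grid(0:1, 0:1, 1)))
  cube22 <- as.matrix(expand.grid(0:21, 0:21, 0:21))
  donor10 <- as.matrix(expand.grid(0:9, 0:9, 0:9))

  origins <- function(n, cell, z0) {
    if (n == 0L) return(list(o = matrix(0L, 0, 3), height = 0L))
    nx <- W %/% cell[1]
    ny <- W %/% cell[2]
    i <- seq_len(n) - 1L
    o <- cbind((i %% nx) * cell[1],
               ((i %/% nx) %% ny) * cell[2],
               z0 + (i %/% (nx * ny)) * cell[3])
    list(o = o, height = (max(i %/% (nx * ny)) + 1L) * cell[3])
  }

  gap <- 16L
  z <- 0L
  plain_neg <- origins(n_neg_plain, c(8L, 8L, 8L), z)
  z <- z + plain_neg$height + gap
  plain_pos <- origins(n_pos_plain, c(8L, 8L, 8L), z)
  z <- z + plain_pos$height + gap
  big_neg <- origins(n_neg_big, c(26L, 26L, 26L), z)
  z <- z + big_neg$height + gap
  big_pos <- origins(n_pos_big, c(26L, 26L, 26L), z)
  z <- z + big_pos$height + gap
  art <- origins(n_neg_artefact + n_pos_artefact, c(32L, 32L, 32L), z)
  z <- z + art$height + gap
  contam <- origins(n_neg_contaminated, c(48L, 24L, 24L), z)
  z <- z + contam$height + 4L
  dims <- c(W, W, z)

  lin <- function(xyz) xyz[, 1] + dims[1] * (xyz[, 2] + dims[2] * xyz[, 3]) + 1
  stamp <- function(orig, inner, offsets) {
    if (nrow(orig) == 0L) return(integer(0))
    base <- sweep(orig, 2, inner, "+")
    idx <- rep(lin(base), each = nrow(offsets)) +
      rep.int(offsets[, 1] + dims[1] * (offsets[, 2] + dims[2] * offsets[, 3]),
              nrow(base))
    as.integer(idx)
  }

  neg_idx <- c(stamp(plain_neg$o, c(2L, 2L, 2L), blob13),
               stamp(big_neg$o, c(2L, 2L, 2L), cube22),
               stamp(art$o[seq_len(n_neg_artefact), , drop = FALSE],
                     c(2L, 2L, 2L), blob13),
               stamp(contam$o, c(13L, 10L, 10L), blob13))
  pos_idx <- c(stamp(plain_pos$o, c(2L, 2L, 2L), blob13),
               stamp(big_pos$o, c(2L, 2L, 2L), cube22),
               stamp(art$o[n_neg_artefact + seq_len(n_pos_artefact), ,
                           drop = FALSE], c(2L, 2L, 2L), blob13),
               stamp(contam$o, c(2L, 7L, 7L), donor10))

  lesion_mask <- array(FALSE, dims)
  lesion_mask[neg_idx] <- TRUE
  lesion_mask[pos_idx] <- TRUE
  rim_pos_mask <- array(FALSE, dims)
  rim_pos_mask[pos_idx] <- TRUE
  artefact_mask <- array(FALSE, dims)
  if (nrow(art$o) > 0L)
    artefact_mask[lin(sweep(art$o, 2, c(13L, 3L, 3L), "+"))] <- TRUE

  list(lesion_mask = lesion_mask, rim_pos_mask = rim_pos_mask,
       artefact_mask = artefact_mask, spacing_mm = 1, patch_size = patch_size,
       expected = list(
         n_neg = n_neg_plain + n_neg_big + n_neg_artefact + n_neg_contaminated,
         n_pos = n_pos_plain + n_pos_big + n_pos_artefact + n_neg_contaminated,
         kept_neg = n_neg_plain,
         kept_pos = n_pos_plain + n_neg_contaminated,
         removed_neg = c(too_big = n_neg_big, artefact = n_neg_artefact,
                         rim_contaminated = n_neg_contaminated),
         removed_pos = c(too_big = n_pos_big, artefact = n_pos_artefact)))
}

#' Run candidate extraction and exclusion on a benchmark cohort
#'
#' @param cohort result of \code{exclusion_benchmark_cohort}.
#' @return The \code{apply_exclusions} result (kept, excluded, report).
#' @export
run_exclusion_benchmark <- function(cohort) {
  cands <- extract_components(cohort$lesion_mask, cohort$spacing_mm)
  cands <- label_candidates(cands, cohort$rim_pos_mask)
  apply_exclusions(cands, cohort$rim_pos_mask, cohort$artefact_mask,
                   exclusion_config(), cohort$patch_size)
}
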