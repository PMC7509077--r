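#' Configuration for the synthetic multimodal phantom
#'
#' The phantom emulates the imaging appearance that drives rim+/rim-
#' classification on co-registered 3D MRI: ellipsoidal lesions that are
#' hyperintense on a FLAIR-like channel; for rim+ lesions only, a thin closed
#' shell at the lesion edge that is hypointense (phase-shifted) on the
#' phase-like channel and signal-attenuated on the T2*-like channel;
#' rim-shaped intensity artefacts on phase that have no FLAIR lesion;
#' optional confluent lesion pairs; additive Gaussian noise and a smooth
#' polynomial bias field. It makes no claim of MR-physical realism: contrast
#' magnitudes are free parameters.
#'
#' @param grid_shape integer vector of 3 voxel counts per axis (each >= 64).
#' @param spacing_mm isotropic voxel size in mm (default 0.65).
#' @param n_rim_pos,n_rim_neg,n_artefacts counts of rim+ lesions, rim-
#'   lesions and lesion-free rim-like artefacts.
#' @param lesion_radius_range_mm min/max ellipsoid semi-axis length in mm.
#'   The minimum must keep every rim+ lesion above the 12.3 mm^3 size filter.
#' @param rim_thickness_mm rim shell width in mm (> 0).
#' @param contrast named list of per-channel intensities: \code{flair_bg},
#'   \code{flair_lesion}, \code{phase_bg}, \code{phase_rim} (added on the
#'   shell; negative = hypointense), \code{t2s_bg}, \code{t2s_lesion},
#'   \code{t2s_rim}.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_field_amplitude peak fractional amplitude of the smooth
#'   multiplicative bias field (0 disables it).
#' @param confluence_probability probability that a lesion is deliberately
#'   placed overlapping a previous one, creating a confluent pair.
#' @param rim_sign +1 or -1: polarity of the phase rim (default -1,
#'   hypointense shell).
#' @param seed integer RNG seed; generation is bit-reproducible given the
#'   seed.
#' @return A \code{phantom_config} list.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L), spacing_mm = 0.65,
                           n_rim_pos = 5L, n_rim_neg = 20L, n_artefacts = 2L,
                           lesion_radius_range_mm = c(1.8, 4.5),
                           rim_thickness_mm = 0.8,
                           contrast = list(flair_bg = 0.2, flair_lesion = 0.8,
                                           phase_bg = 0, phase_rim = 0.5,
                                           t2s_bg = 0.7, t2s_lesion = 0.75,
                                           t2s_rim = 0.35),
                           noise_sd = 0.02, bias_field_amplitude = 0.1,
                           confluence_probability = 0, rim_sign = -1,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 64L))
    stop("grid_shape must be three integers, each >= 64")
  if (any(c(n_rim_pos, n_rim_neg, n_artefacts) < 0)) stop("counts must be >= 0")
  if (rim_thickness_mm <= 0) stop("rim_thickness_mm must be > 0")
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")
  if (length(lesion_radius_range_mm) != 2L ||
      lesion_radius_range_mm[1] > lesion_radius_range_mm[2])
    stop("lesion_radius_range_mm must be (min, max)")
  # smallest possible lesion must survive the 12.3 mm^3 size filter
  min_vol <- 4 / 3 * pi * lesion_radius_range_mm[1]^3
  if (min_vol <= 12.3)
    stop(sprintf(
      "minimum lesion radius %.2f mm gives volume %.1f mm^3 <= 12.3 mm^3",
      lesion_radius_range_mm[1], min_vol))
  if (!rim_sign %in% c(-1, 1)) stop("rim_sign must be -1 or +1")
  if (confluence_probability < 0 || confluence_probability > 1)
    stop("confluence_probability must be in [0, 1]")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 n_rim_pos = as.integer(n_rim_pos),
                 n_rim_neg = as.integer(n_rim_neg),
                 n_artefacts = as.integer(n_artefacts),
                 lesion_radius_range_mm = as.double(lesion_radius_range_mm),
                 rim_thickness_mm = rim_thickness_mm, contrast = contrast,
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 confluence_probability = confluence_probability,
                 rim_sign = rim_sign, seed = as.integer(seed)),
            class = "phantom_config")
}

# voxel mask of a randomly-oriented ellipsoid; returns linear indices
ellipsoid_voxels <- function(center_vox, semi_axes_vox, rot, grid_shape) {
  r_max <- max(semi_axes_vox)
  lo <- pmax(1L, floor(center_vox - r_max - 1))
  hi <- pmin(grid_shape, ceiling(center_vox + r_max + 1))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  rel <- sweep(g, 2, center_vox) %*% t(rot)
  q <- (rel[, 1] / semi_axes_vox[1])^2 + (rel[, 2] / semi_axes_vox[2])^2 +
    (rel[, 3] / semi_axes_vox[3])^2
  inside <- q <= 1
  g <- g[inside, , drop = FALSE]
  (g[, 1] - 1L) + grid_shape[1] * ((g[, 2] - 1L) + grid_shape[2] * (g[, 3] - 1L)) + 1L
}

random_rotation <- function() {
  # QR of a Gaussian matrix gives a uniformly distributed rotation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# smooth multiplicative field: second-order polynomial in normalized coords,
# scaled so its maximum absolute deviation equals `amplitude`
bias_field <- function(grid_shape, amplitude) {
  if (amplitude == 0) return(1)
  co <- rnorm(9)
  u <- (seq_len(grid_shape[1]) - 1) / (grid_shape[1] - 1) * 2 - 1
  v <- (seq_len(grid_shape[2]) - 1) / (grid_shape[2] - 1) * 2 - 1
  w <- (seq_len(grid_shape[3]) - 1) / (grid_shape[3] - 1) * 2 - 1
  f <- outer(co[1] * u + co[4] * u^2, co[2] * v + co[5] * v^2, "+")
  f <- outer(f, co[3] * w + co[6] * w^2, "+") +
    co[7] * outer(outer(u, v), rep(1, grid_shape[3])) +
    co[8] * outer(outer(u, rep(1, grid_shape[2])), w) +
    co[9] * outer(outer(rep(1, grid_shape[1]), v), w)
  1 + amplitude * f / max(abs(f))
}

#' Generate a synthetic multimodal phantom volume with ground truth
#'
#' Places randomly-oriented ellipsoidal lesions (rejecting overlaps unless a
#' confluent pair is drawn), paints the three channels (FLAIR-like,
#' phase-like, T2*-like), carves erosion-based rim shells for rim+ lesions,
#' adds lesion-free rim artefacts on the phase channel, then applies the bias
#' field and noise. Simple geometric region masks (ventricles: central
#' ellipsoid; cortex: outer shell of the brain ellipsoid; deep white matter:
#' remainder) are included for location analyses.
#'
#' @param config a \code{phantom_config}.
#' @return A list with elements \code{volumes} (named list of 3D arrays:
#'   \code{flair}, \code{phase}, \code{t2s}), \code{spacing_mm},
#'   \code{lesion_mask} (integer-labelled components), \code{rim_pos_mask},
#'   \code{artefact_mask}, \code{region_masks} and \code{truth}, a data frame
#'   with one row per placed lesion (id, class, voxel_count, volume_mm3,
#'   center of mass, confluent flag).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  sp <- config$spacing_mm
  n_tot <- config$n_rim_pos + config$n_rim_neg
  with_seed(config$seed, {
    lesion_lab <- array(0L, gs)
    classes <- rep(c("rim+", "rim-"),
                   c(config$n_rim_pos, config$n_rim_neg))
    confluent <- logical(n_tot)
    vox_list <- vector("list", n_tot)
    margin <- config$lesion_radius_range_mm[2] / sp + 2
    centers <- matrix(NA_real_, n_tot, 3)
    placed <- 0L
    failures <- 0L
    max_failures <- 400L  # consecutive failed placements before giving up
    while (placed < n_tot) {
      if (failures > max_failures)
        stop(sprintf(
          "placement failure: %d of %d lesions placed after %d consecutive failed attempts; grid too small",
          placed, n_tot, failures))
      failures <- failures + 1L
      confluence <- placed > 0L && runif(1) < config$confluence_probability
      if (confluence) {
        anchor <- sample.int(placed, 1L)
        center <- centers[anchor, ] +
          rnorm(3, sd = config$lesion_radius_range_mm[1] / sp)
      } else {
        center <- runif(3, margin, gs - margin)
      }
      if (any(center < margin) || any(center > gs - margin)) next
      semi <- runif(3, config$lesion_radius_range_mm[1],
                    config$lesion_radius_range_mm[2]) / sp
      vox <- ellipsoid_voxels(center, semi, random_rotation(), gs)
      if (length(vox) == 0L) next
      overlap <- any(lesion_lab[vox] != 0L)
      if (overlap && !confluence) next
      if (!overlap && confluence) next
      if (!overlap) {
        # distinct lesions must not even touch (face adjacency would merge
        # them into one 6-connected component)
        nb <- c(vox - 1L, vox + 1L, vox - gs[1], vox + gs[1],
                vox - gs[1] * gs[2], vox + gs[1] * gs[2])
        if (any(lesion_lab[nb] != 0L)) next
      }
      placed <- placed + 1L
      failures <- 0L
      lesion_lab[vox] <- placed
      vox_list[[placed]] <- vox
      centers[placed, ] <- center
      if (overlap) confluent[placed] <- TRUE
    }
    # voxel sets may have been partially overwritten by confluent overlaps;
    # re-derive each lesion's surviving voxels
    for (i in seq_len(n_tot)) vox_list[[i]] <- which(lesion_lab == i)

    # rim shells: erosion-based boundary layer of each rim+ lesion
    rim_iters <- max(1L, round_half_up(config$rim_thickness_mm / sp))
    rim_pos_mask <- array(FALSE, gs)
    shell_list <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      if (classes[i] != "rim+") next
      les <- array(FALSE, gs)
      les[vox_list[[i]]] <- TRUE
      core <- array(erode6_cpp(les, gs, rim_iters), gs)
      shell_list[[i]] <- which(les & !core)
      rim_pos_mask[vox_list[[i]]] <- TRUE
    }

    # artefacts: rim-like shells on phase with no FLAIR lesion
    artefact_mask <- array(FALSE, gs)
    art_placed <- 0L
    failures <- 0L
    while (art_placed < config$n_artefacts) {
      if (failures > 400L)
        stop("placement failure: artefacts do not fit the remaining grid")
      failures <- failures + 1L
      center <- runif(3, margin, gs - margin)
      semi <- runif(3, config$lesion_radius_range_mm[1],
                    config$lesion_radius_range_mm[2]) / sp
      vox <- ellipsoid_voxels(center, semi, random_rotation(), gs)
      if (length(vox) == 0L) next
      nb <- c(vox, vox - 1L, vox + 1L, vox - gs[1], vox + gs[1],
              vox - gs[1] * gs[2], vox + gs[1] * gs[2])
      if (any(lesion_lab[nb] != 0L) || any(artefact_mask[nb])) next
      blob <- array(FALSE, gs)
      blob[vox] <- TRUE
      core <- array(erode6_cpp(blob, gs, rim_iters), gs)
      artefact_mask[blob & !core] <- TRUE
      art_placed <- art_placed + 1L
      failures <- 0L
    }

    # paint channels
    ct <- config$contrast
    flair <- array(ct$flair_bg, gs)
    phase <- array(ct$phase_bg, gs)
    t2s <- array(ct$t2s_bg, gs)
    les_idx <- which(lesion_lab != 0L)
    flair[les_idx] <- ct$flair_lesion
    t2s[les_idx] <- ct$t2s_lesion
    for (i in seq_len(n_tot)) {
      if (is.null(shell_list[[i]])) next
      phase[shell_list[[i]]] <- ct$phase_bg + config$rim_sign * ct$phase_rim
      t2s[shell_list[[i]]] <- ct$t2s_rim
    }
    phase[artefact_mask] <- ct$phase_bg + config$rim_sign * ct$phase_rim

    # bias field and noise
    if (config$bias_field_amplitude > 0) {
      bf <- bias_field(gs, config$bias_field_amplitude)
      flair <- flair * bf
      t2s <- t2s * bf
    }
    if (config$noise_sd > 0) {
      flair <- flair + array(rnorm(prod(gs), sd = config$noise_sd), gs)
      phase <- phase + array(rnorm(prod(gs), sd = config$noise_sd), gs)
      t2s <- t2s + array(rnorm(prod(gs), sd = config$noise_sd), gs)
    }

    # geometric region masks for location analysis
    cx <- gs / 2
    brain_r <- gs / 2 - 2
    idx <- arrayInd(seq_len(prod(gs)), gs)
    q_brain <- ((idx[, 1] - cx[1]) / brain_r[1])^2 +
      ((idx[, 2] - cx[2]) / brain_r[2])^2 + ((idx[, 3] - cx[3]) / brain_r[3])^2
    vent_r <- gs / 8
    q_vent <- ((idx[, 1] - cx[1]) / vent_r[1])^2 +
      ((idx[, 2] - cx[2]) / vent_r[2])^2 + ((idx[, 3] - cx[3]) / vent_r[3])^2
    region_masks <- list(
      ventricles = array(q_vent <= 1, gs),
      cortex = array(q_brain <= 1 & q_brain > 0.8, gs),
      deep_gray = array(FALSE, gs),
      brainstem = array(FALSE, gs),
      cerebellum = array(FALSE, gs))

    counts <- vapply(vox_list, length, integer(1))
    com <- t(vapply(vox_list, function(v) {
      colMeans(arrayInd(v, gs))
    }, numeric(3)))
    truth <- data.frame(
      id = seq_len(n_tot),
      class = classes,
      voxel_count = counts,
      volume_mm3 = counts * sp^3,
      com_x = com[, 1] - 1, com_y = com[, 2] - 1, com_z = com[, 3] - 1,
      confluent = confluent,
      stringsAsFactors = FALSE)

    list(volumes = list(flair = flair, phase = phase, t2s = t2s),
         spacing_mm = sp,
         lesion_mask = lesion_lab,
         rim_pos_mask = rim_pos_mask,
         artefact_mask = artefact_mask,
         region_masks = region_masks,
         truth = truth)
  })
}
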