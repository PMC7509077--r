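#' Augmentation configuration
#'
#' Offline augmentation (applied once, before training) rotates each rim+
#' patch by 90, 180 and 270 degrees about each of the three axes (nine
#' rotations, so original + rotated = a tenfold increase) and generates
#' elastically deformed copies. Online augmentation (applied per draw during
#' training) flips along one of X/Y/Z/none and translates each axis by -2, 0
#' or +2 voxels.
#'
#' @param n_elastic elastically deformed copies per patch (default 3,
#'   quadrupling the data).
#' @param elastic_amplitude maximum voxel displacement of the deformation
#'   field.
#' @param elastic_grid control points per axis of the coarse displacement
#'   grid.
#' @param translate_vox online translation step in voxels (applied as -step,
#'   0, +step per axis). Must stay within a quarter of the patch edge.
#' @param patch_size patch edge the translations will apply to (validation
#'   only).
#' @return An \code{augment_config} list.
#' @export
augment_config <- function(n_elastic = 3L, elastic_amplitude = 2,
                           elastic_grid = 4L, translate_vox = 2L,
                           patch_size = 28L) {
  if (n_elastic < 0) stop("n_elastic must be >= 0")
  if (elastic_amplitude < 0) stop("elastic_amplitude must be >= 0")
  if (translate_vox > patch_size / 4)
    stop("translations must stay within a quarter of the patch edge")
  structure(list(n_elastic = as.integer(n_elastic),
                 elastic_amplitude = elastic_amplitude,
                 elastic_grid = as.integer(elastic_grid),
                 translate_vox = as.integer(translate_vox)),
            class = "augment_config")
}

# rotate a 3D array by k*90 degrees about axis (1, 2 or 3); right-handed
# rotation about the array axis
rotate90_3d <- function(a, axis, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  perm <- switch(axis, c(1L, 3L, 2L), c(3L, 2L, 1L), c(2L, 1L, 3L))
  flip <- function(x, ax) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[ax]] <- rev(seq_len(dim(x)[ax]))
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  for (i in seq_len(k)) {
    a <- aperm(a, perm)
    # reverse the axis that, combined with the transpose, yields the rotation
    rev_ax <- switch(axis, 2L, 3L, 1L)
    a <- flip(a, rev_ax)
  }
  a
}

apply_per_modality <- function(data, fn) {
  for (m in seq_len(dim(data)[4])) data[, , , m] <- fn(data[, , , m])
  data
}

#' Offline right-angle rotations of a patch
#'
#' Returns the original patch plus its nine rotations (90, 180, 270 degrees
#' about each axis). All rotations are axis-aligned permutations, so no
#' interpolation occurs; each output records its transform tag.
#'
#' @param patch a \code{lesion_patch} with a cubic \code{data} array.
#' @return List of 10 patches (original first).
#' @export
offline_rotations <- function(patch) {
  d <- dim(patch$data)
  if (!(d[1] == d[2] && d[2] == d[3])) stop("patch must be cubic")
  out <- vector("list", 10L)
  patch$transforms <- c(patch$transforms, "rot:identity")
  out[[1]] <- patch
  i <- 2L
  for (axis in 1:3) {
    for (k in 1:3) {
      p <- patch
      p$data <- apply_per_modality(patch$data,
                                   function(v) rotate90_3d(v, axis, k))
      p$transforms <- c(utils::head(patch$transforms, -1L),
                        sprintf("rot:axis%d_%d", axis, 90L * k))
      out[[i]] <- p
      i <- i + 1L
    }
  }
  out
}

# trilinear sampling of a 3D array at fractional (1-based) coordinates,
# clamped to the border
trilinear_sample <- function(v, x, y, z) {
  d <- dim(v)
  cl <- function(a, n) pmin(pmax(a, 1), n)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x0 <- cl(x0, d[1]); x1 <- cl(x0 + 1, d[1])
  y0 <- cl(y0, d[2]); y1 <- cl(y0 + 1, d[2])
  z0 <- cl(z0, d[3]); z1 <- cl(z0 + 1, d[3])
  at <- function(xi, yi, zi) v[cbind(xi, yi, zi)]
  c000 <- at(x0, y0, z0); c100 <- at(x1, y0, z0)
  c010 <- at(x0, y1, z0); c110 <- at(x1, y1, z0)
  c001 <- at(x0, y0, z1); c101 <- at(x1, y0, z1)
  c011 <- at(x0, y1, z1); c111 <- at(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# smooth random displacement field: coarse Gaussian grid upsampled by
# trilinear interpolation, scaled so the maximum displacement norm equals
# `amplitude` voxels
elastic_field <- function(P, grid_n, amplitude) {
  coarse <- array(rnorm(grid_n^3 * 3), c(grid_n, grid_n, grid_n, 3))
  pos <- (seq_len(P) - 1) / (P - 1) * (grid_n - 1) + 1
  g <- expand.grid(x = pos, y = pos, z = pos)
  field <- sapply(1:3, function(a)
    trilinear_sample(coarse[, , , a], g$x, g$y, g$z))
  norms <- sqrt(rowSums(field^2))
  mx <- max(norms)
  if (mx > 0) field <- field * (amplitude / mx)
  field
}

#' Elastically deform a patch
#'
#' A coarse random vector grid is upsampled to a smooth displacement field
#' (maximum displacement = \code{config$elastic_amplitude} voxels) and the
#' patch is resampled through it with trilinear interpolation; values are
#' re-clamped to [-1, 1]. Deterministic given the seed; amplitude 0 is the
#' identity.
#'
#' @param patch a \code{lesion_patch}.
#' @param config an \code{augment_config}.
#' @param seed integer seed for the displacement field.
#' @return The deformed patch with a transform tag.
#' @export
elastic_deform <- function(patch, config = augment_config(), seed = 1L) {
  P <- dim(patch$data)[1]
  if (config$elastic_amplitude == 0) {
    patch$transforms <- c(patch$transforms, sprintf("elastic:%d", seed))
    return(patch)
  }
  with_seed(seed, {
    field <- elastic_field(P, config$elastic_grid, config$elastic_amplitude)
    g <- expand.grid(x = seq_len(P), y = seq_len(P), z = seq_len(P))
    xs <- g$x + field[, 1]; ys <- g$y + field[, 2]; zs <- g$z + field[, 3]
    for (m in seq_len(dim(patch$data)[4])) {
      v <- trilinear_sample(patch$data[, , , m], xs, ys, zs)
      patch$data[, , , m] <- array(pmin(1, pmax(-1, v)), c(P, P, P))
    }
  })
  patch$transforms <- c(patch$transforms, sprintf("elastic:%d", seed))
  patch
}

#' Enumerate the online augmentation transform space
#'
#' @param translate_vox translation step (default 2).
#' @return Data frame of all 108 (flip, shift) combinations: 4 flips (none,
#'   X, Y, Z) times 27 per-axis translations.
#' @export
online_transform_space <- function(translate_vox = 2L) {
  t <- c(-translate_vox, 0L, translate_vox)
  g <- expand.grid(flip = c("none", "x", "y", "z"), tx = t, ty = t, tz = t,
                   stringsAsFactors = FALSE)
  g[order(match(g$flip, c("none", "x", "y", "z")), g$tx, g$ty, g$tz), ,
    drop = FALSE]
}

flip_3d <- function(v, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(v)[axis]))
  do.call(`[`, c(list(v), idx, list(drop = FALSE)))
}

shift_3d <- function(v, by) {
  d <- dim(v)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- by[a]
    if (abs(s) >= d[a]) return(out)
    src[[a]] <- if (s >= 0) 1:(d[a] - s) else (1 - s):d[a]
    dst[[a]] <- if (s >= 0) (1 + s):d[a] else 1:(d[a] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}

#' Apply one online augmentation draw
#'
#' Uniformly samples a flip (none/X/Y/Z), then a translation of -step, 0 or
#' +step voxels per axis (a 4 x 27 = 108-element transform space); the flip
#' is applied first, translation zero-fills vacated voxels.
#'
#' @param patch a \code{lesion_patch}.
#' @param config an \code{augment_config}.
#' @param seed optional seed; if NULL the current RNG stream is used (the
#'   training loop draws from its own seeded stream).
#' @return The transformed patch with a transform tag.
#' @export
online_augment <- function(patch, config = augment_config(), seed = NULL) {
  draw <- function() {
    flip_ax <- sample.int(4L, 1L) - 1L  # 0 = none
    shift <- sample(c(-config$translate_vox, 0L, config$translate_vox), 3L,
                    replace = TRUE)
    list(flip = flip_ax, shift = shift)
  }
  tr <- if (is.null(seed)) draw() else with_seed(seed, draw())
  for (m in seq_len(dim(patch$data)[4])) {
    v <- patch$data[, , , m]
    if (tr$flip > 0L) v <- flip_3d(v, tr$flip)
    if (any(tr$shift != 0L)) v <- shift_3d(v, tr$shift)
    patch$data[, , , m] <- v
  }
  patch$transforms <- c(patch$transforms,
                        sprintf("online:flip%d_t%+d%+d%+d", tr$flip,
                                tr$shift[1], tr$shift[2], tr$shift[3]))
  patch
}

#' Offline augmentation of a training set
#'
#' Applies the tenfold rotation scheme to every rim+ patch, then (optionally)
#' adds \code{n_elastic} elastically deformed copies of every patch of both
#' classes. Only training patches should be augmented; evaluation uses
#' originals.
#'
#' @param patches list of labelled \code{lesion_patch}.
#' @param config an \code{augment_config}.
#' @param elastic apply the elastic stage (default TRUE when
#'   \code{config$n_elastic > 0}).
#' @param seed base seed for the elastic fields.
#' @return The augmented patch list.
#' @export
offline_augment <- function(patches, config = augment_config(),
                            elastic = config$n_elastic > 0L, seed = 1L) {
  out <- list()
  for (p in patches) {
    if (identical(p$label, "rim+")) {
      out <- c(out, offline_rotations(p))
    } else {
      out <- c(out, list(p))
    }
  }
  if (elastic && config$n_elastic > 0L) {
    n0 <- length(out)
    extra <- vector("list", n0 * config$n_elastic)
    k <- 1L
    for (i in seq_len(n0)) {
      for (j in seq_len(config$n_elastic)) {
        extra[[k]] <- elastic_deform(out[[i]], config,
                                     seed = derive_seed(seed, paste0(i, "_", j)))
        k <- k + 1L
      }
    }
    out <- c(out, extra)
  }
  out
}
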