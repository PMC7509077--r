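`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed is fanned out deterministically to per-stage seeds
#' so that stages can be rerun in isolation while remaining reproducible.
#' Seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483629) + 1L
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# round half up (R's round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

stopifnot_binary <- function(mask, name = "mask") {
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1, NA, TRUE, FALSE)))
    stop(sprintf("%s must be binary (0/1)", name), call. = FALSE)
}

# offsets of a Euclidean ball of given voxel radius, as integer matrix
ball_offsets <- function(radius_vox) {
  r <- as.integer(radius_vox)
  if (r <= 0L) return(matrix(0L, 1, 3))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius_vox^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Dilate a binary 3D mask with a spherical structuring element
#'
#' @param mask logical/0-1 3D array.
#' @param radius_mm dilation radius in millimetres.
#' @param spacing_mm isotropic voxel size in millimetres.
#' @return A logical array of the same dimensions.
#' @export
dilate_ball <- function(mask, radius_mm, spacing_mm) {
  stopifnot(length(dim(mask)) == 3L)
  r_vox <- round_half_up(radius_mm / spacing_mm)
  out <- dilate_offsets_cpp(as.logical(mask), as.integer(dim(mask)),
                            ball_offsets(r_vox))
  array(out, dim(mask))
}
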