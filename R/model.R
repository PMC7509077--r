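#' Architecture configuration for the lesion classification networks
#'
#' The networks are VGG-style 3D CNNs: each modality branch is a succession of
#' three blocks of two 3x3x3 'same' convolutions (batch normalization and a
#' tanh activation after each convolution) followed by 2x2x2 max-pooling.
#' The bimodal network fuses the two branches twice: the secondary branch's
#' first-block output is channel-concatenated onto the main branch's
#' first-block output (early fusion), and both branches' final feature blocks
#' are flattened and concatenated before the fully-connected cascade (late
#' fusion) ending in a 2-way softmax.
#'
#' @param modalities 1 (unimodal baseline) or 2 (bimodal, ordered main then
#'   secondary).
#' @param patch_size cubic patch edge length in voxels (default 28).
#' @param filters integer vector of length 3: convolution filters per block.
#' @param fc integer vector of length 2: widths of the fully-connected layers.
#' @param n_classes number of output classes (2: rim-, rim+).
#' @return An object of class \code{prl_arch}.
#' @export
arch_config <- function(modalities = 2L, patch_size = 28L,
                        filters = c(32L, 64L, 128L), fc = c(256L, 64L),
                        n_classes = 2L) {
  modalities <- as.integer(modalities)
  patch_size <- as.integer(patch_size)
  filters <- as.integer(filters)
  fc <- as.integer(fc)
  if (!modalities %in% c(1L, 2L)) stop("modalities must be 1 or 2")
  if (length(filters) != 3L || any(filters < 1L))
    stop("filters must be three positive integers (one per block)")
  if (length(fc) != 2L || any(fc < 1L))
    stop("fc must be two positive integers")
  if (n_classes != 2L) stop("only 2-class output is supported")
  if (patch_size %/% 8L < 1L)
    stop("patch_size must allow three pooling stages (>= 8)")
  structure(list(modalities = modalities, patch_size = patch_size,
                 filters = filters, fc = fc, n_classes = as.integer(n_classes),
                 blocks_per_branch = 3L, convs_per_block = 2L,
                 kernel = 3L, pool = 2L, activation = "tanh",
                 batch_norm = TRUE),
            class = "prl_arch")
}

# spatial edge length per block and after the final pool
net_dims <- function(patch_size) {
  d0 <- patch_size
  d1 <- d0 %/% 2L
  d2 <- d1 %/% 2L
  d3 <- d2 %/% 2L
  list(block = c(d0, d1, d2), final = d3)
}

conv_channels <- function(arch, branch, layer) {
  f <- arch$filters
  fuse <- arch$modalities > 1L
  cin <- switch(layer,
                1L,
                f[1],
                if (branch == 1L && fuse) 2L * f[1] else f[1],
                f[2], f[2], f[3])
  cout <- f[c(1, 1, 2, 2, 3, 3)][layer]
  c(cin = cin, cout = cout)
}

#' Build the bimodal early/late-fusion network specification
#'
#' @param arch a \code{prl_arch} with \code{modalities = 2}. The first
#'   modality is the main branch (phase in the reference configuration), the
#'   second the secondary branch (FLAIR or T2*-magnitude).
#' @return A \code{prl_net_spec}: the complete, serializable description of
#'   the network (layer shapes, fusion points, parameter dimensions).
#' @export
build_bimodal_net <- function(arch) {
  if (!inherits(arch, "prl_arch")) stop("arch must come from arch_config()")
  if (arch$modalities != 2L) stop("bimodal network requires modalities = 2")
  new_net_spec(arch)
}

#' Build the unimodal baseline network specification
#'
#' A single CNN branch connected directly to the fully-connected cascade.
#'
#' @param arch a \code{prl_arch} with \code{modalities = 1}.
#' @return A \code{prl_net_spec}.
#' @export
build_unimodal_net <- function(arch) {
  if (!inherits(arch, "prl_arch")) stop("arch must come from arch_config()")
  if (arch$modalities != 1L) stop("unimodal network requires modalities = 1")
  new_net_spec(arch)
}

new_net_spec <- function(arch) {
  dims <- net_dims(arch$patch_size)
  if (dims$final < 1L) stop("patch_size too small for three pooling stages")
  shapes <- param_shapes(arch)
  structure(list(n_mod = arch$modalities, patch_size = arch$patch_size,
                 filters = arch$filters, fc = arch$fc,
                 n_classes = arch$n_classes,
                 spatial_trace = c(dims$block, dims$final),
                 feature_dim = arch$modalities * dims$final^3 * arch$filters[3],
                 param_shapes = shapes,
                 n_params = sum(vapply(shapes, prod, numeric(1)))),
            class = "prl_net_spec")
}

param_shapes <- function(arch) {
  dims <- net_dims(arch$patch_size)
  shapes <- list()
  for (m in seq_len(arch$modalities)) {
    for (l in 1:6) {
      ch <- conv_channels(arch, m, l)
      base <- sprintf("b%d_c%d", m, l)
      shapes[[paste0(base, "_W")]] <- c(27L * ch[["cin"]], ch[["cout"]])
      shapes[[paste0(base, "_bn_g")]] <- ch[["cout"]]
      shapes[[paste0(base, "_bn_b")]] <- ch[["cout"]]
    }
  }
  D <- arch$modalities * dims$final^3 * arch$filters[3]
  shapes$fc1_W <- c(D, arch$fc[1]); shapes$fc1_b <- arch$fc[1]
  shapes$fc2_W <- c(arch$fc[1], arch$fc[2]); shapes$fc2_b <- arch$fc[2]
  shapes$out_W <- c(arch$fc[2], arch$n_classes); shapes$out_b <- arch$n_classes
  shapes
}

#' @export
print.prl_net_spec <- function(x, ...) {
  kind <- if (x$n_mod == 2L) "bimodal (early + late fusion)" else "unimodal"
  cat(sprintf("3D CNN specification: %s\n", kind))
  cat(sprintf("  patch %d^3, filters %s, fc %s\n", x$patch_size,
              paste(x$filters, collapse = "/"), paste(x$fc, collapse = "/")))
  cat(sprintf("  spatial trace %s, %d parameters\n",
              paste(x$spatial_trace, collapse = " -> "), x$n_params))
  invisible(x)
}

#' Initialize network parameters (Xavier uniform)
#'
#' Weights are drawn from the Xavier/Glorot uniform distribution; batch-norm
#' scale is 1, all shifts/biases 0, running statistics (mean 0, variance 1).
#'
#' @param net a \code{prl_net_spec}.
#' @param seed integer RNG seed.
#' @return A \code{prl_model}: parameters, batch-norm state and the spec.
#' @export
init_network <- function(net, seed = 1L) {
  stopifnot(inherits(net, "prl_net_spec"))
  params <- list()
  running <- list()
  with_seed(seed, {
    for (nm in names(net$param_shapes)) {
      shp <- net$param_shapes[[nm]]
      if (grepl("_W$", nm)) {
        lim <- sqrt(6 / (shp[1] + shp[2]))
        params[[nm]] <- matrix(runif(prod(shp), -lim, lim), shp[1], shp[2])
      } else if (grepl("_bn_g$", nm)) {
        params[[nm]] <- rep(1, shp)
      } else {
        params[[nm]] <- rep(0, shp)
      }
    }
  })
  for (m in seq_len(net$n_mod)) {
    for (l in 1:6) {
      co <- net$param_shapes[[sprintf("b%d_c%d_bn_g", m, l)]]
      running[[sprintf("b%d_c%d_rm", m, l)]] <- rep(0, co)
      running[[sprintf("b%d_c%d_rv", m, l)]] <- rep(1, co)
    }
  }
  structure(list(spec = net, params = params, running = running),
            class = "prl_model")
}

cpp_spec <- function(net) {
  list(n_mod = net$n_mod, patch_size = net$patch_size,
       filters = as.integer(net$filters), fc = as.integer(net$fc),
       n_classes = net$n_classes)
}

# x: array (P, P, P, n_mod, N) or (P, P, P, n_mod) for a single input
as_input_array <- function(x, net) {
  d <- dim(x)
  P <- net$patch_size
  if (length(d) == 4L) d <- c(d, 1L)
  if (length(d) != 5L || !all(d[1:3] == P) || d[4] != net$n_mod)
    stop(sprintf("input must be a %d^3 x %d (x N) array", P, net$n_mod))
  list(x = as.double(x), n = d[5])
}

#' Predict rim+ probabilities with a trained model
#'
#' @param model a \code{prl_model}.
#' @param x input array of dimension (P, P, P, modalities, N) or a list of
#'   patches from \code{extract_patch}.
#' @param batch_size evaluation batch size.
#' @return Numeric vector of per-input rim+ probabilities (class 2 softmax).
#' @export
predict_proba <- function(model, x, batch_size = 32L) {
  stopifnot(inherits(model, "prl_model"))
  if (is.list(x) && !is.array(x)) x <- patches_to_array(x, model$spec$n_mod)
  inp <- as_input_array(x, model$spec)
  P <- model$spec$patch_size
  per <- P^3 * model$spec$n_mod
  out <- numeric(inp$n)
  i <- 1L
  while (i <= inp$n) {
    j <- min(i + batch_size - 1L, inp$n)
    xb <- inp$x[((i - 1) * per + 1):(j * per)]
    res <- cnn_batch_cpp(cpp_spec(model$spec), model$params, model$running,
                         xb, integer(0), FALSE, FALSE, 0.1, 1e-5)
    out[i:j] <- res$probs[, 2]
    i <- j + 1L
  }
  out
}

#' Number of trainable parameters of a network specification
#' @param net a \code{prl_net_spec}.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) net$n_params

arch_fingerprint <- function(net) {
  paste(net$n_mod, net$patch_size, paste(net$filters, collapse = "."),
        paste(net$fc, collapse = "."), net$n_classes, sep = "-")
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files carrying the parameters, batch-norm state and
#' an architecture fingerprint that is verified on load.
#'
#' @param model a \code{prl_model}.
#' @param path checkpoint path (.rds).
#' @return \code{save_model}: the path, invisibly. \code{load_model}: the
#'   restored \code{prl_model}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "prl_model"))
  obj <- unclass(model)
  obj$fingerprint <- arch_fingerprint(model$spec)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$fingerprint, arch_fingerprint(obj$spec)))
    stop("checkpoint fingerprint does not match its architecture")
  obj$fingerprint <- NULL
  class(obj) <- "prl_model"
  obj
}
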