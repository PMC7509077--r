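reduced_arch <- function(modalities = 2L, P = 8L)
  arch_config(modalities = modalities, patch_size = P,
              filters = c(2L, 3L, 4L), fc = c(10L, 5L))

test_that("spatial shape propagation follows same-conv + stride-2 pooling", {
  net <- build_bimodal_net(arch_config())
  expect_equal(net$spatial_trace, c(28, 14, 7, 3))
  expect_equal(net$feature_dim, 2 * 27 * 128)
  net16 <- build_bimodal_net(arch_config(patch_size = 16L,
                                         filters = c(8L, 16L, 32L),
                                         fc = c(64L, 16L)))
  expect_equal(net16$spatial_trace, c(16, 8, 4, 2))
})

test_that("early fusion doubles the main branch's block-2 input channels", {
  net <- build_bimodal_net(arch_config())
  expect_equal(net$param_shapes$b1_c3_W, c(27 * 64, 64))  # 32+32 fused
  expect_equal(net$param_shapes$b2_c3_W, c(27 * 32, 64))  # secondary unfused
  uni <- build_unimodal_net(arch_config(modalities = 1L))
  expect_equal(uni$param_shapes$b1_c3_W, c(27 * 32, 64))
})

test_that("softmax outputs are probabilities summing to one", {
  net <- build_bimodal_net(reduced_arch())
  mod <- init_network(net, 2L)
  set.seed(1)
  x <- array(rnorm(8^3 * 2 * 4), c(8, 8, 8, 2, 4))
  p <- predict_proba(mod, x)
  expect_length(p, 4)
  expect_true(all(p >= 0 & p <= 1))
  r <- prlnet:::cnn_batch_cpp(prlnet:::cpp_spec(net), mod$params, mod$running,
                              as.double(x), integer(0), FALSE, FALSE, 0.1, 1e-5)
  expect_equal(rowSums(r$probs), rep(1, 4), tolerance = 1e-6)
})

test_that("zero input under Xavier initialization gives 0.5/0.5", {
  for (m in c(1L, 2L)) {
    net <- if (m == 2L) build_bimodal_net(reduced_arch(2L)) else
      build_unimodal_net(reduced_arch(1L))
    mod <- init_network(net, 7L)
    p <- predict_proba(mod, array(0, c(8, 8, 8, m, 1)))
    expect_equal(p, 0.5, tolerance = 1e-6)
  }
})

test_that("the unimodal baseline is a strict sub-network in parameters", {
  bi <- build_bimodal_net(arch_config())
  uni <- build_unimodal_net(arch_config(modalities = 1L))
  expect_lt(n_parameters(uni), n_parameters(bi))
})

test_that("analytic gradients match central finite differences", {
  net <- build_bimodal_net(reduced_arch())
  mod <- init_network(net, 42L)
  set.seed(1)
  B <- 3
  x <- as.double(array(rnorm(8^3 * 2 * B), c(8, 8, 8, 2, B)))
  y <- c(0L, 1L, 1L)
  spec <- prlnet:::cpp_spec(net)
  r <- prlnet:::cnn_batch_cpp(spec, mod$params, mod$running, x, y,
                              TRUE, TRUE, 0.1, 1e-5)
  lossfn <- function(p) prlnet:::cnn_batch_cpp(spec, p, mod$running, x, y,
                                               TRUE, FALSE, 0.1, 1e-5)$loss
  eps <- 1e-3
  set.seed(2)
  worst <- 0
  for (nm in names(mod$params)) {
    n <- length(mod$params[[nm]])
    for (idx in sample(n, min(2, n))) {
      p2 <- mod$params; p2[[nm]][idx] <- p2[[nm]][idx] + eps
      p3 <- mod$params; p3[[nm]][idx] <- p3[[nm]][idx] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      ana <- r$grads[[nm]][idx]
      # absolute comparison: single precision floors the attainable accuracy
      worst <- max(worst, abs(num - ana))
    }
  }
  expect_lt(worst, 5e-3)
})

test_that("network specifications round-trip through YAML bit-exactly", {
  net <- build_bimodal_net(arch_config(patch_size = 16L,
                                       filters = c(8L, 16L, 32L),
                                       fc = c(64L, 16L)))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(net)[c("n_mod", "patch_size", "filters", "fc",
                                  "n_classes")], path)
  back <- yaml::read_yaml(path)
  rebuilt <- build_bimodal_net(arch_config(
    modalities = back$n_mod, patch_size = back$patch_size,
    filters = back$filters, fc = back$fc))
  expect_identical(unclass(rebuilt), unclass(net))
})

test_that("checkpoints round-trip with a verified fingerprint", {
  net <- build_bimodal_net(reduced_arch())
  mod <- init_network(net, 3L)
  path <- tempfile(fileext = ".rds")
  save_model(mod, path)
  back <- load_model(path)
  expect_identical(back$params, mod$params)
  set.seed(1)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2, 1))
  expect_identical(predict_proba(back, x), predict_proba(mod, x))
  # tampering with the stored architecture is caught
  obj <- readRDS(path)
  obj$spec$filters <- c(9L, 9L, 9L)
  saveRDS(obj, path)
  expect_error(load_model(path), "fingerprint")
  unlink(path)
})

test_that("configuration invariants are enforced", {
  expect_error(arch_config(modalities = 3L), "1 or 2")
  expect_error(arch_config(patch_size = 4L), "pooling")
  expect_error(build_bimodal_net(arch_config(modalities = 1L)), "modalities = 2")
  expect_error(build_unimodal_net(arch_config(modalities = 2L)), "modalities = 1")
  net <- build_bimodal_net(reduced_arch())
  mod <- init_network(net, 1L)
  expect_error(predict_proba(mod, array(0, c(4, 4, 4, 2, 1))), "array")
})
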