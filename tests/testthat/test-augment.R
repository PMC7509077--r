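marker_patch <- function(P = 6L, n_mod = 1L) {
  # a patch with a unique corner marker so every orientation is distinct
  d <- array(0, c(P, P, P, n_mod))
  d[1, 1, 1, ] <- 1
  d[2, 1, 1, ] <- 0.5
  d[1, 2, 1, ] <- 0.25
  structure(list(data = d, label = "rim+", candidate_id = 1L,
                 patient_id = "P", site_id = "S", transforms = character(0)),
            class = "lesion_patch")
}

test_that("offline rotations return exactly ten pairwise-distinct outputs", {
  p <- marker_patch()
  out <- offline_rotations(p)
  expect_length(out, 10)
  tags <- vapply(out, function(q) utils::tail(q$transforms, 1), "")
  expect_equal(anyDuplicated(tags), 0L)
  # enumerate arrays: all 10 must differ pairwise on an asymmetric patch
  flat <- vapply(out, function(q) paste(as.vector(q$data), collapse = ","), "")
  expect_equal(anyDuplicated(flat), 0L)
})

test_that("rotations preserve content on a constant patch", {
  p <- marker_patch()
  p$data[] <- 0.3
  out <- offline_rotations(p)
  expect_length(out, 10)
  for (q in out) expect_equal(q$data, p$data)
  tags <- vapply(out, function(q) utils::tail(q$transforms, 1), "")
  expect_equal(anyDuplicated(tags), 0L)
})

test_that("rotations are cyclic of order four and need a cubic patch", {
  p <- marker_patch()
  r <- p$data[, , , 1]
  for (axis in 1:3) {
    r4 <- prlnet:::rotate90_3d(r, axis, 4L)
    expect_equal(r4, r)
    r2 <- prlnet:::rotate90_3d(prlnet:::rotate90_3d(r, axis, 1L), axis, 1L)
    expect_equal(r2, prlnet:::rotate90_3d(r, axis, 2L))
  }
  bad <- p
  bad$data <- array(0, c(4, 4, 6, 1))
  expect_error(offline_rotations(bad), "cubic")
})

test_that("elastic deformation: identity at amplitude 0, deterministic, bounded", {
  p <- marker_patch(P = 10L)
  cfg0 <- augment_config(elastic_amplitude = 0, patch_size = 10L)
  expect_equal(elastic_deform(p, cfg0, seed = 4L)$data, p$data)

  cfg <- augment_config(elastic_amplitude = 1.5, patch_size = 10L)
  a <- elastic_deform(p, cfg, seed = 9L)
  b <- elastic_deform(p, cfg, seed = 9L)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, p$data))
  expect_true(all(a$data >= -1 & a$data <= 1))

  # the generated displacement field never exceeds the amplitude
  for (amp in c(0.5, 2)) {
    f <- prlnet:::with_seed(5L, prlnet:::elastic_field(10L, 4L, amp))
    expect_lte(max(sqrt(rowSums(f^2))), amp + 1e-12)
  }
})

test_that("the online transform space has 4 x 27 = 108 distinct elements", {
  sp <- online_transform_space(2L)
  expect_equal(nrow(sp), 108L)
  expect_equal(anyDuplicated(sp), 0L)
  expect_setequal(unique(sp$flip), c("none", "x", "y", "z"))
})

test_that("online draws are uniform over the transform space", {
  p <- marker_patch(P = 8L)
  cfg <- augment_config(translate_vox = 2L, patch_size = 8L)
  n <- 10000L
  tags <- prlnet:::with_seed(77L, vapply(seq_len(n), function(i) {
    utils::tail(online_augment(p, cfg)$transforms, 1)
  }, ""))
  counts <- table(tags)
  expect_equal(length(counts), 108L)
  # each frequency within 5 SD of n/108
  expected <- n / 108
  sd5 <- 5 * sqrt(n * (1 / 108) * (1 - 1 / 108))
  expect_true(all(abs(counts - expected) <= sd5))
})

test_that("identity online draw leaves the patch unchanged; shifts zero-fill", {
  p <- marker_patch(P = 8L)
  cfg <- augment_config(translate_vox = 2L, patch_size = 8L)
  # find a seed that samples (none, 0, 0, 0)
  ident <- NULL
  for (s in 1:300) {
    q <- online_augment(p, cfg, seed = s)
    if (utils::tail(q$transforms, 1) == "online:flip0_t+0+0+0") {
      ident <- q
      break
    }
  }
  expect_false(is.null(ident))
  expect_equal(ident$data, p$data)

  shifted <- prlnet:::shift_3d(p$data[, , , 1], c(2L, 0L, 0L))
  expect_equal(shifted[1:2, , ], array(0, c(2, 8, 8)))
  expect_equal(shifted[3:8, , ], p$data[1:6, , , 1])
})

test_that("augmentation preserves shape and the [-1, 1] range", {
  set.seed(10)
  p <- marker_patch(P = 8L)
  p$data <- array(runif(8^3, -1, 1), c(8, 8, 8, 1))
  cfg <- augment_config(elastic_amplitude = 2, patch_size = 8L)
  for (q in c(offline_rotations(p),
              list(elastic_deform(p, cfg, 3L), online_augment(p, cfg, 5L)))) {
    expect_equal(dim(q$data), dim(p$data))
    expect_true(all(q$data >= -1 & q$data <= 1))
  }
})

test_that("offline augmentation yields the documented class ratio", {
  # tenfold rim+ increase: with n-/n+ inputs the ratio becomes n- : 10 n+
  ps <- c(lapply(1:8, function(i) { p <- marker_patch(); p$label <- "rim-"; p }),
          lapply(1:2, function(i) marker_patch()))
  out <- offline_augment(ps, augment_config(n_elastic = 0L, translate_vox = 1L,
                                            patch_size = 6L))
  labs <- vapply(out, `[[`, "", "label")
  expect_equal(sum(labs == "rim-"), 8)
  expect_equal(sum(labs == "rim+"), 20)
  # elastic stage quadruples everything
  out2 <- offline_augment(ps, augment_config(n_elastic = 3L,
                                             elastic_amplitude = 1,
                                             translate_vox = 1L,
                                             patch_size = 6L))
  expect_length(out2, 4 * length(out))
})
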