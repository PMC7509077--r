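test_that("empty and diagonal masks follow 6-connectivity", {
  m <- array(FALSE, c(8, 8, 8))
  expect_length(extract_components(m, 1), 0)

  # two voxels sharing only an edge are two components under 6-connectivity
  m[2, 2, 2] <- TRUE
  m[3, 3, 2] <- TRUE
  expect_length(extract_components(m, 1), 2)

  # face-adjacent voxels are one component
  m2 <- array(FALSE, c(8, 8, 8))
  m2[2, 2, 2] <- TRUE
  m2[3, 2, 2] <- TRUE
  expect_length(extract_components(m2, 1), 1)
})

test_that("component extraction matches a BFS flood-fill oracle", {
  set.seed(42)
  for (rep in 1:3) {
    m <- array(runif(32^3) < 0.1, c(32, 32, 32))
    cands <- extract_components(m, 0.65)
    oracle <- flood_fill_components(m, offsets_6)
    expect_equal(length(cands), max(oracle))
    # identical partition: each candidate's voxels carry one oracle label
    for (cc in cands[seq_len(min(10, length(cands)))]) {
      expect_length(unique(oracle[cc$voxels]), 1L)
      expect_equal(cc$voxel_count, sum(oracle == oracle[cc$voxels[1]]))
    }
  }
})

test_that("non-binary masks are rejected and volumes follow spacing", {
  expect_error(extract_components(array(2, c(4, 4, 4)), 1), "binary")
  m <- array(FALSE, c(8, 8, 8))
  m[1:3, 1, 1] <- TRUE
  cc <- extract_components(m, 0.65)[[1]]
  expect_equal(cc$volume_mm3, 3 * 0.65^3)
  expect_equal(cc$center_of_mass, c(1, 0, 0))  # 0-based
})

test_that("labelling follows the any-overlap rule", {
  ph <- small_phantom()
  cands <- extract_components(ph$lesion_mask != 0, ph$spacing_mm)
  # empty rim+ map: everything rim-
  all_neg <- label_candidates(cands, array(FALSE, dim(ph$lesion_mask)))
  expect_true(all(vapply(all_neg, `[[`, "", "label") == "rim-"))

  # single overlapping voxel is enough for rim+
  one <- array(FALSE, dim(ph$lesion_mask))
  one[cands[[1]]$voxels[1]] <- TRUE
  lab1 <- label_candidates(cands, one)
  expect_equal(lab1[[1]]$label, "rim+")
  expect_true(all(vapply(lab1[-1], `[[`, "", "label") == "rim-"))

  expect_error(label_candidates(cands, array(FALSE, c(4, 4, 4))), "grid")
})

test_that("phantom labels agree with the ground-truth table", {
  ph <- generate_phantom(phantom_config(n_rim_pos = 5L, n_rim_neg = 20L,
                                        seed = 31L))
  cands <- labelled_candidates(ph)
  expect_equal(length(cands), nrow(ph$truth))
  # match components to truth rows via any shared voxel
  for (cc in cands) {
    truth_id <- ph$lesion_mask[cc$voxels[1]]
    expect_equal(cc$label, ph$truth$class[ph$truth$id == truth_id])
  }
})

test_that("volume threshold arithmetic matches 0.65 mm voxels", {
  # 44 voxels -> 12.08 mm^3 (excluded); 45 voxels -> 12.36 mm^3 (kept)
  m <- array(FALSE, c(70, 16, 16))
  m[1:44, 2, 2] <- TRUE
  m[1:45, 2, 6] <- TRUE
  cands <- label_candidates(extract_components(m, 0.65),
                            array(FALSE, dim(m)))
  res <- apply_exclusions(cands, config = exclusion_config(), patch_size = 4L)
  reasons <- vapply(res$excluded, `[[`, "", "exclusion_reason")
  expect_equal(vapply(res$excluded, `[[`, 0, "voxel_count"), 44)
  expect_equal(reasons, "too_small")
  expect_equal(vapply(res$kept, `[[`, 0, "voxel_count"), 45)
  expect_equal(res$excluded[[1]]$volume_mm3, 44 * 0.65^3, tolerance = 1e-12)
})

test_that("a no-op configuration keeps every candidate", {
  ph <- small_phantom()
  cands <- labelled_candidates(ph)
  res <- apply_exclusions(cands, ph$rim_pos_mask, NULL,
                          exclusion_config(min_volume_mm3 = 0,
                                           max_voxels = Inf),
                          patch_size = 16L)
  expect_length(res$excluded, 0)
  expect_length(res$kept, length(cands))
})

test_that("kept and excluded partition the input and size rule is monotone", {
  ph <- small_phantom()
  cands <- labelled_candidates(ph)
  res <- apply_exclusions(cands, ph$rim_pos_mask, ph$artefact_mask,
                          exclusion_config(), patch_size = 16L)
  ids <- sort(c(vapply(res$kept, `[[`, 0L, "id"),
                vapply(res$excluded, `[[`, 0L, "id")))
  expect_equal(ids, vapply(cands, `[[`, 0L, "id"))

  # raising the volume threshold never un-excludes
  for (thr in c(20, 50, 100)) {
    res2 <- apply_exclusions(cands, ph$rim_pos_mask, ph$artefact_mask,
                             exclusion_config(min_volume_mm3 = thr),
                             patch_size = 16L)
    excl1 <- vapply(res$excluded, `[[`, 0L, "id")
    excl2 <- vapply(res2$excluded, `[[`, 0L, "id")
    expect_true(all(excl1 %in% excl2))
    res <- res2
  }
})

test_that("well-separated rim+ lesions cause no contamination exclusions", {
  ph <- generate_phantom(phantom_config(n_rim_pos = 3L, n_rim_neg = 6L,
                                        confluence_probability = 0,
                                        seed = 17L))
  cands <- labelled_candidates(ph)
  res <- apply_exclusions(cands, ph$rim_pos_mask, NULL, exclusion_config(),
                          patch_size = 8L)
  expect_false(any(vapply(res$excluded, `[[`, "", "exclusion_reason") ==
                     "rim_contaminated"))
})
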