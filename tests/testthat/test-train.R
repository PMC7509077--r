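test_that("scheduler follows the hand-simulated decay trace", {
  # minimum at epoch 2, then three non-decreasing epochs: decay at epoch 5
  s <- lr_scheduler(c(1e-4, 5e-5, 2.5e-5, 1e-5), patience = 3L)
  for (loss in c(1.0, 0.9, 0.9, 0.9)) s <- scheduler_step(s, loss)
  expect_equal(s$rate_index, 1L)
  s <- scheduler_step(s, 0.9)
  expect_equal(s$decay_epochs, 5L)
  expect_equal(s$rate, 5e-5)
  expect_false(s$stopped)
})

test_that("a never-improving loss stops after rates x patience epochs", {
  s <- lr_scheduler(c(1e-4, 5e-5, 2.5e-5, 1e-5), patience = 3L,
                    baseline = 0.5)
  epochs <- 0L
  while (!s$stopped) {
    s <- scheduler_step(s, 0.6)  # never below the baseline
    epochs <- epochs + 1L
  }
  expect_equal(epochs, 4L * 3L)
  expect_equal(s$decay_epochs, c(3L, 6L, 9L, 12L))
})

test_that("an improving loss keeps the first rate alive", {
  s <- lr_scheduler(c(1e-3, 1e-4), patience = 2L)
  for (loss in seq(1, 0.1, by = -0.1)) s <- scheduler_step(s, loss)
  expect_equal(s$rate_index, 1L)
  expect_false(s$stopped)
})

test_that("fold assignment is patient-grouped, site-stratified and balanced", {
  # 4 patients, one per fold
  p4 <- data.frame(patient_id = paste0("P", 1:4), site_id = "A",
                   n_rim_pos = 1L, n_rim_neg = 5L)
  f <- make_folds(p4, 4L, seed = 1L)
  expect_setequal(f$fold, 1:4)

  # 8 patients with one rim+ each: every fold gets exactly two
  p8 <- data.frame(patient_id = paste0("P", 1:8), site_id = "A",
                   n_rim_pos = 1L, n_rim_neg = 3L)
  f8 <- make_folds(p8, 4L, seed = 2L)
  loads <- tapply(rep(1L, 8), f8$fold, sum)
  expect_true(all(loads == 2L))

  expect_error(make_folds(p4, 8L), "fewer patients")
})

test_that("greedy fold balancing is near the exhaustive optimum", {
  # small instances solvable by enumeration
  set.seed(5)
  for (rep in 1:3) {
    n <- 8L
    pts <- data.frame(patient_id = sprintf("P%02d", 1:n), site_id = "A",
                      n_rim_pos = rpois(n, 3), n_rim_neg = rpois(n, 10))
    f <- make_folds(pts, 4L, seed = rep)
    m <- merge(f, pts)
    spread_greedy <- diff(range(tapply(m$n_rim_pos, m$fold, sum)))
    # exhaustive search over all 4^8 assignments
    grid <- as.matrix(expand.grid(rep(list(1:4), n)))
    pos <- pts$n_rim_pos
    S <- sapply(1:4, function(k) (grid == k) %*% pos)
    nonempty <- sapply(1:4, function(k) rowSums(grid == k) > 0)
    ok <- rowSums(nonempty) == 4L
    spread_best <- min(apply(S[ok, , drop = FALSE], 1, function(s)
      diff(range(s))))
    expect_lte(spread_greedy, spread_best + max(pos))
  }
})

test_that("training reduces loss and fits a separable synthetic task", {
  # strong-contrast phantom patches, no noise: linearly separable in effect
  coh <- phantom_cohort(n_patients = 6L, lesions_per_patient = 8,
                        rim_pos_fraction = 0.4, patch_size = 12L,
                        config_fn = function(np, nn, seed)
                          phantom_config(n_rim_pos = np, n_rim_neg = nn,
                                         n_artefacts = 0L, noise_sd = 0,
                                         bias_field_amplitude = 0,
                                         lesion_radius_range_mm = c(1.8, 3),
                                         seed = seed),
                        seed = 5L)
  net <- build_bimodal_net(arch_config(modalities = 2L, patch_size = 12L,
                                       filters = c(4L, 8L, 8L),
                                       fc = c(16L, 8L)))
  x <- patches_to_array(coh$patches, modalities = c(2L, 1L))
  y <- patch_labels(coh$patches)
  cfg <- train_config(learning_rates = 1e-3, epoch_budget = 12L,
                      online_augment = FALSE, batch_size = 8L)
  m <- train_model(x, y, net, cfg, seed = 2L)
  expect_lt(utils::tail(m$history$train_loss, 1), m$history$train_loss[1])
  acc <- mean((predict_proba(m, x) >= 0.5) == (y == 1))
  expect_gte(acc, 0.95)
})

test_that("single-class training data is rejected", {
  net <- build_unimodal_net(arch_config(modalities = 1L, patch_size = 8L,
                                        filters = c(2L, 2L, 2L), fc = c(4L, 2L)))
  x <- array(rnorm(8^3 * 4), c(8, 8, 8, 1, 4))
  expect_error(train_model(x, c(1L, 1L, 1L, 1L), net,
                           train_config(epoch_budget = c(1L, 0L, 0L, 0L))),
               "both classes")
})

test_that("training is deterministic given one seed", {
  set.seed(99)
  x <- array(rnorm(8^3 * 2 * 12), c(8, 8, 8, 2, 12))
  y <- rep(c(0L, 1L), 6)
  net <- build_bimodal_net(arch_config(modalities = 2L, patch_size = 8L,
                                       filters = c(2L, 3L, 4L), fc = c(8L, 4L)))
  cfg <- train_config(learning_rates = 1e-3, epoch_budget = 2L,
                      online_augment = TRUE, batch_size = 4L)
  m1 <- train_model(x, y, net, cfg, seed = 11L)
  m2 <- train_model(x, y, net, cfg, seed = 11L)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("inner cross-validation returns positive deterministic budgets", {
  coh <- phantom_cohort(n_patients = 6L, lesions_per_patient = 6,
                        rim_pos_fraction = 0.4, patch_size = 8L, seed = 9L)
  net <- build_bimodal_net(arch_config(modalities = 2L, patch_size = 8L,
                                       filters = c(2L, 3L, 4L), fc = c(8L, 4L)))
  x <- patches_to_array(coh$patches, modalities = c(2L, 1L))
  y <- patch_labels(coh$patches)
  groups <- vapply(coh$patches, `[[`, "", "patient_id")
  cfg <- train_config(learning_rates = c(1e-3, 5e-4), patience = 1L,
                      max_epochs = 4L, online_augment = FALSE,
                      inner_folds = 3L)
  b1 <- inner_cv_epochs(x, y, groups, net, cfg, seed = 3L)
  b2 <- inner_cv_epochs(x, y, groups, net, cfg, seed = 3L)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0L))
  expect_gte(b1[1], 1L)
  expect_length(b1, 2L)
})

test_that("ensembles average probabilities", {
  net <- build_unimodal_net(arch_config(modalities = 1L, patch_size = 8L,
                                        filters = c(2L, 2L, 2L), fc = c(4L, 2L)))
  m1 <- init_network(net, 1L)
  m2 <- init_network(net, 2L)
  set.seed(4)
  x <- array(rnorm(8^3 * 3), c(8, 8, 8, 1, 3))
  p1 <- predict_proba(m1, x)
  p2 <- predict_proba(m2, x)
  expect_equal(ensemble_predict(list(m1), x), p1)
  expect_equal(ensemble_predict(list(m1, m2), x), (p1 + p2) / 2)
  expect_equal(ensemble_predict(list(m1, m1, m1), x), p1)
  other <- init_network(build_unimodal_net(
    arch_config(modalities = 1L, patch_size = 8L, filters = c(3L, 3L, 3L),
                fc = c(4L, 2L))), 1L)
  expect_error(ensemble_predict(list(m1, other), x), "architecture")
})
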