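test_that("ROC AUC equals the brute-force pairwise estimate", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 60
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- rnorm(n) + labels  # informative with ties impossible
    expect_equal(auc_mw(scores, labels), auc_bruteforce(scores, labels))
    # discrete scores force ties
    sc2 <- sample(1:5, n, replace = TRUE)
    expect_equal(auc_mw(sc2, labels), auc_bruteforce(sc2, labels))
  }
})

test_that("fold averaging reports the mean of per-fold AUCs", {
  # two constructed folds with per-fold AUCs 0.95 and 0.5
  f1 <- list(scores = c(5.5, 10.5, rep(10.5, 8), 1:10),
             labels = rep(c(1, 0), each = 10))
  # fold 1: one positive beats 5/10 negatives, nine beat all: AUC = 95/100
  expect_equal(auc_bruteforce(f1$scores, f1$labels), 0.95)
  f2 <- list(scores = c(rep(0.5, 5), rep(10.5, 5), 1:10),
             labels = rep(c(1, 0), each = 10))
  # fold 2: five positives beat none, five beat all: AUC = 0.5
  expect_equal(auc_bruteforce(f2$scores, f2$labels), 0.5)
  avg <- averaged_curves(list(f1$scores, f2$scores),
                         list(f1$labels, f2$labels))
  expect_equal(avg$auc_roc, (0.95 + 0.5) / 2)
  expect_equal(avg$auc_roc_by_fold,
               c(auc_bruteforce(f1$scores, f1$labels),
                 auc_bruteforce(f2$scores, f2$labels)))
})

test_that("perfect separation gives mean AUC 1 and random scores ~0.5", {
  folds_s <- list()
  folds_l <- list()
  set.seed(1)
  for (f in 1:4) {
    l <- rep(c(0, 1), each = 25)
    folds_s[[f]] <- l * 2 + runif(50)
    folds_l[[f]] <- l
  }
  expect_equal(averaged_curves(folds_s, folds_l)$auc_roc, 1)

  # label-independent scores: AUC near 1/2 within 3 SE
  set.seed(2)
  n <- 400
  l <- rep(c(0, 1), each = n / 2)
  s <- rnorm(n)
  a <- auc_mw(s, l)
  se <- sqrt((n / 2 + 1) / (3 * (n / 2)^2))  # null MW variance approximation
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("single-class folds are rejected with the fold named", {
  expect_error(averaged_curves(list(1:4, 1:4), list(c(0, 1, 0, 1), rep(1, 4))),
               "fold 2")
})

test_that("DeLong agrees with pROC and is symmetric", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (rep in 1:4) {
    n <- 80
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    a <- rnorm(n) + 1.2 * labels
    b <- 0.6 * a + rnorm(n) + 0.5 * labels
    mine <- delong_test(a, b, labels)
    ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                          pROC::roc(labels, b, quiet = TRUE),
                          method = "delong")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$auc_a, as.numeric(pROC::auc(pROC::roc(labels, a,
                                                            quiet = TRUE))))
    swapped <- delong_test(b, a, labels)
    expect_equal(swapped$p_value, mine$p_value)
    expect_equal(swapped$auc_a - swapped$auc_b,
                 -(mine$auc_a - mine$auc_b))
  }
})

test_that("DeLong on identical scores returns p = 1", {
  labels <- rep(c(0, 1), each = 10)
  s <- rnorm(20)
  r <- delong_test(s, s, labels)
  expect_equal(r$p_value, 1)
  expect_equal(r$auc_a, r$auc_b)
  expect_error(delong_test(s[-1], s, labels), "paired")
})

test_that("DeLong AUC equals the scaled Mann-Whitney U statistic", {
  set.seed(3)
  labels <- rbinom(50, 1, 0.5)
  labels[1:2] <- c(0, 1)
  s <- sample(1:8, 50, replace = TRUE)
  r <- delong_test(s, rnorm(50), labels)
  expect_equal(r$auc_a, auc_bruteforce(s, labels))
})

test_that("McNemar matches the closed form and stats::mcnemar.test", {
  expect_equal(mcnemar_discordant(0, 0)$p_value, 1)
  r55 <- mcnemar_discordant(5, 5)
  expect_equal(r55$statistic, 0.1)
  expect_equal(r55$p_value, pchisq(0.1, 1, lower.tail = FALSE))
  r <- mcnemar_discordant(15, 3)
  expect_equal(r$statistic, 11^2 / 18)
  ref <- stats::mcnemar.test(matrix(c(10, 15, 3, 10), 2), correct = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_error(mcnemar_discordant(-1, 2), "non-negative")
})

test_that("operating point hits the target specificity", {
  # separable scores: any threshold in the gap, specificity 1
  s <- c(rep(0.1, 10), rep(0.9, 5))
  l <- rep(c(0, 1), c(10, 5))
  op <- operating_point(s, l, 0.95)
  expect_equal(op$specificity, 1)
  expect_equal(op$sensitivity, 1)

  # 20 negatives scored 1..20: threshold 20 gives specificity 0.95 exactly
  s2 <- c(1:20, 25, 30)
  l2 <- c(rep(0, 20), 1, 1)
  op2 <- operating_point(s2, l2, 0.95)
  expect_equal(op2$specificity, 0.95)
  expect_equal(op2$threshold, 20)

  # monotone in the target
  thr <- vapply(c(0.5, 0.8, 0.95, 0.99), function(t)
    operating_point(s2, l2, t)$threshold, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("confusion-matrix metrics follow their definitions", {
  m <- lesion_metrics(7, 3, 3, 87)
  expect_equal(m$sensitivity, 0.7)
  expect_equal(m$specificity, 87 / 90)
  expect_equal(m$ppv, 0.7)
  expect_equal(m$npv, 87 / 90)
  expect_equal(m$f1, 0.7)
  expect_equal(round(100 * m$specificity, 1), 96.7)

  perfect <- lesion_metrics(10, 0, 0, 90)
  expect_true(all(unlist(perfect) == 1))

  degen <- lesion_metrics(0, 0, 5, 95)
  expect_equal(degen$sensitivity, 0)
  expect_true(is.na(degen$ppv))
  expect_error(lesion_metrics(0, 0, 0, 0), "empty")
})

test_that("patient categorization is inclusive at the threshold and monotone", {
  pid <- rep(c("A", "B", "C"), c(3, 4, 5))
  probs <- c(rep(1, 3), rep(1, 4), rep(1, 5))
  labels <- rep(1, 12)
  r <- patient_categorize(pid, probs, labels, 0.5, 4L)
  df <- r$patients[order(r$patients$patient_id), ]
  expect_equal(df$pred_active, c(FALSE, TRUE, TRUE))  # counts 3, 4, 5

  # zero predicted rim+: never chronic active
  r0 <- patient_categorize(pid, rep(0, 12), labels, 0.5, 1L)
  expect_false(any(r0$patients$pred_active))

  # monotone: higher count threshold never yields more active patients
  set.seed(8)
  probs2 <- runif(12)
  labels2 <- rbinom(12, 1, 0.5)
  n_active <- vapply(1:6, function(k)
    sum(patient_categorize(pid, probs2, labels2, 0.5, k)$patients$pred_active),
    numeric(1))
  expect_true(all(diff(n_active) <= 0))

  # confusion equals a brute-force recount
  cm <- patient_categorize(pid, probs2, labels2, 0.5, 2L)$confusion
  pred_counts <- tapply(probs2 >= 0.5, pid, sum)
  true_counts <- tapply(labels2, pid, sum)
  expect_equal(cm$tp, sum(pred_counts >= 2 & true_counts >= 2))
  expect_equal(cm$tn, sum(pred_counts < 2 & true_counts < 2))
})

test_that("region assignment follows dilation radii and precedence", {
  dims <- c(40L, 40L, 40L)
  spacing <- 1
  region_masks <- list(ventricles = array(FALSE, dims),
                       cortex = array(FALSE, dims),
                       deep_gray = array(FALSE, dims))
  region_masks$ventricles[18:22, 18:22, 18:22] <- TRUE
  region_masks$cortex[1:3, , ] <- TRUE

  mk <- function(xr, yr, zr) {
    m <- array(FALSE, dims)
    m[xr, yr, zr] <- TRUE
    m
  }
  # lesion touching the 3 mm-dilated ventricle mask: periventricular;
  # a lesion far from everything: deep white matter
  m <- mk(24:26, 20, 20)  # nearest ventricle voxel at x=22: distance 2 <= 3
  cands <- c(extract_components(m, spacing),
             extract_components(mk(30:33, 30, 30), spacing))
  regs <- assign_regions(cands, region_masks, spacing)
  expect_equal(regs, c("periventricular", "deep_white_matter"))

  # >= half-overlap rule against an exhaustive voxel-count oracle
  cort_dil <- dilate_ball(region_masks$cortex, 2, spacing)
  for (x0 in 1:6) {
    m3 <- mk(x0:(x0 + 5), 10, 10)
    cc <- extract_components(m3, spacing)
    reg <- assign_regions(cc, region_masks, spacing)
    frac <- sum(cort_dil[cc[[1]]$voxels]) / cc[[1]]$voxel_count
    expect_equal(reg == "juxtacortical", frac >= 0.5)
  }

  # precedence: ventricle contact wins over cortex overlap
  both <- mk(2:4, 18:22, 18:22)
  region_masks2 <- region_masks
  region_masks2$ventricles <- mk(2:4, 18:22, 18:22)
  cc2 <- extract_components(both, spacing)
  expect_equal(assign_regions(cc2, region_masks2, spacing), "periventricular")
})

test_that("location reports give per-class percentages summing to 100", {
  regions <- c(rep("periventricular", 3), rep("deep_white_matter", 2),
               rep("juxtacortical", 5))
  labels <- c(rep("rim+", 4), rep("rim-", 6))
  rep_ <- location_report(regions, labels)
  for (cl in unique(labels)) {
    expect_equal(sum(rep_$pct[rep_$class == cl]), 100, tolerance = 0.1)
  }
  single <- location_report(rep("deep_white_matter", 4), rep("rim+", 4))
  expect_equal(single$pct[single$n > 0], 100)
})
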