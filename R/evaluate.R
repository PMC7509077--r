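#' ROC curve points of one score set
#'
#' @param scores classifier scores (higher = more rim+).
#' @param labels binary labels (1 = rim+).
#' @return Data frame (threshold, fpr, tpr) over all distinct thresholds,
#'   from (0,0) to (1,1).
#' @keywords internal
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  n_pos <- sum(l == 1L)
  n_neg <- sum(l == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes are required")
  tp <- cumsum(l == 1L)
  fp <- cumsum(l == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last duplicate of each threshold
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp[keep] / n_neg),
             tpr = c(0, tp[keep] / n_pos))
}

# precision-recall points (recall ascending)
pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  n_pos <- sum(l == 1L)
  if (n_pos == 0L) stop("both classes are required")
  tp <- cumsum(l == 1L)
  pred_pos <- seq_along(l)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = s[keep],
             recall = tp[keep] / n_pos,
             precision = tp[keep] / pred_pos[keep])
}

#' ROC AUC by pairwise comparison (Mann-Whitney; ties count 1/2)
#'
#' @param scores scores; @param labels binary labels (1 = positive).
#' @return The AUC.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes are required")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# average precision (step integral of the PR curve)
auc_pr <- function(scores, labels) {
  p <- pr_points(scores, labels)
  rec <- c(0, p$recall)
  sum(diff(rec) * p$precision)
}

#' Fold-averaged ROC and PR curves
#'
#' Per-fold curves are interpolated onto a common abscissa grid with
#' piecewise-constant (step) interpolation and averaged pointwise. The
#' reported AUC is the mean of the per-fold AUCs (ROC: pairwise-comparison
#' estimate; PR: average precision), not the AUC of the averaged curve.
#'
#' @param scores_by_fold list of per-fold score vectors.
#' @param labels_by_fold list of matching binary label vectors.
#' @param grid_n number of abscissa points (default 1001).
#' @return List: \code{roc} (data frame fpr, mean tpr), \code{pr} (recall,
#'   mean precision), \code{auc_roc}, \code{auc_pr}, per-fold AUC vectors.
#' @export
averaged_curves <- function(scores_by_fold, labels_by_fold, grid_n = 1001L) {
  stopifnot(length(scores_by_fold) == length(labels_by_fold),
            length(scores_by_fold) >= 1L)
  for (f in seq_along(labels_by_fold)) {
    if (length(unique(as.integer(labels_by_fold[[f]]))) < 2L)
      stop(sprintf("fold %d contains a single class", f))
  }
  grid <- seq(0, 1, length.out = grid_n)
  tprs <- matrix(NA_real_, length(scores_by_fold), grid_n)
  precs <- matrix(NA_real_, length(scores_by_fold), grid_n)
  auc_r <- numeric(length(scores_by_fold))
  auc_p <- numeric(length(scores_by_fold))
  for (f in seq_along(scores_by_fold)) {
    s <- scores_by_fold[[f]]
    l <- as.integer(labels_by_fold[[f]])
    rp <- roc_points(s, l)
    # step interpolation: tpr(x) = tpr at the largest fpr <= x
    tprs[f, ] <- approx(rp$fpr, rp$tpr, xout = grid, method = "constant",
                        f = 0, ties = max, rule = 2)$y
    pp <- pr_points(s, l)
    prev <- sum(l == 1L) / length(l)
    # precision(r): piecewise-constant in recall; recall 0 anchored at the
    # precision of the smallest predicted-positive set
    precs[f, ] <- approx(c(0, pp$recall), c(pp$precision[1], pp$precision),
                         xout = grid, method = "constant", f = 1, ties = max,
                         rule = 2)$y
    auc_r[f] <- auc_mw(s, l)
    auc_p[f] <- auc_pr(s, l)
  }
  list(roc = data.frame(fpr = grid, tpr = colMeans(tprs)),
       pr = data.frame(recall = grid, precision = colMeans(precs)),
       auc_roc = mean(auc_r), auc_pr = mean(auc_p),
       auc_roc_by_fold = auc_r, auc_pr_by_fold = auc_p)
}

# midranks as used by the DeLong estimator
midranks <- function(x) rank(x, ties.method = "average")

#' DeLong test for two correlated ROC AUCs
#'
#' Nonparametric comparison of the AUCs of two score sets over the same
#' cases, using midrank-based structural components and the DeLong
#' covariance estimate; two-sided normal test on the AUC difference. When
#' the variance of the difference is zero and the AUCs are equal the p-value
#' is 1.
#'
#' @param scores_a,scores_b paired score vectors (same cases, same order).
#' @param labels binary labels (1 = positive).
#' @return List: \code{auc_a}, \code{auc_b}, \code{statistic} (z),
#'   \code{p_value}, \code{var_diff}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores and labels must be paired (equal length)")
  pos <- labels == 1L
  m <- sum(pos)
  n <- sum(!pos)
  if (m == 0L || n == 0L) stop("both classes are required")
  comp <- function(s) {
    x <- s[pos]
    y <- s[!pos]
    r_all <- midranks(c(x, y))
    r_x <- midranks(x)
    r_y <- midranks(y)
    auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
    v10 <- (r_all[seq_len(m)] - r_x) / n            # per-positive components
    v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m    # per-negative components
    list(auc = auc, v10 = v10, v01 = v01)
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- a$auc - b$auc
  if (var_diff <= .Machine$double.eps) {
    p <- if (abs(d) < .Machine$double.eps^0.5) 1 else 0
    z <- if (p == 1) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, statistic = z, p_value = p,
       var_diff = var_diff)
}

#' McNemar test with continuity correction
#'
#' Paired test on the discordant counts b and c:
#' statistic (|b - c| - 1)^2 / (b + c), chi-square with 1 df. p = 1 when
#' b + c = 0.
#'
#' @param b,c discordant counts (method A right / B wrong, and vice versa).
#' @return List: \code{statistic}, \code{p_value}.
#' @export
mcnemar_discordant <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be non-negative")
  if (b + c == 0) return(list(statistic = 0, p_value = 1))
  stat <- (abs(b - c) - 1)^2 / (b + c)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Operating threshold at a target specificity
#'
#' Returns the smallest candidate threshold (from the observed scores, plus
#' Inf) whose empirical specificity (fraction of negatives with score below
#' the threshold, prediction rule: positive iff score >= threshold) is at
#' least the target.
#'
#' @param scores scores; @param labels binary labels (1 = positive).
#' @param target_specificity required specificity (default 0.95).
#' @return List: \code{threshold}, \code{specificity} (achieved),
#'   \code{sensitivity} (at that threshold).
#' @export
operating_point <- function(scores, labels, target_specificity = 0.95) {
  labels <- as.integer(labels)
  neg <- scores[labels == 0L]
  pos <- scores[labels == 1L]
  if (length(neg) == 0L || length(pos) == 0L) stop("both classes are required")
  cand <- sort(unique(c(scores, Inf)))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  ok <- which(spec >= target_specificity)
  t <- cand[ok[1]]
  list(threshold = t, specificity = spec[ok[1]],
       sensitivity = mean(pos >= t))
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return List of accuracy, F1, sensitivity, specificity, PPV, NPV (each in
#'   [0, 1]); ratios with zero denominators are NA, not 0.
#' @export
lesion_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(tp, tp + fn)
  ppv <- div(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  list(accuracy = (tp + tn) / total, f1 = f1, sensitivity = sens,
       specificity = div(tn, tn + fp), ppv = ppv, npv = div(tn, tn + fn))
}

confusion_counts <- function(pred, truth) {
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Patient-level chronic-active categorization
#'
#' A patient is "chronic active" when the number of rim+ lesions reaches the
#' threshold (predicted counts from thresholded per-lesion probabilities;
#' ground-truth counts with the same rule on true labels).
#'
#' @param patient_ids per-lesion patient identifiers.
#' @param probs per-lesion rim+ probabilities.
#' @param labels per-lesion true binary labels.
#' @param prob_threshold lesion-level operating threshold (predicted rim+
#'   iff probability >= threshold).
#' @param count_threshold lesions needed to call a patient chronic active
#'   (default 4; the reference clinical cut-off).
#' @return List: per-patient data frame (patient_id, n_pred, n_true,
#'   pred_active, true_active), confusion counts and metrics.
#' @export
patient_categorize <- function(patient_ids, probs, labels,
                               prob_threshold = 0.5, count_threshold = 4L) {
  stopifnot(length(patient_ids) == length(probs),
            length(probs) == length(labels))
  pred <- as.integer(probs >= prob_threshold)
  truth <- as.integer(labels)
  n_pred <- tapply(pred, patient_ids, sum)
  n_true <- tapply(truth, patient_ids, sum)
  df <- data.frame(patient_id = names(n_pred),
                   n_pred = as.integer(n_pred),
                   n_true = as.integer(n_true[names(n_pred)]),
                   stringsAsFactors = FALSE)
  df$pred_active <- df$n_pred >= count_threshold
  df$true_active <- df$n_true >= count_threshold
  cm <- confusion_counts(df$pred_active, df$true_active)
  metrics <- if (sum(unlist(cm)) > 0 && (cm$tp + cm$fn) > 0 &&
                 (cm$tn + cm$fp) > 0)
    lesion_metrics(cm$tp, cm$fp, cm$fn, cm$tn) else NULL
  list(patients = df, confusion = cm, metrics = metrics)
}

#' Assign lesions to anatomical regions
#'
#' The cortex mask is dilated by 2 mm and the ventricle mask by 3 mm
#' (spherical structuring elements). Precedence: periventricular (any
#' overlap with the dilated ventricles), then juxtacortical (at least half
#' of the lesion inside the dilated cortex), then deep gray / brainstem /
#' cerebellum (at least half), then deep white matter (residual).
#'
#' @param candidates list of \code{lesion_candidate}.
#' @param region_masks named list of binary arrays: \code{ventricles},
#'   \code{cortex}, optionally \code{deep_gray}, \code{brainstem},
#'   \code{cerebellum}.
#' @param spacing_mm isotropic voxel size.
#' @param cortex_dilation_mm,ventricle_dilation_mm dilation radii (defaults
#'   2 and 3 mm).
#' @return Character vector of region labels ("periventricular",
#'   "juxtacortical", "deep_gray", "brainstem", "cerebellum",
#'   "deep_white_matter"), one per candidate.
#' @export
assign_regions <- function(candidates, region_masks, spacing_mm,
                           cortex_dilation_mm = 2, ventricle_dilation_mm = 3) {
  if (length(candidates) == 0L) return(character(0))
  dims <- candidates[[1]]$dims
  for (nm in names(region_masks)) {
    if (!identical(as.integer(dim(region_masks[[nm]])), as.integer(dims)))
      stop(sprintf("region mask '%s' grid does not match candidates", nm))
  }
  vent <- dilate_ball(region_masks$ventricles, ventricle_dilation_mm, spacing_mm)
  cort <- dilate_ball(region_masks$cortex, cortex_dilation_mm, spacing_mm)
  half_regions <- intersect(names(region_masks),
                            c("deep_gray", "brainstem", "cerebellum"))
  vapply(candidates, function(cc) {
    v <- cc$voxels
    if (any(vent[v])) return("periventricular")
    if (sum(cort[v]) >= cc$voxel_count / 2) return("juxtacortical")
    for (r in half_regions) {
      if (sum(region_masks[[r]][v] != 0) >= cc$voxel_count / 2) return(r)
    }
    "deep_white_matter"
  }, character(1))
}

#' Per-region lesion counts and percentages by class
#'
#' @param regions character vector of region assignments.
#' @param labels parallel class labels ("rim+" / "rim-").
#' @return Data frame (region, class, n, pct) where pct is the percentage of
#'   that class's total.
#' @export
location_report <- function(regions, labels) {
  stopifnot(length(regions) == length(labels))
  tab <- as.data.frame(table(region = regions, class = labels),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  totals <- tapply(tab$n, tab$class, sum)
  tab$pct <- 100 * tab$n / as.numeric(totals[tab$class])
  tab[tab$n > 0 | TRUE, , drop = FALSE]
}

#' Lesion-level evaluation report
#'
#' Combines fold-averaged curves, the fixed-specificity operating point
#' (chosen on the pooled scores), the lesion confusion matrix and metrics,
#' and patient-level categorization across count thresholds 1-6.
#'
#' @param scores_by_fold,labels_by_fold per-fold scores and labels.
#' @param patient_ids_by_fold per-fold patient ids (optional; enables the
#'   patient-level analysis).
#' @param target_specificity operating specificity (default 0.95).
#' @return An \code{eval_report} list.
#' @export
eval_report <- function(scores_by_fold, labels_by_fold,
                        patient_ids_by_fold = NULL,
                        target_specificity = 0.95) {
  curves <- averaged_curves(scores_by_fold, labels_by_fold)
  scores <- unlist(scores_by_fold)
  labels <- as.integer(unlist(labels_by_fold))
  op <- operating_point(scores, labels, target_specificity)
  pred <- scores >= op$threshold
  cm <- confusion_counts(pred, labels == 1L)
  metrics <- lesion_metrics(cm$tp, cm$fp, cm$fn, cm$tn)
  patient <- NULL
  if (!is.null(patient_ids_by_fold)) {
    pid <- unlist(patient_ids_by_fold)
    patient <- lapply(setNames(1:6, paste0("threshold_", 1:6)), function(k)
      patient_categorize(pid, scores, labels, op$threshold, k))
  }
  structure(list(curves = curves, operating_point = op, confusion = cm,
                 metrics = metrics, pooled_auc = auc_mw(scores, labels),
                 patient = patient),
            class = "eval_report")
}
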