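# Repeated stratified patient-wise 5-fold cross-validation with ROC/PR
# analysis, F1-maximizing operating points, median(IQR) aggregation over
# repetitions, and Mann-Whitney comparison of feature sets.

#' Stratified patient-wise cross-validation partitions
#'
#' Within each repetition, patients are shuffled within their class and
#' dealt round-robin into `k` folds, so per-fold positive counts differ by
#' at most one. Every patient appears in exactly one test fold per
#' repetition.
#'
#' @param labels Binary labels named by patient id (names optional).
#' @param k Number of folds.
#' @param n_reps Number of repetitions.
#' @param seed Integer seed.
#' @return A list of length `n_reps`; each element is an integer fold
#'   assignment (1..k) per patient, in the order of `labels`.
#' @export
make_cv_partitions <- function(labels, k = 5L, n_reps = 100L, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  for (cls in c(0L, 1L)) {
    assert_that(sum(labels == cls) >= k,
                sprintf("class %d has fewer than k patients", cls))
  }
  seeds <- spawn_seeds(seed, n_reps)
  lapply(seq_len(n_reps), function(r) {
    with_seed(seeds[r], {
      fold <- integer(n)
      for (cls in c(0L, 1L)) {
        idx <- which(labels == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      fold
    })
  })
}

#' ROC and PR curves with their areas
#'
#' Thresholds are the sorted unique scores (an instance is positive when
#' its score is >= the threshold). The ROC area is trapezoidal. The PR
#' area treats the curve as a rectangular, right-continuous step function
#' of recall (each precision value is carried forward to the next recall
#' level); this conservative rule avoids the documented optimism of PR
#' interpolation, leaves the constant-score classifier at exactly the
#' prevalence, and keeps the mean over random score draws at the
#' theoretical random-classifier baseline. `"ap"` (average precision,
#' precision carried backward) and `"trapezoid"` are available as
#' alternatives. Both areas are on the 0-100 scale.
#'
#' @param scores Classifier scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @param pr_rule PR integration rule: `"step"` (right-continuous,
#'   default), `"ap"` or `"trapezoid"`.
#' @return A list with `roc` (data.frame `fpr`, `tpr` as fractions),
#'   `pr` (data.frame `recall`, `precision`), `auroc`, `auprc` (percent).
#' @export
compute_roc_pr <- function(scores, labels,
                           pr_rule = c("step", "ap", "trapezoid")) {
  pr_rule <- match.arg(pr_rule)
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) == 2L, "both classes must be present")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  tpr <- tp / np
  fpr <- fp / nn
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auroc <- 100 * trapz(roc$fpr, roc$tpr)
  precision <- tp / (tp + fp)
  recall <- tpr
  k <- length(recall)
  auprc <- 100 * switch(pr_rule,
    step = precision[1L] * recall[1L] +
      if (k > 1L) sum(precision[-k] * diff(recall)) else 0,
    ap = sum(diff(c(0, recall)) * precision),
    trapezoid = trapz(c(0, recall), c(precision[1L], precision)))
  list(roc = roc, pr = data.frame(recall = recall, precision = precision),
       auroc = auroc, auprc = auprc)
}

#' Operating point maximizing the F1 score
#'
#' Evaluates sensitivity, specificity, precision and F1 at every unique
#' score threshold (positive when score >= threshold) and returns the
#' metrics at the F1-maximizing threshold, breaking ties toward higher
#' specificity.
#'
#' @param scores Classifier scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return A list with `se`, `sp`, `precision`, `f1` (percent) and
#'   `threshold`.
#' @export
metrics_at_best_f1 <- function(scores, labels) {
  labels <- as.integer(labels)
  assert_that(length(unique(labels)) == 2L, "both classes must be present")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    se <- tp / np
    sp <- (nn - fp) / nn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + se > 0) 2 * prec * se / (prec + se) else 0
    if (is.null(best) || f1 > best$f1 + 1e-12 ||
        (abs(f1 - best$f1) <= 1e-12 && sp > best$sp)) {
      best <- list(se = se, sp = sp, precision = prec, f1 = f1, threshold = t)
    }
  }
  list(se = 100 * best$se, sp = 100 * best$sp,
       precision = 100 * best$precision, f1 = 100 * best$f1,
       threshold = best$threshold)
}

#' Median and IQR of per-repetition metrics
#'
#' @param metrics A data.frame with one row per repetition.
#' @return A data.frame with rows `median` and `iqr` (Q3 - Q1).
#' @export
aggregate_median_iqr <- function(metrics) {
  med <- vapply(metrics, stats::median, numeric(1))
  iqr <- vapply(metrics, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    q[2L] - q[1L]
  }, numeric(1))
  out <- rbind(median = med, iqr = iqr)
  as.data.frame(out)
}

#' Repetition closest to the median AUROC
#'
#' @param aurocs Per-repetition AUROC values.
#' @return The index of the repetition whose AUROC is closest to the
#'   median (ties to the lower index).
#' @export
select_median_repetition <- function(aurocs) {
  which.min(abs(aurocs - stats::median(aurocs)))
}

#' Repeated stratified cross-validation of the rearrest classifier
#'
#' Per fold: impute missing feature values by the training-fold median,
#' run the two-stage forest ([select_and_retrain()]) on the training
#' patients only, and score the held-out patients. Test scores are pooled
#' across the 5 folds of each repetition before curves and metrics are
#' computed; metrics are aggregated as median(IQR) over repetitions.
#'
#' @param features A data.frame with a `label` column and feature columns.
#' @param feature_cols Feature column names (default `v1`...`v21`
#'   intersected with the available columns).
#' @param k Folds per repetition.
#' @param n_reps Repetitions.
#' @param rf An [rf_config()] template (its seed is re-spawned per fold).
#' @param seed Master seed.
#' @return An object of class `cv_report`: list with `per_rep`
#'   (data.frame of per-repetition metrics), `aggregate`
#'   (median/IQR), `median_rep` (index), `curves` (ROC/PR of the median
#'   repetition), `config`.
#' @export
run_repeated_cv <- function(features, feature_cols = NULL, k = 5L,
                            n_reps = 100L, rf = rf_config(), seed = 1L) {
  assert_that("label" %in% names(features), "features must have a label column")
  assert_that(nrow(features) >= 10, "at least 10 patients are required")
  if (is.null(feature_cols)) {
    feature_cols <- intersect(paste0("v", 1:21), names(features))
  }
  y <- as.integer(features$label)
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  parts <- make_cv_partitions(y, k = k, n_reps = n_reps, seed = seed)
  fold_seeds <- matrix(spawn_seeds(seed + 1L, n_reps * k), nrow = n_reps)
  per_rep <- vector("list", n_reps)
  curves_all <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    fold <- parts[[r]]
    scores <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr_rows <- which(fold != f)
      te_rows <- which(fold == f)
      assert_that(length(unique(y[tr_rows])) == 2L,
                  "training fold contains a single class")
      Xtr <- X[tr_rows, , drop = FALSE]
      Xte <- X[te_rows, , drop = FALSE]
      med <- apply(Xtr, 2L, stats::median, na.rm = TRUE)
      med[!is.finite(med)] <- 0
      for (j in seq_along(med)) {
        Xtr[!is.finite(Xtr[, j]), j] <- med[j]
        Xte[!is.finite(Xte[, j]), j] <- med[j]
      }
      rf_f <- rf
      rf_f$seed <- fold_seeds[r, f]
      fit <- select_and_retrain(Xtr, y[tr_rows], rf_f)
      scores[te_rows] <- predict_likelihood(fit$model, Xte)
    }
    curves <- compute_roc_pr(scores, y)
    op <- metrics_at_best_f1(scores, y)
    per_rep[[r]] <- data.frame(rep = r, auroc = curves$auroc,
                               auprc = curves$auprc, se = op$se, sp = op$sp,
                               precision = op$precision, f1 = op$f1,
                               threshold = op$threshold)
    curves_all[[r]] <- curves[c("roc", "pr")]
  }
  per_rep <- do.call(rbind, per_rep)
  metric_cols <- c("auroc", "auprc", "se", "sp", "precision", "f1")
  agg <- aggregate_median_iqr(per_rep[, metric_cols])
  med_rep <- select_median_repetition(per_rep$auroc)
  structure(list(per_rep = per_rep, aggregate = agg, median_rep = med_rep,
                 curves = curves_all[[med_rep]],
                 config = list(k = k, n_reps = n_reps, rf = rf, seed = seed,
                               feature_cols = feature_cols)),
            class = "cv_report")
}

#' Compare two cross-validation reports with a Mann-Whitney test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the per-repetition
#' distributions of a metric from two [run_repeated_cv()] reports, e.g.
#' HRV-only versus all features.
#'
#' @param report_a,report_b `cv_report` objects (>= 10 repetitions each).
#' @param metric Metric column to compare.
#' @return The two-sided p-value.
#' @export
compare_feature_sets <- function(report_a, report_b, metric = "auroc") {
  a <- report_a$per_rep[[metric]]
  b <- report_b$per_rep[[metric]]
  assert_that(length(a) >= 10 && length(b) >= 10,
              "both reports need at least 10 repetitions")
  if (length(a) != length(b)) {
    warning("reports have different numbers of repetitions")
  }
  stats::wilcox.test(a, b, exact = FALSE)$p.value
}
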