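# Evaluation harness: three cross-validation blinding settings (held-out
# pairs, held-out drugs, held-out targets), repeated stratified 10-fold CV,
# ROC/PR summaries, and a bootstrap paired t-test for method comparison.

#' Build a cross-validation plan
#'
#' Three blinding settings: `CVS1` partitions all drug-target pairs into
#' stratified folds (new-pair prediction); `CVS2` partitions drugs, so a
#' fold's test set is every pair involving its drugs (new-drug prediction);
#' `CVS3` does the same for targets. Each repeat reshuffles with a seed
#' derived from `seed`.
#'
#' @param dataset A `dti_dataset`.
#' @param setting One of `"CVS1"`, `"CVS2"`, `"CVS3"`.
#' @param n_folds Number of folds (default 10).
#' @param n_repeats Number of repeats (default 5).
#' @param seed Integer seed.
#' @return An object of class `cv_plan`: `setting`, `n_folds`, `n_repeats`,
#'   `assignments` (per repeat, an integer fold id per unit: pairs in
#'   drug-major order for CVS1, drugs for CVS2, targets for CVS3), and the
#'   dataset dimensions.
#' @export
make_cv_plan <- function(dataset, setting = c("CVS1", "CVS2", "CVS3"),
                         n_folds = 10L, n_repeats = 5L, seed = 1L) {
  setting <- match.arg(setting)
  stopifnot(inherits(dataset, "dti_dataset"))
  n_folds <- as.integer(n_folds)
  n_repeats <- as.integer(n_repeats)
  y <- dataset$interactions$y
  n_d <- nrow(y)
  n_t <- ncol(y)
  n_units <- switch(setting, CVS1 = n_d * n_t, CVS2 = n_d, CVS3 = n_t)
  if (n_units < n_folds) {
    stop_dtifuse(sprintf("%d units cannot fill %d folds", n_units, n_folds),
                 "dtifuse_config_error")
  }
  pair_labels <- if (setting == "CVS1") {
    # drug-major pair order: pair p = (drug (p-1) %/% n_t + 1, target (p-1) %% n_t + 1)
    as.numeric(t(y))
  } else NULL
  assignments <- lapply(seq_len(n_repeats), function(r) {
    with_seed(derive_seed(seed, paste0("cv_", setting, "_rep", r)), {
      fold <- integer(n_units)
      if (setting == "CVS1") {
        # label-stratified with load balancing: each class is dealt
        # cyclically starting at the currently lightest folds, so per-class
        # counts AND total fold sizes differ by at most one
        load <- integer(n_folds)
        for (cls in unique(pair_labels)) {
          idx <- which(pair_labels == cls)
          ord_folds <- order(load, sample.int(n_folds))
          assign_to <- rep_len(ord_folds, length(idx))
          fold[idx[sample.int(length(idx))]] <- assign_to
          load <- load + tabulate(assign_to, n_folds)
        }
      } else {
        fold[sample.int(n_units)] <- rep_len(sample.int(n_folds), n_units)
      }
      fold
    })
  })
  structure(list(setting = setting, n_folds = n_folds, n_repeats = n_repeats,
                 assignments = assignments, n_drugs = n_d, n_targets = n_t,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# pair indices (2-col matrix, drug-major enumeration) for one fold's test
# and train sets under a plan
cv_fold_pairs <- function(plan, repeat_i, fold) {
  all_pairs <- cbind(drug = rep(seq_len(plan$n_drugs), each = plan$n_targets),
                     target = rep(seq_len(plan$n_targets), plan$n_drugs))
  fold_of <- plan$assignments[[repeat_i]]
  test_units <- which(fold_of == fold)
  in_test <- switch(plan$setting,
                    CVS1 = seq_len(nrow(all_pairs)) %in% test_units,
                    CVS2 = all_pairs[, "drug"] %in% test_units,
                    CVS3 = all_pairs[, "target"] %in% test_units)
  list(train = all_pairs[!in_test, , drop = FALSE],
       test = all_pairs[in_test, , drop = FALSE])
}

#' Confusion-matrix metrics
#'
#' @param labels,predictions Equal-length binary vectors.
#' @return A list with `tpr` (= recall, TP/(TP+FN)), `fpr` (FP/(FP+TN)) and
#'   `precision` (TP/(TP+FP)); a metric with a zero denominator is reported
#'   as `NA` rather than 0.
#' @export
confusion_metrics <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions),
            all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tpr = ratio(tp, tp + fn), fpr = ratio(fp, fp + tn),
       precision = ratio(tp, tp + fp))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive is scored above a random negative, ties counting one half
#' (rank-based implementation).
#'
#' @param labels Binary vector with both classes present.
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_dtifuse("AUC needs both classes present", "dtifuse_validation_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-curve area traversed from the highest score threshold down, with no
#' linear interpolation of precision: tied scores enter as one threshold
#' step, and each recall increment contributes `delta_recall * precision`
#' at that step. All-equal scores give the class prevalence.
#'
#' @param labels Binary vector with at least one positive.
#' @param scores Numeric scores.
#' @return AUPR in \[0, 1\].
#' @export
aupr_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  if (n1 == 0) {
    stop_dtifuse("AUPR needs at least one positive", "dtifuse_validation_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each unique-score threshold
  steps <- which(!duplicated(s, fromLast = TRUE))  # last index of each group
  tp <- cumsum(l)[steps]
  k <- steps                                       # predicted positives
  prec <- tp / k
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Entity features come from the unsupervised autoencoder stage, computed
#' once per dataset (it never reads the interaction matrix, so no fold
#' leakage is possible there). Per fold: training labels are taken only
#' from training units, the training rows are optionally SMOTE-balanced,
#' the classifier is trained, and the held-out pairs are scored. Per
#' repeat, AUC/AUPR are computed over the repeat's pooled fold predictions;
#' the final metrics average the per-repeat values.
#'
#' @param dataset A `dti_dataset`.
#' @param plan A [make_cv_plan()].
#' @param drug_cfg,target_cfg Autoencoder [layer_config()]s; may be omitted
#'   when `features` is supplied.
#' @param rwr_cfg,mda_cfg,dnn_cfg Stage configurations.
#' @param smote_cfg A [smote_config()], or `NULL` to skip oversampling.
#' @param features Optionally, a precomputed [extract_features()] result to
#'   reuse.
#' @return An object of class `cv_result`: `per_fold` data frame (repeat,
#'   fold, AUC, AUPR, n_test, n_test_pos), `per_repeat` data frame (pooled
#'   AUC/AUPR), `mean_auc`, `mean_aupr`, and the pooled predictions.
#' @export
run_cv <- function(dataset, plan, drug_cfg = NULL, target_cfg = NULL,
                   rwr_cfg = rwr_config(), mda_cfg = mda_train_config(),
                   dnn_cfg = dnn_config(), smote_cfg = smote_config(),
                   features = NULL) {
  stopifnot(inherits(dataset, "dti_dataset"), inherits(plan, "cv_plan"))
  if (is.null(features)) {
    if (is.null(drug_cfg) || is.null(target_cfg)) {
      stop_dtifuse("either autoencoder layer configs or precomputed features are required",
                   "dtifuse_config_error")
    }
    features <- extract_features(dataset, drug_cfg, target_cfg, rwr_cfg,
                                 mda_cfg)
  }
  y <- dataset$interactions$y
  per_fold <- NULL
  per_repeat <- NULL
  predictions <- NULL
  for (r in seq_len(plan$n_repeats)) {
    pooled_scores <- numeric(0)
    pooled_labels <- numeric(0)
    for (f in seq_len(plan$n_folds)) {
      fp <- cv_fold_pairs(plan, r, f)
      train <- make_pairs(features$drugs, features$targets, y, fp$train)
      test <- make_pairs(features$drugs, features$targets, y, fp$test)
      if (!is.null(smote_cfg)) {
        sc <- smote_cfg
        sc$seed <- derive_seed(smote_cfg$seed,
                               sprintf("smote_r%d_f%d", r, f))
        train <- smote(train, sc)
      }
      dc <- dnn_cfg
      dc$seed <- derive_seed(dnn_cfg$seed, sprintf("dnn_r%d_f%d", r, f))
      model <- train_dnn(train, dc)
      scores <- predict_proba(model, test)
      fold_auc <- fold_aupr <- NA_real_
      if (length(unique(test$labels)) == 2L) {
        fold_auc <- auc_score(test$labels, scores)
        fold_aupr <- aupr_score(test$labels, scores)
      } else {
        warning(sprintf("repeat %d fold %d: single-class test set, fold metrics skipped",
                        r, f))
      }
      per_fold <- rbind(per_fold,
                        data.frame(repeat_i = r, fold = f, auc = fold_auc,
                                   aupr = fold_aupr, n_test = length(scores),
                                   n_test_pos = sum(test$labels)))
      pooled_scores <- c(pooled_scores, scores)
      pooled_labels <- c(pooled_labels, test$labels)
      predictions <- rbind(predictions,
                           data.frame(repeat_i = r, fold = f,
                                      drug = test$pairs[, 1],
                                      target = test$pairs[, 2],
                                      label = test$labels, score = scores))
    }
    per_repeat <- rbind(per_repeat,
                        data.frame(repeat_i = r,
                                   auc = auc_score(pooled_labels, pooled_scores),
                                   aupr = aupr_score(pooled_labels, pooled_scores)))
  }
  structure(list(setting = plan$setting, per_fold = per_fold,
                 per_repeat = per_repeat,
                 mean_auc = mean(per_repeat$auc),
                 mean_aupr = mean(per_repeat$aupr),
                 predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean AUC %.4f, mean AUPR %.4f over %d repeat(s)\n",
              x$setting, x$mean_auc, x$mean_aupr, nrow(x$per_repeat)))
  invisible(x)
}

#' Bootstrap paired t-test
#'
#' Tests whether two paired metric series (e.g. 50 per-fold AUCs from two
#' methods) differ in mean. The observed paired t statistic is compared
#' with a bootstrap null distribution built by resampling the mean-centered
#' paired differences (`n_boot` resamples); the two-sided p-value is the
#' add-one-corrected proportion of null statistics at least as extreme.
#' Degenerate all-equal inputs give p = 1.
#'
#' @param a,b Equal-length numeric vectors (length >= 2) of paired metrics.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @return Two-sided p-value.
#' @export
paired_t_bootstrap <- function(a, b, n_boot = 2000L, seed = 1L) {
  if (length(a) != length(b)) {
    stop_dtifuse("paired series must have equal length", "dtifuse_validation_error")
  }
  stopifnot(length(a) >= 2L)
  d <- a - b
  if (all(d == 0)) return(1)
  n <- length(d)
  t_stat <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(if (mean(x) == 0) 0 else sign(mean(x)) * Inf)
    mean(x) / (s / sqrt(n))
  }
  t_obs <- t_stat(d)
  centered <- d - mean(d)
  with_seed(seed, {
    t_null <- vapply(seq_len(n_boot), function(i)
      t_stat(sample(centered, n, replace = TRUE)), numeric(1))
  })
  (1 + sum(abs(t_null) >= abs(t_obs))) / (n_boot + 1)
}
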