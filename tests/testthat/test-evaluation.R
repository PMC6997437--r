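test_that("pair-blinded plans stratify positives evenly across folds", {
  ds <- small_synth()
  plan <- make_cv_plan(ds, "CVS1", n_folds = 10, n_repeats = 2, seed = 3)
  y_flat <- as.numeric(t(ds$interactions$y))
  for (r in 1:2) {
    fold <- plan$assignments[[r]]
    sizes <- table(fold)
    expect_equal(sum(sizes), length(y_flat))
    expect_lte(diff(range(sizes)), 1)
    pos_per_fold <- table(fold[y_flat == 1])
    expect_lte(diff(range(pos_per_fold)), 1)
  }
  expect_identical(make_cv_plan(ds, "CVS1", 10, 2, seed = 3)$assignments,
                   plan$assignments)
  expect_error(make_cv_plan(ds, "CVS2", n_folds = 100),
               class = "dtifuse_config_error")
})

test_that("drug- and target-blinded folds never leak test entities into training", {
  ds <- small_synth()
  for (setting in c("CVS2", "CVS3")) {
    plan <- make_cv_plan(ds, setting, n_folds = 5, n_repeats = 2, seed = 5)
    col <- if (setting == "CVS2") "drug" else "target"
    for (r in 1:2) for (f in 1:5) {
      fp <- dtifuse:::cv_fold_pairs(plan, r, f)
      test_entities <- unique(fp$test[, col])
      expect_length(intersect(unique(fp$train[, col]), test_entities), 0)
      # folds are exhaustive over pairs
      expect_equal(nrow(fp$train) + nrow(fp$test),
                   plan$n_drugs * plan$n_targets)
    }
  }
})

test_that("confusion metrics follow the worked example and mark undefined ratios", {
  m <- confusion_metrics(c(1, 1, 1, 0), c(1, 1, 0, 0))
  expect_equal(m$tpr, 2 / 3)
  expect_equal(m$fpr, 0)
  expect_equal(m$precision, 1)
  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perfect), c(tpr = 1, fpr = 0, precision = 1))
  none <- confusion_metrics(c(1, 0), c(0, 0))
  expect_true(is.na(none$precision))
})

test_that("auc and aupr match worked cases and handle edge conventions", {
  labels <- c(1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.1)
  expect_equal(auc_score(labels, scores), 0.75)
  expect_equal(aupr_score(labels, scores), aupr_oracle(labels, scores))
  expect_equal(auc_score(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(aupr_score(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(auc_score(c(1, 0), c(0.5, 0.5)), 0.5)    # tie convention
  # all-equal scores: constant precision = prevalence
  expect_equal(aupr_score(c(1, 0, 0, 0), rep(0.3, 4)), 0.25)
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), class = "dtifuse_validation_error")
  expect_error(aupr_score(c(0, 0), c(0.2, 0.3)), class = "dtifuse_validation_error")
})

test_that("auc and aupr agree with brute-force oracles on random instances", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_lt(abs(auc_score(labels, scores) - auc_oracle(labels, scores)), 1e-12)
    expect_lt(abs(aupr_score(labels, scores) - aupr_oracle(labels, scores)), 1e-12)
  }
})

test_that("the bootstrap paired t-test separates shifts and returns 1 on ties", {
  set.seed(23)
  a <- runif(50, 0.8, 0.9)
  expect_equal(paired_t_bootstrap(a, a), 1)
  b <- a - 0.2                       # shift far beyond the spread
  expect_lt(paired_t_bootstrap(a, b, seed = 1), 0.05)
  noise <- a + rnorm(50, 0, 0.05)
  p1 <- paired_t_bootstrap(a, noise, seed = 2)
  expect_identical(p1, paired_t_bootstrap(a, noise, seed = 2))
  expect_error(paired_t_bootstrap(a, a[1:10]), class = "dtifuse_validation_error")
})

test_that("cross-validated evaluation pools folds per repeat and averages repeats", {
  ds <- small_synth()
  plan <- make_cv_plan(ds, "CVS1", n_folds = 4, n_repeats = 2, seed = 7)
  cv <- run_cv(ds, plan,
               layer_config(2, 24, bottleneck = 6L),
               layer_config(2, 18, bottleneck = 4L),
               rwr_config(0.9, 5),
               mda_train_config(epochs = 20, seed = 2),
               dnn_config(hidden_widths = c(32L, 16L), max_epochs = 20,
                          seed = 3),
               smote_config(seed = 4))
  expect_equal(nrow(cv$per_repeat), 2)
  expect_equal(nrow(cv$per_fold), 8)
  expect_equal(cv$mean_auc, mean(cv$per_repeat$auc))
  expect_equal(cv$mean_aupr, mean(cv$per_repeat$aupr))
  expect_true(all(cv$per_repeat$auc >= 0 & cv$per_repeat$auc <= 1))
  # per-repeat metric equals the metric over that repeat's pooled predictions
  pr <- cv$predictions[cv$predictions$repeat_i == 1, ]
  expect_equal(cv$per_repeat$auc[1], auc_score(pr$label, pr$score))
  # every pair is tested exactly once per repeat
  expect_equal(nrow(pr), 24 * 18)
  expect_false(any(duplicated(pr[, c("drug", "target")])))

  cv2 <- run_cv(ds, plan,
                layer_config(2, 24, bottleneck = 6L),
                layer_config(2, 18, bottleneck = 4L),
                rwr_config(0.9, 5),
                mda_train_config(epochs = 20, seed = 2),
                dnn_config(hidden_widths = c(32L, 16L), max_epochs = 20,
                           seed = 3),
                smote_config(seed = 4))
  expect_identical(cv$per_repeat, cv2$per_repeat)
})
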