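test_that("confusion matrix counts match a brute-force per-row counter", {
  cm <- confusion_at_threshold(c(0.9, 0.4), c(1, 0), 0.5)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 0, fp = 0, tn = 1))
  cm0 <- confusion_at_threshold(c(0.1, 0.2, 0.3), c(1, 0, 1), 0.5)
  expect_equal(cm0$tp + cm0$fp, 0)
  set.seed(1234)
  p <- runif(1000); y <- rbinom(1000, 1, 0.3)
  cm <- confusion_at_threshold(p, y, 0.4)
  counts <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  for (i in 1:1000) {
    counts[if (p[i] >= 0.4) {if (y[i] == 1) "tp" else "fp"} else
             {if (y[i] == 1) "fn" else "tn"}] <-
      counts[if (p[i] >= 0.4) {if (y[i] == 1) "tp" else "fp"} else
               {if (y[i] == 1) "fn" else "tn"}] + 1
  }
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]), counts)
  # conservation
  expect_equal(cm$tp + cm$fn, sum(y == 1))
  expect_equal(cm$fp + cm$tn, sum(y == 0))
  expect_error(confusion_at_threshold(numeric(0), integer(0)), "empty")
})

test_that("threshold metrics reproduce the published cohort confusion rows", {
  rows <- utils::read.delim(system.file("extdata", "cohort_confusion_counts.tsv",
                                        package = "asepred"))
  metrics <- lapply(seq_len(nrow(rows)), function(i) {
    metrics_from_confusion(confusion_matrix(rows$tp[i], rows$fn[i],
                                            rows$fp[i], rows$tn[i]))
  })
  names(metrics) <- paste(rows$train, rows$test, sep = "->")
  two_dp <- function(m) round2(c(m$ppv, m$npv, m$sensitivity, m$specificity))
  # within-cohort test sets
  expect_equal(two_dp(metrics[["BIOS90->BIOS10"]]), c(0.73, 0.91, 0.29, 0.99))
  expect_equal(two_dp(metrics[["GTEx90->GTEx10"]]), c(0.82, 0.91, 0.26, 0.99))
  # cross-cohort application to the full other cohort
  expect_equal(two_dp(metrics[["GTEx90->BIOS_full"]]), c(0.65, 0.92, 0.37, 0.97))
  cross <- two_dp(metrics[["BIOS90->GTEx_full"]])
  expect_equal(cross[c(1, 2, 4)], c(0.63, 0.91, 0.98))
  # the table-derived sensitivity for this row
  expect_equal(cross[3], 0.29)
})

test_that("degenerate confusion matrices flag undefined metrics", {
  m <- metrics_from_confusion(confusion_matrix(10, 0, 0, 10))
  expect_equal(c(m$ppv, m$npv, m$sensitivity, m$specificity), rep(1, 4))
  m0 <- metrics_from_confusion(confusion_matrix(0, 5, 0, 5))
  expect_true(is.na(m0$ppv))
  expect_true(m0$undefined[["ppv"]])
  expect_false(m0$undefined[["npv"]])
})

test_that("AUROC equals all-pairs concordance, with ties at one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "classes")
  set.seed(77)
  p <- sample(round(runif(500), 2))  # rounded scores force ties
  y <- rbinom(500, 1, 0.4)
  expect_equal(roc_auc(p, y), oracle_auc_pairs(p, y), tolerance = 1e-10)
  # invariance under a strictly monotone transform
  expect_equal(roc_auc(qlogis(p * 0.98 + 0.01), y), roc_auc(p, y),
               tolerance = 1e-12)
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(88)
  p <- runif(300); y <- rbinom(300, 1, 0.5)
  expect_equal(roc_auc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, levels = c(0, 1),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("ensemble evaluation reports fold AUROC spread and threshold metrics", {
  toy <- make_toy_model(n = 300, seed = 61)
  rep <- evaluate_ensemble(toy$ensemble, toy$fm, toy$truth, 0.5)
  expect_length(rep$per_fold_auroc, 3)
  expect_gte(rep$auroc_sd, 0)
  # training-set AUROC beats shuffled labels
  set.seed(62)
  shuf <- sample(toy$truth)
  rep_shuf <- evaluate_ensemble(toy$ensemble, toy$fm, shuf, 0.5)
  expect_gt(rep$auroc_mean, rep_shuf$auroc_mean)
  # duplicated fold models have zero AUROC spread
  twin <- toy$ensemble
  twin$models <- list(twin$models[[1]], twin$models[[1]])
  rep_twin <- evaluate_ensemble(twin, toy$fm, toy$truth, 0.5)
  expect_equal(rep_twin$auroc_sd, 0)
})

test_that("holdout performance is stable across an independent refit", {
  truth <- rep(c(TRUE, FALSE), 1000)
  fm <- impute_and_encode(simulate_feature_matrix(
    truth, feature_sim_config(n_features_numeric = 6,
                              effect_vector = c(1.5, 1, 0.8, 0, 0, 0),
                              seed = 71)))
  aucs <- vapply(c(5, 6), function(s) {
    sp <- split_holdout(fm, truth, 0.2, seed = s)
    ens <- train_nested_cv(sp$train$x, sp$train$labels,
                           train_config(n_boost_iterations = 50,
                                        outer_folds = 5, seed = s))
    evaluate_ensemble(ens, sp$test$x, sp$test$labels)$auroc_mean
  }, numeric(1))
  expect_lt(abs(aucs[1] - aucs[2]), 0.05)
})
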