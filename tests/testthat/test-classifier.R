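test_that("stratified holdout preserves class ratio and partitions the rows", {
  truth <- rep(c(TRUE, FALSE), c(300, 700))
  fm <- impute_and_encode(simulate_feature_matrix(
    truth, feature_sim_config(n_features_numeric = 3, seed = 1)))
  sp <- split_holdout(fm, truth, 0.10, seed = 4)
  expect_equal(length(sp$test$labels), 100)
  expect_equal(sum(sp$test$labels), 30)   # class ratio preserved
  expect_equal(length(sp$train$labels) + length(sp$test$labels), 1000)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)
  expect_setequal(c(sp$train$ids, sp$test$ids), fm$row_ids)
  sp2 <- split_holdout(fm, truth, 0.10, seed = 4)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_error(split_holdout(fm, rep(TRUE, 1000), 0.1, 1), "classes")
})

test_that("a perfectly separating feature yields near-perfect outer AUROC", {
  set.seed(5)
  n <- 300
  y <- rep(c(1L, 0L), n / 2)
  x <- cbind(sep = y * 2 + runif(n, 0, 0.1), noise = rnorm(n))
  ens <- train_nested_cv(x, y, train_config(n_boost_iterations = 30,
                                            outer_folds = 3, seed = 2))
  expect_true(all(ens$outer_auroc >= 0.99))
})

test_that("pure-noise features give chance-level outer AUROC", {
  truth <- rep(c(TRUE, FALSE), 1500)
  fm <- impute_and_encode(simulate_feature_matrix(
    truth, feature_sim_config(n_features_numeric = 8, seed = 21)))
  ens <- train_nested_cv(fm, truth,
                         train_config(n_boost_iterations = 50, outer_folds = 5,
                                      seed = 3))
  expect_gt(mean(ens$outer_auroc), 0.45)
  expect_lt(mean(ens$outer_auroc), 0.55)
})

test_that("training is reproducible from (data, config, seed)", {
  toy <- make_toy_model(seed = 33)
  toy2 <- make_toy_model(seed = 33)
  expect_identical(toy$ensemble$importances, toy2$ensemble$importances)
  expect_identical(predict_proba(toy$ensemble, toy$fm),
                   predict_proba(toy2$ensemble, toy2$fm))
})

test_that("predictions are probabilities, a pure function of features", {
  toy <- make_toy_model()
  m <- as.matrix(toy$fm)
  p <- predict_proba(toy$ensemble, m)
  expect_true(all(p >= 0 & p <= 1))
  # a duplicated row scores identically
  dup <- m[c(1, 1), , drop = FALSE]
  pd <- predict_proba(toy$ensemble, dup)
  expect_identical(pd[1], pd[2])
  # fold-mean aggregation: single-fold mean equals that model's output
  pf <- predict_proba(toy$ensemble, m, per_fold = TRUE)
  expect_equal(rowMeans(pf), p, tolerance = 1e-12)
  one <- toy$ensemble; one$models <- one$models[1]
  expect_equal(predict_proba(one, m), pf[, 1], tolerance = 1e-12)
  # mismatched columns are refused with the differences listed
  bad <- m; colnames(bad)[2] <- "zzz"
  expect_error(predict_proba(toy$ensemble, bad), "zzz")
})

test_that("importances normalize per fold and ignore unsplittable features", {
  truth <- rep(c(TRUE, FALSE), 400)
  fcfg <- feature_sim_config(n_features_numeric = 4,
                             effect_vector = c(2.5, 0, 0, 0), seed = 12)
  fm <- simulate_feature_matrix(truth, fcfg)
  fm$data$num04 <- 1.0  # constant feature: no split can use it
  fm <- impute_and_encode(fm)
  ens <- train_nested_cv(fm, truth, train_config(n_boost_iterations = 40,
                                                 outer_folds = 4, seed = 6))
  expect_equal(unname(rowSums(ens$importances)), rep(1, 4), tolerance = 1e-9)
  imp <- feature_importance(ens)
  expect_identical(imp$feature[1], "num01")   # dominant planted feature first
  expect_lt(imp$mean_importance[imp$feature == "num04"], 1e-3)
  expect_true(all(diff(imp$mean_importance) <= 0))
})

test_that("label permutation destroys holdout performance", {
  truth <- rep(c(TRUE, FALSE), 1000)
  fm <- impute_and_encode(simulate_feature_matrix(
    truth, feature_sim_config(n_features_numeric = 6,
                              effect_vector = c(1.5, 1, rep(0, 4)), seed = 14)))
  set.seed(99)
  perm <- sample(truth)
  sp <- split_holdout(fm, perm, 0.2, seed = 15)
  ens <- train_nested_cv(sp$train$x, sp$train$labels,
                         train_config(n_boost_iterations = 50, outer_folds = 5,
                                      seed = 16))
  auc <- roc_auc(predict_proba(ens, sp$test$x), sp$test$labels)
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
})

test_that("inner-fold selection picks the clearly better grid point", {
  set.seed(77)
  n <- 600
  y <- rep(c(1L, 0L), n / 2)
  x <- cbind(a = y * 1.5 + rnorm(n), b = rnorm(n), c = rnorm(n))
  grid <- data.frame(learning_rate = c(0.1, 1e-4), tree_depth = c(3L, 1L))
  ens <- train_nested_cv(x, y, train_config(n_boost_iterations = 20,
                                            outer_folds = 3,
                                            hyperparameter_grid = grid,
                                            seed = 8))
  expect_true(all(ens$chosen_params$learning_rate == 0.1))
})

test_that("a saved ensemble reloads with identical predictions", {
  toy <- make_toy_model(n = 200, seed = 55)
  path <- file.path(tempdir(), "toy_model")
  save_ensemble(toy$ensemble, path)
  back <- load_ensemble(path)
  m <- as.matrix(toy$fm)
  expect_equal(predict_proba(back, m), predict_proba(toy$ensemble, m),
               tolerance = 1e-7)
  expect_equal(back$importances, toy$ensemble$importances, tolerance = 1e-12)
  # schema version is verified
  meta <- jsonlite::read_json(file.path(path, "ensemble.json"), simplifyVector = TRUE)
  meta$version <- 99
  jsonlite::write_json(meta, file.path(path, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  expect_error(load_ensemble(path), "schema")
  unlink(path, recursive = TRUE)
})
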