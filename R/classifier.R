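#' Training configuration for the boosted ASE classifier
#'
#' @param n_boost_iterations boosting stages (trees) per model; default 100.
#' @param outer_folds outer cross-validation folds (performance and
#'   per-fold models); default 10.
#' @param inner_folds inner cross-validation folds (hyperparameter
#'   selection); default 6.
#' @param holdout_fraction fraction left out as the independent test set;
#'   default 0.10.
#' @param probability_threshold decision threshold; default 0.5.
#' @param hyperparameter_grid data.frame with columns `learning_rate` and
#'   `tree_depth`; with a single row (the default, learning rate 0.1 and
#'   depth 3) inner selection is skipped.
#' @param seed integer seed controlling fold assignment and tree fitting.
#' @return validated list of class `train_config`.
#' @export
train_config <- function(n_boost_iterations = 100L,
                         outer_folds = 10L,
                         inner_folds = 6L,
                         holdout_fraction = 0.10,
                         probability_threshold = 0.5,
                         hyperparameter_grid = data.frame(learning_rate = 0.1,
                                                          tree_depth = 3L),
                         seed = 1L) {
  if (outer_folds < 2L || inner_folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 0.5) {
    stop("holdout_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  check_interior(probability_threshold, "probability_threshold")
  stopifnot(all(c("learning_rate", "tree_depth") %in% names(hyperparameter_grid)),
            nrow(hyperparameter_grid) >= 1)
  structure(list(
    n_boost_iterations = as.integer(n_boost_iterations),
    outer_folds = as.integer(outer_folds),
    inner_folds = as.integer(inner_folds),
    holdout_fraction = holdout_fraction,
    probability_threshold = probability_threshold,
    hyperparameter_grid = hyperparameter_grid,
    seed = as.integer(seed)
  ), class = "train_config")
}

as_numeric_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) as.matrix(x) else as.matrix(x)
}

#' Stratified holdout split
#'
#' Splits rows into a training set and an independent test set of
#' approximately `fraction` of the rows, sampling within each label class
#' so the class ratio is preserved.
#'
#' @param x encoded [feature_matrix()] or numeric matrix.
#' @param labels binary labels aligned with rows; both classes required.
#' @param fraction test fraction (default 0.10).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a list of `x` (matrix),
#'   `labels` and `ids` (row names), plus the test row indices in `test_idx`.
#' @export
split_holdout <- function(x, labels, fraction = 0.10, seed = 1L) {
  m <- as_numeric_matrix(x)
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (nrow(m) != length(y)) stop("labels do not align with rows", call. = FALSE)
  withr_seed(seed, {
    test_idx <- sort(unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(length(idx) * fraction))
    }), use.names = FALSE))
  })
  train_idx <- setdiff(seq_along(y), test_idx)
  pick <- function(idx) list(x = m[idx, , drop = FALSE], labels = y[idx],
                             ids = rownames(m)[idx])
  list(train = pick(train_idx), test = pick(test_idx), test_idx = test_idx)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

xgb_params <- function(lr, depth, seed) {
  list(objective = "binary:logistic", eta = lr, max_depth = depth,
       tree_method = "exact", nthread = 1, seed = seed, verbosity = 0)
}

fit_boosted <- function(x, y, lr, depth, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = xgb_params(lr, depth, seed), data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

# normalized impurity-decrease (gain) importance over all training columns
model_importance <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  out <- stats::setNames(rep(0, length(feature_names)), feature_names)
  out[imp$Feature] <- imp$Gain
  if (sum(out) > 0) out <- out / sum(out)
  out
}

#' Train the boosted ASE classifier under nested cross-validation
#'
#' The rows are dealt into `outer_folds` stratified folds. For each outer
#' fold, the remaining rows form the outer-training portion: if the
#' hyperparameter grid has more than one row, an inner `inner_folds`-fold
#' cross-validation selects the grid row with the best mean AUROC; a
#' gradient-boosted model with `n_boost_iterations` trees is then fitted on
#' the full outer-training portion. Per fold, the model, its normalized
#' impurity (gain) importance vector and its AUROC on the held-out outer
#' fold are recorded.
#'
#' @param x encoded [feature_matrix()] or numeric matrix (no missing
#'   values); columns must be named.
#' @param labels binary labels aligned with rows.
#' @param config a [train_config()].
#' @return object of class `ase_ensemble`: `models` (list of per-fold
#'   boosters), `importances` (folds x features matrix), `outer_auroc`,
#'   `chosen_params` (per-fold data.frame), `feature_names`, `config`,
#'   `version`.
#' @export
train_nested_cv <- function(x, labels, config = train_config()) {
  m <- as_numeric_matrix(x)
  if (is.null(colnames(m))) stop("feature columns must be named", call. = FALSE)
  y <- as.integer(as.logical(labels))
  if (min(table(y)) < config$outer_folds) {
    stop("too few rows in a class for ", config$outer_folds,
         " outer folds; use fewer folds", call. = FALSE)
  }
  fold <- stratified_folds(y, config$outer_folds, config$seed)

  grid <- config$hyperparameter_grid
  models <- vector("list", config$outer_folds)
  importances <- matrix(0, config$outer_folds, ncol(m),
                        dimnames = list(NULL, colnames(m)))
  outer_auroc <- numeric(config$outer_folds)
  chosen <- grid[rep(1L, config$outer_folds), , drop = FALSE]

  for (f in seq_len(config$outer_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      stop("a fold lost a class; use fewer folds", call. = FALSE)
    }
    g <- if (nrow(grid) > 1L) {
      select_inner(m[tr, , drop = FALSE], y[tr], grid, config, fold_seed(config$seed, f))
    } else 1L
    chosen[f, ] <- grid[g, ]
    model <- fit_boosted(m[tr, , drop = FALSE], y[tr],
                         grid$learning_rate[g], grid$tree_depth[g],
                         config$n_boost_iterations, fold_seed(config$seed, f))
    models[[f]] <- model
    importances[f, ] <- model_importance(model, colnames(m))
    pred <- stats::predict(model, xgboost::xgb.DMatrix(m[!tr, , drop = FALSE]))
    outer_auroc[f] <- roc_auc(pred, y[!tr])
  }
  rownames(chosen) <- NULL
  structure(list(models = models, importances = importances,
                 outer_auroc = outer_auroc, chosen_params = chosen,
                 feature_names = colnames(m), config = config,
                 version = 1L),
            class = "ase_ensemble")
}

fold_seed <- function(seed, f) as.integer((as.double(seed) * 7919 + f) %% 2147483647)

# inner CV: mean validation AUROC per grid row, best row index returned
select_inner <- function(x, y, grid, config, seed) {
  fold <- stratified_folds(y, config$inner_folds, seed)
  score <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(config$inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2L) return(NA_real_)
      mdl <- fit_boosted(x[tr, , drop = FALSE], y[tr],
                         grid$learning_rate[g], grid$tree_depth[g],
                         config$n_boost_iterations, seed)
      roc_auc(stats::predict(mdl, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE])), y[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  which.max(score)
}

#' @export
print.ase_ensemble <- function(x, ...) {
  cat(sprintf("ASE ensemble: %d fold models, %d features, %d trees each\n",
              length(x$models), length(x$feature_names),
              x$config$n_boost_iterations))
  cat(sprintf("outer-fold AUROC %.3f (sd %.4f)\n",
              mean(x$outer_auroc), stats::sd(x$outer_auroc)))
  invisible(x)
}

#' Predict ASE probabilities
#'
#' Per-row probability that a variant undergoes ASE. By default the
#' arithmetic mean of the outer-fold models' probabilities is returned;
#' `per_fold = TRUE` gives the rows-by-folds matrix instead.
#'
#' @param ensemble an `ase_ensemble`.
#' @param x encoded [feature_matrix()] or numeric matrix; column names and
#'   order must match training.
#' @param per_fold return the per-fold probability matrix?
#' @return numeric vector (or matrix) of probabilities in \[0, 1\].
#' @export
predict_proba <- function(ensemble, x, per_fold = FALSE) {
  m <- as_numeric_matrix(x)
  if (!identical(colnames(m), ensemble$feature_names)) {
    extra <- setdiff(colnames(m), ensemble$feature_names)
    missing <- setdiff(ensemble$feature_names, colnames(m))
    stop("feature columns do not match training columns",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         "; order must match as well", call. = FALSE)
  }
  dm <- xgboost::xgb.DMatrix(m)
  probs <- vapply(ensemble$models, function(mod) stats::predict(mod, dm),
                  numeric(nrow(m)))
  probs <- matrix(probs, nrow = nrow(m))
  if (per_fold) probs else rowMeans(probs)
}

#' Summarize feature importance across outer folds
#'
#' Each fold's impurity (gain) importance vector is already normalized to
#' sum 1; the summary reports the mean and quartiles across folds, sorted
#' most to least important by mean.
#'
#' @param ensemble an `ase_ensemble`.
#' @return data.frame: `feature`, `mean_importance`, `q25`, `median`,
#'   `q75`.
#' @export
feature_importance <- function(ensemble) {
  imp <- ensemble$importances
  out <- data.frame(
    feature = colnames(imp),
    mean_importance = colMeans(imp),
    q25 = apply(imp, 2, stats::quantile, 0.25),
    median = apply(imp, 2, stats::median),
    q75 = apply(imp, 2, stats::quantile, 0.75),
    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a trained ensemble
#'
#' The archive is a directory holding one portable JSON tree dump per
#' outer-fold model plus a metadata file (importances, configuration,
#' feature names, schema version); loading verifies the schema version.
#'
#' @param ensemble an `ase_ensemble`.
#' @param path archive directory.
#' @name ensemble_io
#' @export
save_ensemble <- function(ensemble, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(ensemble$models)) {
    xgboost::xgb.save(ensemble$models[[f]], file.path(path, sprintf("fold%02d.ubj", f)))
  }
  meta <- ensemble[setdiff(names(ensemble), "models")]
  meta$config$hyperparameter_grid <- as.data.frame(meta$config$hyperparameter_grid)
  jsonlite::write_json(meta, file.path(path, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname ensemble_io
#' @export
load_ensemble <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "ensemble.json"), simplifyVector = TRUE)
  if (!identical(as.integer(meta$version), 1L)) {
    stop("unsupported ensemble schema version: ", meta$version, call. = FALSE)
  }
  files <- sort(list.files(path, pattern = "^fold[0-9]+\\.ubj$", full.names = TRUE))
  models <- lapply(files, xgboost::xgb.load)
  imp <- as.matrix(meta$importances)
  colnames(imp) <- meta$feature_names
  cfg <- meta$config
  structure(list(models = models, importances = imp,
                 outer_auroc = meta$outer_auroc,
                 chosen_params = as.data.frame(meta$chosen_params),
                 feature_names = meta$feature_names,
                 config = train_config(
                   n_boost_iterations = cfg$n_boost_iterations,
                   outer_folds = cfg$outer_folds,
                   inner_folds = cfg$inner_folds,
                   holdout_fraction = cfg$holdout_fraction,
                   probability_threshold = cfg$probability_threshold,
                   hyperparameter_grid = as.data.frame(cfg$hyperparameter_grid),
                   seed = cfg$seed),
                 version = 1L),
            class = "ase_ensemble")
}
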