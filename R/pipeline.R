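#' Configuration for the end-to-end synthetic analysis pipeline
#'
#' Bundles the per-stage configurations and the global seed. Stage seeds
#' are derived deterministically from the global seed, so a pipeline run
#' is a pure function of its configuration.
#'
#' @param cohort a [cohort_sim_config()] (its `seed` is overridden by the
#'   derived stage seed).
#' @param features a [feature_sim_config()].
#' @param train a [train_config()].
#' @param bias list of bias-test settings: `n_genes`, `n_terms`,
#'   `genes_per_term`, `loci_per_gene`, `n_resamples`, `top_k`.
#' @param min_individuals minimum individuals per locus for ASE calling.
#' @param fdr_threshold FDR level for the ASE flag.
#' @param threshold probability threshold for predicted ASE.
#' @param seed global integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_sim_config(),
                            features = feature_sim_config(
                              n_features_numeric = 10L,
                              effect_vector = c(1.5, 1.0, 0.8, rep(0, 7))),
                            train = train_config(),
                            bias = list(n_genes = 60L, n_terms = 15L,
                                        genes_per_term = c(5L, 15L),
                                        loci_per_gene = 3L,
                                        n_resamples = 10L, top_k = 10L),
                            min_individuals = 5L,
                            fdr_threshold = 0.05,
                            threshold = 0.5,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_sim_config"),
            inherits(features, "feature_sim_config"),
            inherits(train, "train_config"))
  check_interior(threshold, "threshold")
  structure(list(cohort = cohort, features = features, train = train,
                 bias = bias, min_individuals = as.integer(min_individuals),
                 fdr_threshold = fdr_threshold, threshold = threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic analysis end-to-end
#'
#' Executes the stages in dependency order: simulate an allelic-count
#' cohort; call ASE per locus; simulate the annotation feature matrix for
#' the tested loci (signal planted on the true ASE status) and label rows
#' with the cohort-level ASE calls; split off the stratified holdout;
#' train the boosted ensemble under nested cross-validation; evaluate on
#' the holdout; and run the rank-resampling bias test on the predicted
#' ASE-SNVs. Every stage writes its outputs under `out_dir` and is
#' recorded in a manifest (file, md5 checksum), so a rerun with the same
#' configuration reproduces the checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_result`: the manifest data.frame plus
#'   the in-memory stage objects (`cohort`, `calls`, `ensemble`,
#'   `report`, `bias`).
#' @export
run_end_to_end <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage,
      file = sub(paste0(normalizePath(out_dir), .Platform$file.sep), "",
                 normalizePath(file), fixed = TRUE),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }

  # stage 1: cohort simulation
  cfg_cohort <- config$cohort
  cfg_cohort$seed <- substream_seed(config$seed, 1L)
  cohort <- simulate_cohort(cfg_cohort)
  write_counts(cohort$counts, file.path(out_dir, "counts.tsv"))
  utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("simulate", file.path(out_dir, "counts.tsv"))
  emit("simulate", file.path(out_dir, "truth.tsv"))

  # stage 2: ASE calling
  calls <- call_ase(cohort$counts, min_individuals = config$min_individuals,
                    fdr_threshold = config$fdr_threshold)
  write_ase_calls(calls, file.path(out_dir, "ase_calls.tsv"))
  emit("call_ase", file.path(out_dir, "ase_calls.tsv"))
  message(sprintf("tested %d loci (of %d simulated); %d called ASE",
                  nrow(calls), cfg_cohort$n_loci, sum(calls$is_ase)))

  # stage 3: feature matrix for tested loci, labelled by the ASE calls
  tested <- calls$locus_id[order(calls$locus_id)]
  truth <- cohort$truth$is_ase[match(tested, cohort$truth$locus_id)]
  names(truth) <- tested
  cfg_feat <- config$features
  cfg_feat$seed <- substream_seed(config$seed, 2L)
  fm <- impute_and_encode(simulate_feature_matrix(truth, cfg_feat))
  labels <- as.integer(calls$is_ase[match(tested, calls$locus_id)])
  write_feature_matrix(fm, file.path(out_dir, "features"))
  utils::write.table(data.frame(locus_id = tested, is_ase = labels),
                     file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("build_features", file.path(out_dir, "features.tsv"))
  emit("build_features", file.path(out_dir, "labels.tsv"))

  # stage 4: holdout split + nested-CV training
  cfg_train <- config$train
  cfg_train$seed <- substream_seed(config$seed, 3L)
  sp <- split_holdout(fm, labels, cfg_train$holdout_fraction, cfg_train$seed)
  ensemble <- train_nested_cv(sp$train$x, sp$train$labels, cfg_train)
  save_ensemble(ensemble, file.path(out_dir, "model"))
  imp <- feature_importance(ensemble)
  utils::write.table(imp, file.path(out_dir, "importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("train", file.path(out_dir, "importance.tsv"))
  emit("train", file.path(out_dir, "model", "ensemble.json"))

  # stage 5: holdout evaluation
  report <- evaluate_ensemble(ensemble, sp$test$x, sp$test$labels,
                              config$threshold)
  report_json <- list(
    auroc_mean = report$auroc_mean, auroc_sd = report$auroc_sd,
    per_fold_auroc = report$per_fold_auroc,
    ppv = report$ppv, npv = report$npv,
    sensitivity = report$sensitivity, specificity = report$specificity,
    counts = report$counts[c("tp", "fn", "fp", "tn", "threshold")])
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("evaluate", file.path(out_dir, "report.json"))

  # stage 6: bias test on the predicted ASE-SNVs
  bias <- NULL
  full_ase <- calls$locus_id[calls$is_ase]
  if (length(full_ase) >= 2L) {
    probs <- predict_proba(ensemble, as.matrix(fm)[match(full_ase, fm$row_ids), ,
                                                   drop = FALSE])
    predicted <- full_ase[probs >= config$threshold]
    if (length(predicted) >= 1L) {
      bcfg <- config$bias
      ann <- simulate_gene_annotation(bcfg$n_genes, bcfg$n_terms,
                                      bcfg$genes_per_term,
                                      seed = substream_seed(config$seed, 4L))
      gene_map <- data.frame(
        locus_id = tested,
        gene = ann$universe[((seq_along(tested) - 1L) %/% bcfg$loci_per_gene) %%
                              length(ann$universe) + 1L],
        stringsAsFactors = FALSE)
      bias <- rank_resampling_test(predicted, full_ase, gene_map, ann,
                                   n_resamples = bcfg$n_resamples,
                                   top_k = bcfg$top_k,
                                   seed = substream_seed(config$seed, 5L))
      write_bias_report(bias, file.path(out_dir, "bias_report.tsv"))
      emit("bias_test", file.path(out_dir, "bias_report.tsv"))
    } else message("bias test skipped: no ASE-SNV predicted at the threshold")
  } else message("bias test skipped: fewer than 2 called ASE-SNVs")

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(manifest = manifest, cohort = cohort, calls = calls,
                 ensemble = ensemble, report = report, bias = bias,
                 config = config, out_dir = out_dir),
            class = "pipeline_result")
}

#' Apply a trained model to a table of annotated variants
#'
#' Scores every variant with the ensemble and flags those whose
#' probability reaches the threshold. Pass-through annotation columns
#' (e.g. gene, allele frequency, consequence) supplied via `info` are
#' carried into the output; when a `gene` column is present, a per-gene
#' summary line `k out of N variants predicted ASE` is reported.
#'
#' @param ensemble an `ase_ensemble`.
#' @param fm a [feature_matrix()]; raw matrices are encoded with
#'   `encoders` (required in that case) so apply-time encoding matches
#'   training.
#' @param threshold probability threshold (default 0.5).
#' @param encoders training encoders for a raw (un-encoded) matrix.
#' @param info optional data.frame of pass-through columns with a
#'   `locus_id` column.
#' @return data.frame: `locus_id`, pass-through columns, `p_ase`,
#'   `predicted_ase`.
#' @export
apply_to_variants <- function(ensemble, fm, threshold = 0.5, encoders = NULL,
                              info = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$encoders)) {
    if (is.null(encoders)) {
      stop("raw matrix: supply the training encoders", call. = FALSE)
    }
    fm <- impute_and_encode(fm, encoders)
  }
  m <- as.matrix(fm)
  missing <- setdiff(ensemble$feature_names, colnames(m))
  if (length(missing)) {
    stop("annotation table lacks model features: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- m[, ensemble$feature_names, drop = FALSE]
  p <- predict_proba(ensemble, m)
  out <- data.frame(locus_id = fm$row_ids, stringsAsFactors = FALSE)
  if (!is.null(info)) {
    stopifnot("locus_id" %in% names(info))
    out <- cbind(out, info[match(out$locus_id, info$locus_id),
                           setdiff(names(info), "locus_id"), drop = FALSE])
  }
  out$p_ase <- p
  out$predicted_ase <- p >= threshold
  rownames(out) <- NULL
  if (!is.null(out$gene)) {
    for (g in unique(out$gene)) {
      sel <- out$gene == g
      message(sprintf("%s: %d out of %d variants predicted ASE",
                      g, sum(out$predicted_ase[sel]), sum(sel)))
    }
  }
  out
}
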