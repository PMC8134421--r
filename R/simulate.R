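#' Configuration for a synthetic allelic-count cohort
#'
#' Describes a cohort of heterozygous loci whose alternative-allele read
#' fractions are beta-binomially distributed: null loci centred at
#' `pi_null`, true-ASE loci with mean fractions drawn from
#' `pi_ase_distribution`, and a shared overdispersion `rho`.
#'
#' @param n_loci number of loci.
#' @param n_individuals_per_locus single integer (fixed) or length-2 range
#'   `c(min, max)` from which each locus's individual count is drawn
#'   uniformly; minimum 1.
#' @param depth_distribution total-read-count model per individual; a list
#'   with `type = "nbinom"` (shifted negative binomial, fields `mean`,
#'   `dispersion`, draws are `1 + NB(mean - 1, dispersion)` so depth >= 1)
#'   or `type = "fixed"` (field `value`). Default: mean 40, dispersion 5,
#'   resembling exome-coverage RNA read depths.
#' @param ase_fraction proportion of loci that truly show ASE, in \[0, 1\].
#' @param pi_null mean alternative fraction of null loci (default 0.5).
#' @param pi_ase_distribution per-ASE-locus mean fraction model: list with
#'   `type = "uniform_mirrored"` (fields `lo`, `hi`; drawn uniform on
#'   (lo, hi) then reflected to (1-hi, 1-lo) with probability 1/2, keeping
#'   ASE direction symmetric) or `type = "fixed"` (field `value`).
#' @param rho beta-binomial overdispersion, in (0, 1).
#' @param seed integer seed; all draws are reproducible from it. Per-locus
#'   substreams are derived by a counter scheme so any subset of loci is
#'   reproducible independent of iteration order.
#' @return validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_loci = 200L,
                              n_individuals_per_locus = c(20L, 60L),
                              depth_distribution = list(type = "nbinom", mean = 40, dispersion = 5),
                              ase_fraction = 0.15,
                              pi_null = 0.5,
                              pi_ase_distribution = list(type = "uniform_mirrored", lo = 0.6, hi = 0.95),
                              rho = 0.05,
                              seed = 1L) {
  if (!is.numeric(n_loci) || n_loci < 1) stop("invalid field n_loci", call. = FALSE)
  nip <- as.integer(n_individuals_per_locus)
  if (!length(nip) %in% 1:2 || any(nip < 1)) {
    stop("invalid field n_individuals_per_locus: need fixed value or range, min >= 1",
         call. = FALSE)
  }
  if (!is.numeric(ase_fraction) || ase_fraction < 0 || ase_fraction > 1) {
    stop("invalid field ase_fraction: must lie in [0, 1]", call. = FALSE)
  }
  check_interior(pi_null, "pi_null")
  check_interior(rho, "rho")
  validate_depth_spec(depth_distribution)
  validate_pi_ase_spec(pi_ase_distribution)
  structure(list(
    n_loci = as.integer(n_loci),
    n_individuals_per_locus = nip,
    depth_distribution = depth_distribution,
    ase_fraction = ase_fraction,
    pi_null = pi_null,
    pi_ase_distribution = pi_ase_distribution,
    rho = rho,
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

validate_depth_spec <- function(spec) {
  if (!is.list(spec) || is.null(spec$type)) {
    stop("invalid field depth_distribution: need list with a type", call. = FALSE)
  }
  if (spec$type == "nbinom") {
    if (is.null(spec$mean) || is.null(spec$dispersion) || spec$mean < 1 || spec$dispersion <= 0)
      stop("invalid field depth_distribution: nbinom needs mean >= 1, dispersion > 0",
           call. = FALSE)
  } else if (spec$type == "fixed") {
    if (is.null(spec$value) || spec$value < 1)
      stop("invalid field depth_distribution: fixed value must be >= 1", call. = FALSE)
  } else stop("invalid field depth_distribution: unknown type ", spec$type, call. = FALSE)
  invisible(spec)
}

validate_pi_ase_spec <- function(spec) {
  if (!is.list(spec) || is.null(spec$type)) {
    stop("invalid field pi_ase_distribution", call. = FALSE)
  }
  if (spec$type == "uniform_mirrored") {
    if (is.null(spec$lo) || is.null(spec$hi) || spec$lo <= 0.5 || spec$hi >= 1 || spec$lo >= spec$hi)
      stop("invalid field pi_ase_distribution: need 0.5 < lo < hi < 1", call. = FALSE)
  } else if (spec$type == "fixed") {
    check_interior(spec$value, "pi_ase_distribution$value")
    if (abs(spec$value - 0.5) < 1e-8)
      stop("invalid field pi_ase_distribution: fixed value must differ from 0.5", call. = FALSE)
  } else stop("invalid field pi_ase_distribution: unknown type ", spec$type, call. = FALSE)
  invisible(spec)
}

# Counter-based substream: a distinct, order-independent seed per locus.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 1000003) %% 2147483647)
}

draw_depths <- function(m, spec) {
  switch(spec$type,
         fixed = rep.int(as.integer(spec$value), m),
         nbinom = 1L + stats::rnbinom(m, size = spec$dispersion, mu = spec$mean - 1))
}

draw_pi_ase <- function(spec) {
  switch(spec$type,
         fixed = spec$value,
         uniform_mirrored = {
           p <- stats::runif(1, spec$lo, spec$hi)
           if (stats::runif(1) < 0.5) 1 - p else p
         })
}

#' Simulate an allelic-count cohort with known ASE ground truth
#'
#' Draws, for each locus, a set of individuals with total read depths from
#' the configured depth distribution and alternative-allele counts from a
#' beta-binomial with the locus's mean fraction (`pi_null` for null loci,
#' a draw from `pi_ase_distribution` for true-ASE loci) and shared
#' overdispersion. The number of true-ASE loci is `round(n_loci *
#' ase_fraction)`, assigned to random loci.
#'
#' @param config a [cohort_sim_config()].
#' @return list of class `simulated_cohort`: `counts` (allelic count table
#'   as used by [call_ase()]), `truth` (data.frame `locus_id`, `is_ase`,
#'   `true_pi`), and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  nl <- config$n_loci
  locus_ids <- sprintf("chr1:%d:A:G", 10000L + 100L * seq_len(nl))

  n_ase <- round(nl * config$ase_fraction)
  withr_seed(config$seed, {
    ase_flag <- rep(FALSE, nl)
    if (n_ase > 0) ase_flag[sample.int(nl, n_ase)] <- TRUE
  })

  per_locus <- vector("list", nl)
  true_pi <- numeric(nl)
  for (i in seq_len(nl)) {
    withr_seed(substream_seed(config$seed, i), {
      m <- if (length(config$n_individuals_per_locus) == 1L) {
        config$n_individuals_per_locus
      } else {
        sample(config$n_individuals_per_locus[1]:config$n_individuals_per_locus[2], 1L)
      }
      pi_i <- if (ase_flag[i]) draw_pi_ase(config$pi_ase_distribution) else config$pi_null
      depth <- draw_depths(m, config$depth_distribution)
      alt <- rbetabinom(m, depth, pi_i, config$rho)
      per_locus[[i]] <- data.frame(
        locus_id = locus_ids[i],
        individual_id = sprintf("ind%04d", seq_len(m)),
        ref_count = depth - alt,
        alt_count = alt,
        stringsAsFactors = FALSE)
      true_pi[i] <- pi_i
    })
  }

  structure(list(
    counts = do.call(rbind, per_locus),
    truth = data.frame(locus_id = locus_ids, is_ase = ase_flag,
                       true_pi = true_pi, stringsAsFactors = FALSE),
    config = config
  ), class = "simulated_cohort")
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Configuration for a synthetic annotation feature matrix
#'
#' @param n_features_numeric number of numeric feature columns.
#' @param n_features_categorical number of categorical feature columns
#'   (three levels each).
#' @param effect_vector per-feature effect size, length
#'   `n_features_numeric + n_features_categorical` (numeric features first).
#'   For a numeric feature the class-conditional mean is shifted by the
#'   effect for true-ASE rows; for a categorical feature the level
#'   probabilities are tilted towards later levels by the effect.
#' @param missing_rate probability that any one entry is missing, in
#'   \[0, 1); scalar or per-feature vector.
#' @param seed integer seed.
#' @return validated list of class `feature_sim_config`.
#' @export
feature_sim_config <- function(n_features_numeric = 10L,
                               n_features_categorical = 0L,
                               effect_vector = NULL,
                               missing_rate = 0,
                               seed = 1L) {
  p <- n_features_numeric + n_features_categorical
  if (p < 1) stop("need at least one feature", call. = FALSE)
  if (is.null(effect_vector)) effect_vector <- rep(0, p)
  if (length(effect_vector) != p) {
    stop(sprintf("effect_vector length %d does not match %d features",
                 length(effect_vector), p), call. = FALSE)
  }
  if (any(missing_rate < 0) || any(missing_rate >= 1)) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (!length(missing_rate) %in% c(1L, p)) {
    stop("missing_rate must be scalar or one value per feature", call. = FALSE)
  }
  structure(list(
    n_features_numeric = as.integer(n_features_numeric),
    n_features_categorical = as.integer(n_features_categorical),
    effect_vector = effect_vector,
    missing_rate = rep(missing_rate, length.out = p),
    seed = as.integer(seed)
  ), class = "feature_sim_config")
}

#' Simulate an annotation feature matrix with planted ASE signal
#'
#' Numeric feature `j` is N(0, 1) for non-ASE rows and N(effect_j, 1) for
#' ASE rows. Categorical features have three levels `lvlA < lvlB < lvlC`
#' whose probabilities are tilted towards the later levels for ASE rows in
#' proportion to the feature's effect. Entries are then masked missing at
#' `missing_rate`.
#'
#' @param truth logical vector of per-locus ASE labels, optionally named by
#'   locus id.
#' @param config a [feature_sim_config()].
#' @return an [feature_matrix()] object; the planted `effect_vector` is kept
#'   in `attr(x, "sim_effects")` for recovery tests.
#' @export
simulate_feature_matrix <- function(truth, config) {
  stopifnot(inherits(config, "feature_sim_config"))
  n <- length(truth)
  if (n == 0L) stop("truth labels are empty", call. = FALSE)
  row_ids <- names(truth)
  if (is.null(row_ids)) row_ids <- sprintf("locus%05d", seq_len(n))
  lab <- as.numeric(truth)

  p_num <- config$n_features_numeric
  p_cat <- config$n_features_categorical
  cols <- list()
  withr_seed(config$seed, {
    for (j in seq_len(p_num)) {
      cols[[sprintf("num%02d", j)]] <- stats::rnorm(n, mean = lab * config$effect_vector[j])
    }
    for (j in seq_len(p_cat)) {
      eff <- config$effect_vector[p_num + j]
      lv <- c("lvlA", "lvlB", "lvlC")
      base <- c(0.5, 0.3, 0.2)
      tilt <- base * exp(eff * c(-1, 0, 1))
      tilt <- tilt / sum(tilt)
      x <- character(n)
      x[lab == 0] <- sample(lv, sum(lab == 0), TRUE, prob = base)
      x[lab == 1] <- sample(lv, sum(lab == 1), TRUE, prob = tilt)
      cols[[sprintf("cat%02d", j)]] <- x
    }
    df <- data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
    for (j in seq_along(df)) {
      mr <- config$missing_rate[j]
      if (mr > 0) df[[j]][stats::runif(n) < mr] <- NA
    }
  })

  specs <- data.frame(
    name = names(df),
    kind = c(rep("numeric", p_num), rep("categorical", p_cat)),
    stringsAsFactors = FALSE)
  fm <- feature_matrix(df, row_ids = row_ids, specs = specs)
  attr(fm, "sim_effects") <- config$effect_vector
  fm
}

#' Simulate a gene-set collection (GMT-compatible)
#'
#' Builds a gene universe `GENE0001..` and random gene-set terms whose sizes
#' are drawn from `genes_per_term`. Optionally one extra term is planted to
#' be enriched in a designated gene subset, as a positive control for
#' over-representation tests.
#'
#' @param n_genes size of the gene universe.
#' @param n_terms number of random terms (may be 0, giving an empty
#'   collection).
#' @param genes_per_term length-2 integer range of term sizes.
#' @param seed integer seed.
#' @param planted_subset_size if not `NULL`, a subset of this many genes is
#'   designated and a term `TERM_PLANTED` is added drawing 80% of its genes
#'   from the subset.
#' @return list of class `gene_annotation`: `universe` (character),
#'   `gene_sets` (named list of character vectors), `planted_subset`
#'   (character or NULL).
#' @export
simulate_gene_annotation <- function(n_genes, n_terms, genes_per_term = c(5L, 25L),
                                     seed = 1L, planted_subset_size = NULL) {
  genes_per_term <- as.integer(genes_per_term)
  if (n_genes < max(genes_per_term)) {
    stop("n_genes must be >= the largest term size requested", call. = FALSE)
  }
  universe <- sprintf("GENE%04d", seq_len(n_genes))
  sets <- list()
  planted <- NULL
  withr_seed(seed, {
    for (t in seq_len(n_terms)) {
      sz <- sample(genes_per_term[1]:genes_per_term[2], 1L)
      sets[[sprintf("TERM%03d", t)]] <- sort(sample(universe, sz))
    }
    if (!is.null(planted_subset_size)) {
      if (planted_subset_size > n_genes) {
        stop("planted_subset_size exceeds the gene universe", call. = FALSE)
      }
      planted <- sort(sample(universe, planted_subset_size))
      sz <- max(genes_per_term)
      n_in <- ceiling(0.8 * sz)
      sets[["TERM_PLANTED"]] <- sort(c(
        sample(planted, min(n_in, length(planted))),
        sample(setdiff(universe, planted), sz - min(n_in, length(planted)))))
    }
  })
  structure(list(universe = universe, gene_sets = sets, planted_subset = planted),
            class = "gene_annotation")
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member gene symbols.
#'
#' @param gene_sets named list of character vectors (or a `gene_annotation`).
#' @param path file path.
#' @name gmt_io
#' @export
write_gmt <- function(gene_sets, path) {
  if (inherits(gene_sets, "gene_annotation")) gene_sets <- gene_sets$gene_sets
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gmt_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}
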