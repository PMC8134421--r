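# Independent oracles used across the suite. Each recomputes a quantity by
# a route different from the package implementation.

# beta-binomial log PMF via raw log-gamma identities (no lbeta/lchoose)
oracle_betabin_logpmf <- function(k, n, pi, rho) {
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
    lgamma(k + a) + lgamma(n - k + b) - lgamma(n + a + b) +
    lgamma(a + b) - lgamma(a) - lgamma(b)
}

# beta-binomial PMF by numeric integration of the binomial over the beta
# mixing density
oracle_betabin_pmf_integral <- function(k, n, pi, rho) {
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  stats::integrate(function(p) choose(n, k) * p^k * (1 - p)^(n - k) * stats::dbeta(p, a, b),
                   0, 1, rel.tol = 1e-12)$value
}

# maximized log-likelihood by exhaustive grid search; fix_pi restricts the
# search to the overdispersion axis
oracle_grid_loglik <- function(k, n, fix_pi = NULL, grid_n = 300) {
  ax <- seq(1e-6, 1 - 1e-6, length.out = grid_n)
  if (is.null(fix_pi)) {
    g <- expand.grid(pi = ax, rho = ax)
  } else {
    g <- data.frame(pi = fix_pi, rho = ax)
  }
  ll <- 0
  for (i in seq_along(k)) {
    ll <- ll + oracle_betabin_logpmf(k[i], n[i], g$pi, g$rho)
  }
  max(ll)
}

# Benjamini-Hochberg step-up written from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(p[o][i:n] * n / (i:n), 1)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# AUROC by brute-force concordance over all positive/negative pairs
oracle_auc_pairs <- function(probs, labels) {
  y <- as.logical(labels)
  pos <- probs[y]; neg <- probs[!y]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(x, term_size, background_size, query_size) {
  xs <- x:min(term_size, query_size)
  sum(choose(term_size, xs) * choose(background_size - term_size, query_size - xs)) /
    choose(background_size, query_size)
}

# small labelled feature matrix + ensemble for classifier/evaluation tests
make_toy_model <- function(n = 400, seed = 42, effect = 2, outer_folds = 3) {
  truth <- rep(c(TRUE, FALSE), length.out = n)
  fcfg <- feature_sim_config(n_features_numeric = 4,
                             effect_vector = c(effect, 0, 0, 0), seed = seed)
  fm <- impute_and_encode(simulate_feature_matrix(truth, fcfg))
  ens <- train_nested_cv(fm, truth,
                         train_config(n_boost_iterations = 30,
                                      outer_folds = outer_folds, seed = seed))
  list(fm = fm, truth = truth, ensemble = ens)
}

# gene map assigning consecutive SNVs to genes round-robin
make_gene_map <- function(snvs, genes, per_gene = 3) {
  data.frame(locus_id = snvs,
             gene = genes[((seq_along(snvs) - 1) %/% per_gene) %% length(genes) + 1],
             stringsAsFactors = FALSE)
}
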