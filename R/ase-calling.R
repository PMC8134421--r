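#' Beta-binomial log-likelihood for a locus
#'
#' Sums the beta-binomial log probability mass over all individuals observed
#' at one heterozygous locus. Computed via log-gamma functions so that large
#' read depths stay numerically stable.
#'
#' @param counts a data.frame or list with components `k` (alternative-allele
#'   reads) and `n` (total reads), one entry per individual. An empty set of
#'   counts has log-likelihood 0.
#' @param pi mean alternative-allele fraction in (0, 1).
#' @param rho overdispersion in (0, 1).
#' @return scalar log-likelihood.
#' @export
betabin_loglik <- function(counts, pi, rho) {
  check_interior(pi, "pi")
  check_interior(rho, "rho")
  k <- counts$k
  n <- counts$n
  if (length(k) == 0L) return(0)
  bad <- which(k > n | k < 0)
  if (length(bad)) {
    stop(sprintf("invalid record %d: k = %d > n = %d (or k < 0)",
                 bad[1], k[bad[1]], n[bad[1]]), call. = FALSE)
  }
  sum(dbetabinom(k, n, pi, rho, log = TRUE))
}

PARAM_LO <- 1e-6
PARAM_HI <- 1 - 1e-6

#' Maximum-likelihood beta-binomial fit for one locus
#'
#' Aggregates all individuals' allelic counts at a locus by maximizing the
#' beta-binomial likelihood over the mean fraction `pi` and overdispersion
#' `rho`, within bounds \[1e-6, 1 - 1e-6\]. Initialization uses the pooled
#' alternative fraction for `pi` and a moment-based overdispersion estimate;
#' on non-convergence two random restarts are attempted and the best fit
#' returned with `converged = FALSE` if all fail.
#'
#' @param counts data.frame/list with `k` and `n` per individual (>= 1 row).
#' @param fix_pi if supplied, `pi` is held at this interior value and only
#'   `rho` is estimated (the balanced null uses `fix_pi = 0.5`).
#' @return an object of class `betabin_fit`: list with `pi_hat`, `rho_hat`,
#'   `loglik`, `converged`, `n_individuals`.
#' @export
fit_locus <- function(counts, fix_pi = NULL) {
  k <- as.numeric(counts$k)
  n <- as.numeric(counts$n)
  if (length(k) < 1L) stop("at least one record required", call. = FALSE)
  if (!is.null(fix_pi)) check_interior(fix_pi, "fix_pi")

  clamp <- function(x) pmin(pmax(x, PARAM_LO), PARAM_HI)
  pi0 <- clamp(sum(k) / sum(n))
  rho0 <- clamp(moment_rho(k, n))

  if (!is.null(fix_pi)) {
    # one free parameter: Brent search, fully deterministic
    nll1 <- function(rho) -betabin_loglik(list(k = k, n = n), fix_pi, rho)
    opt <- stats::optimize(nll1, c(PARAM_LO, PARAM_HI), tol = 1e-9)
    return(structure(list(
      pi_hat = fix_pi, rho_hat = opt$minimum, loglik = -opt$objective,
      converged = TRUE, n_individuals = length(k)
    ), class = "betabin_fit"))
  }

  nll <- function(par) -betabin_loglik(list(k = k, n = n), par[1], par[2])
  # fixed extra starts keep the fit deterministic on non-convergence
  starts <- list(c(pi0, rho0), c(0.5, 0.05), c(pi0, 0.3))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = c(PARAM_LO, PARAM_LO), upper = c(PARAM_HI, PARAM_HI),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value ||
        (opt$convergence == 0L && best$convergence != 0L && opt$value <= best$value + 1e-8)) {
      best <- opt
    }
    if (opt$convergence == 0L && identical(opt$value, best$value)) break
  }
  if (is.null(best)) {
    best <- list(par = c(pi0, rho0), value = nll(c(pi0, rho0)), convergence = 1L)
  }
  if (best$convergence != 0L) {
    # polish on the logit scale with Nelder-Mead, which has no line search
    # to fail near the boundary
    nll_logit <- function(q) nll(clamp(stats::plogis(q)))
    nm <- tryCatch(
      stats::optim(stats::qlogis(clamp(best$par)), nll_logit,
                   method = "Nelder-Mead", control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(nm) && nm$convergence == 0L && nm$value <= best$value + 1e-6) {
      par <- clamp(stats::plogis(nm$par))
      if (nm$value > best$value) { par <- best$par; nm$value <- best$value }
      best <- list(par = par, value = nm$value, convergence = 0L)
    }
  }
  structure(list(
    pi_hat = best$par[1],
    rho_hat = best$par[2],
    loglik = -best$value,
    converged = identical(best$convergence, 0L),
    n_individuals = length(k)
  ), class = "betabin_fit")
}

# Method-of-moments overdispersion: chi-square inflation of per-individual
# counts around the pooled fraction, mapped through the beta-binomial
# variance inflation factor 1 + (n - 1) * rho.
moment_rho <- function(k, n) {
  p <- sum(k) / sum(n)
  p <- min(max(p, 1e-3), 1 - 1e-3)
  if (length(k) < 2L) return(0.01)
  s2 <- sum((k - n * p)^2 / (n * p * (1 - p))) / (length(k) - 1)
  nbar <- mean(n)
  if (nbar <= 1) return(0.01)
  min(max((s2 - 1) / (nbar - 1), 1e-4), 0.5)
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat(sprintf("beta-binomial fit: pi_hat = %.4f, rho_hat = %.4f, loglik = %.3f (%s, %d individuals)\n",
              x$pi_hat, x$rho_hat, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_individuals))
  invisible(x)
}

#' Likelihood-ratio test for allelic imbalance at one locus
#'
#' Compares the balanced null (`pi` fixed at 0.5, overdispersion free)
#' against the alternative with both parameters free. The statistic
#' `max(0, 2 * (LL_alt - LL_null))` is referred to a chi-square distribution
#' with one degree of freedom; clipping at zero absorbs tiny negative values
#' a bounded optimizer can produce when the null is true.
#'
#' @inheritParams fit_locus
#' @return list with `lrt_stat`, `p_value`, `null_fit`, `alt_fit`,
#'   `converged` (TRUE only if both fits converged; otherwise `p_value` is
#'   `NA` and the locus is excluded from FDR control downstream).
#' @export
lrt_test <- function(counts) {
  null_fit <- fit_locus(counts, fix_pi = 0.5)
  alt_fit <- fit_locus(counts)
  ok <- null_fit$converged && alt_fit$converged
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  list(
    lrt_stat = stat,
    p_value = if (ok) stats::pchisq(stat, df = 1, lower.tail = FALSE) else NA_real_,
    null_fit = null_fit,
    alt_fit = alt_fit,
    converged = ok
  )
}

#' Call ASE across a cohort of heterozygous loci
#'
#' For every locus observed in at least `min_individuals` individuals, all
#' allelic counts are aggregated under the beta-binomial model and tested
#' for allelic imbalance with [lrt_test()]. P-values are adjusted across all
#' tested loci with the Benjamini-Hochberg step-up procedure and loci with
#' an adjusted value below `fdr_threshold` are flagged as ASE.
#'
#' Records with zero total reads are dropped (with a message reporting how
#' many); loci observed in fewer than `min_individuals` individuals are
#' excluded before testing.
#'
#' @param table allelic count table: data.frame with columns `locus_id`,
#'   `individual_id`, `ref_count`, `alt_count` (one row per locus/individual
#'   pair; pairs must be unique).
#' @param min_individuals minimum number of individuals per locus (default 5).
#' @param fdr_threshold FDR level for the ASE flag (default 0.05).
#' @return data.frame of class `ase_calls`, one row per tested locus, sorted
#'   by p-value then locus id: `locus_id`, `n_individuals`, `pi_hat`,
#'   `rho_hat`, `lrt_stat`, `p_value`, `q_value`, `is_ase`.
#' @export
call_ase <- function(table, min_individuals = 5L, fdr_threshold = 0.05) {
  req <- c("locus_id", "individual_id", "ref_count", "alt_count")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("count table lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(table) == 0L) stop("count table is empty", call. = FALSE)
  key <- paste(table$locus_id, table$individual_id)
  if (anyDuplicated(key)) stop("duplicated (locus, individual) pairs", call. = FALSE)

  tot <- table$ref_count + table$alt_count
  if (any(tot == 0L)) {
    message(sum(tot == 0L), " record(s) with zero total reads dropped")
    table <- table[tot > 0L, , drop = FALSE]
  }

  split_idx <- split(seq_len(nrow(table)), table$locus_id)
  n_ind <- lengths(split_idx)
  keep <- n_ind >= min_individuals
  if (!any(keep)) {
    warning("no locus passes the minimum-individuals filter; empty result")
    return(empty_ase_calls())
  }
  split_idx <- split_idx[keep]

  rows <- lapply(names(split_idx), function(loc) {
    idx <- split_idx[[loc]]
    counts <- list(k = table$alt_count[idx], n = tot_reads(table, idx))
    res <- lrt_test(counts)
    data.frame(locus_id = loc,
               n_individuals = length(idx),
               pi_hat = res$alt_fit$pi_hat,
               rho_hat = res$alt_fit$rho_hat,
               lrt_stat = res$lrt_stat,
               p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$is_ase <- !is.na(out$q_value) & out$q_value < fdr_threshold
  out <- out[order(out$p_value, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ase_calls", "data.frame")
  out
}

tot_reads <- function(table, idx) table$ref_count[idx] + table$alt_count[idx]

empty_ase_calls <- function() {
  out <- data.frame(locus_id = character(), n_individuals = integer(),
                    pi_hat = numeric(), rho_hat = numeric(),
                    lrt_stat = numeric(), p_value = numeric(),
                    q_value = numeric(), is_ase = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("ase_calls", "data.frame")
  out
}

#' Read / write allelic count tables and ASE call tables
#'
#' Tab-separated formats: count tables have header
#' `locus_id individual_id ref_count alt_count`; call tables have the
#' columns produced by [call_ase()].
#'
#' @param path file path.
#' @param x table to write.
#' @name ase_io
#' @export
read_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer", "integer"))
}

#' @rdname ase_io
#' @export
write_counts <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ase_io
#' @export
write_ase_calls <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
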