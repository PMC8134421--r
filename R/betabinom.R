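#' Beta-binomial distribution, mean/overdispersion parameterization
#'
#' The allelic read count k out of n total reads at a heterozygous locus is
#' modelled as beta-binomial with mean alternative-allele fraction `pi` and
#' overdispersion `rho`. The shape parameters of the mixing beta are
#' `alpha = pi * (1 - rho) / rho` and `beta = (1 - pi) * (1 - rho) / rho`,
#' so that `E[k/n] = pi` and `Var[k] = n * pi * (1 - pi) * (1 + (n - 1) * rho)`.
#' This parameterization makes the balanced-expression null a single
#' constraint, `pi = 0.5`.
#'
#' @param k integer vector of alternative-allele read counts.
#' @param n integer vector of total read counts (recycled against `k`).
#' @param pi mean alternative-allele fraction, strictly inside (0, 1).
#' @param rho overdispersion, strictly inside (0, 1).
#' @param log logical; return log density?
#'
#' @return `dbetabinom` returns the (log) probability mass; `rbetabinom`
#'   returns random counts.
#' @examples
#' dbetabinom(4, 10, pi = 0.5, rho = 0.1)
#' sum(dbetabinom(0:10, 10, 0.3, 0.2)) # == 1
#' @export
dbetabinom <- function(k, n, pi, rho, log = FALSE) {
  check_interior(pi, "pi")
  check_interior(rho, "rho")
  if (any(k < 0) || any(k > n)) {
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  }
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  lp <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

#' @rdname dbetabinom
#' @param m number of draws.
#' @export
rbetabinom <- function(m, n, pi, rho) {
  check_interior(pi, "pi")
  check_interior(rho, "rho")
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  p <- stats::rbeta(m, a, b)
  stats::rbinom(m, n, p)
}

check_interior <- function(x, name, lo = 0, hi = 1) {
  if (any(!is.finite(x)) || any(x <= lo) || any(x >= hi)) {
    stop(sprintf("%s must lie strictly inside (%g, %g)", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
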