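# Marginal likelihood of the expression data given a partition.
#
# Genes in a group are modelled as zero-mean multivariate normal across
# samples with covariance Sigma_k, given an inverse-Wishart prior
# IW(Psi_k, m_k) with Psi_k = rho_k * I and m_k = n_k + 2. Integrating
# Sigma_k out gives a closed form per group:
#
#   log P(X_k) = (m_k/2) log|Psi_k| + log Gamma_{n_k}((m_k + N)/2)
#              - (N n_k / 2) log pi
#              - ((m_k + N)/2) log|Psi_k + X_k' X_k|
#              - log Gamma_{n_k}(m_k / 2)
#
# and groups are independent, so the total is the sum over groups. The
# m_k = n_k + 2, rho_k = 1 choice encodes unit prior variance for
# standardized expression; standardization is therefore mandatory.

#' Standardize expression columns
#'
#' Centres each gene to mean zero and scales to unit variance
#' (denominator N - 1). Idempotent.
#'
#' @param x numeric matrix, samples in rows, genes in columns.
#' @return matrix of the same shape with attribute
#'   \code{standardized = TRUE}.
#' @export
standardize_expression <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be numeric without NA")
  if (nrow(x) < 2L) stop("at least 2 samples required to standardize")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant gene(s) cannot be standardized: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

.is_standardized <- function(x, tol = 1e-6) {
  isTRUE(attr(x, "standardized")) ||
    (max(abs(colMeans(x))) < tol &&
       max(abs(apply(x, 2L, stats::sd) - 1)) < tol)
}

#' Log multivariate gamma function
#'
#' log Gamma_p(a) = p(p-1)/4 * log(pi) + sum_{i=1..p} log Gamma(a + (1-i)/2).
#'
#' @param p dimension (positive integer).
#' @param a argument; must exceed (p - 1)/2.
#' @return log Gamma_p(a).
#' @export
log_multivariate_gamma <- function(p, a) {
  if (!is.numeric(p) || length(p) != 1L || p < 1) stop("'p' must be >= 1")
  p <- as.integer(p)
  if (!is.numeric(a) || length(a) != 1L || a <= (p - 1) / 2)
    stop("'a' must exceed (p - 1)/2")
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' Log marginal likelihood of one group
#'
#' @param X_k numeric matrix: N samples x n_k genes of one group (columns
#'   taken from a standardized expression matrix). N = 0 rows gives 0.
#' @param rho prior covariance scale (Psi_k = rho * I; default 1).
#' @param m prior sharpness; default n_k + 2 (the minimal value encoding
#'   standardized data with a defined prior expectation).
#' @return log marginal likelihood of the group.
#' @export
log_marginal_likelihood_group <- function(X_k, rho = 1, m = NULL) {
  X_k <- as.matrix(X_k)
  nk <- ncol(X_k)
  N <- nrow(X_k)
  if (nk < 1L) stop("group must contain at least one gene")
  if (is.null(m)) m <- nk + 2
  if (m <= nk + 1) stop("'m' must exceed n_k + 1")
  if (rho <= 0) stop("'rho' must be positive")
  if (N == 0L) return(0)
  # log|rho I + X'X|: when n_k > N use |rho I_nk + X'X| =
  # rho^(nk - N) |rho I_N + X X'| (Weinstein-Aronszajn), keeping the
  # Cholesky at min(nk, N) and guaranteed positive definite
  if (nk <= N) {
    G <- crossprod(X_k)
    ld <- 2 * sum(log(diag(chol(diag(rho, nk) + G))))
  } else {
    G <- tcrossprod(X_k)
    ld <- (nk - N) * log(rho) + 2 * sum(log(diag(chol(diag(rho, N) + G))))
  }
  (m / 2) * nk * log(rho) +
    log_multivariate_gamma(nk, (m + N) / 2) -
    (N * nk / 2) * log(pi) -
    ((m + N) / 2) * ld -
    log_multivariate_gamma(nk, m / 2)
}

#' Log marginal likelihood of a partition
#'
#' Sum of \code{\link{log_marginal_likelihood_group}} over the groups of
#' \code{labels}. Genes in different groups are independent under the
#' model, so the total is additive over groups.
#'
#' @param x standardized expression matrix (samples x genes); see
#'   \code{\link{standardize_expression}}.
#' @param labels group membership vector, one entry per gene (column).
#' @param rho prior covariance scale, default 1.
#' @return log P(D | g).
#' @export
log_marginal_likelihood <- function(x, labels, rho = 1) {
  x <- as.matrix(x)
  if (length(labels) != ncol(x))
    stop("'labels' length must equal the number of genes (columns)")
  if (!.is_standardized(x))
    stop("'x' must be standardized (mean 0, variance 1 per gene); ",
         "the m_k = n_k + 2 prior encodes this")
  g <- canonical_labels(labels)
  sum(vapply(seq_len(max(g)), function(k) {
    log_marginal_likelihood_group(x[, g == k, drop = FALSE], rho = rho)
  }, numeric(1)))
}
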