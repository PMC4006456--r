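# Independent oracles used across tests. These deliberately avoid the
# package's own computational shortcuts: brute-force enumeration and
# direct summation only.

# number of partitions of n items into K groups by exhaustive enumeration
enumerate_partition_count <- function(n, K) {
  sum(vapply(all_partitions(n), function(g) max(g) == K, logical(1)))
}

# literal 2^q mask enumeration of the informative prior (no factoring)
brute_force_log_prior <- function(labels, pairs_df, genes) {
  labels <- canonical_labels(labels)
  n <- length(genes)
  K <- max(labels)
  q <- nrow(pairs_df)
  ia <- match(pairs_df$gene_a, genes)
  ib <- match(pairs_df$gene_b, genes)
  p <- pmin(pairs_df$p, 1 - 1e-12)
  tot <- 0
  for (mask in seq_len(2^q) - 1L) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(q) - 1L)))
    w <- prod(ifelse(on, p, 1 - p))
    x <- sum(on)
    compatible <- all(labels[ia[on]] == labels[ib[on]])
    if (compatible && K <= n - x)
      tot <- tot + w * exp(-log(n - x) - log_partition_count(n - x, K))
  }
  log(tot)
}

# quadrature oracle for the 1-gene marginal likelihood (scaled
# inverse-chi-square integral, Psi = 1, m = 3)
quadrature_log_marginal_1d <- function(x) {
  N <- length(x)
  S <- sum(x^2)
  f <- function(s2) {
    exp(-N / 2 * log(2 * pi * s2) - S / (2 * s2)) *
      (1 / (2^(3 / 2) * gamma(3 / 2))) * s2^(-(3 / 2 + 1)) *
      exp(-1 / (2 * s2))
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value)
}

# exact posterior over all partitions of a small instance
enumerate_posterior <- function(xs, prior) {
  n <- ncol(xs)
  parts <- all_partitions(n)
  lp <- vapply(parts, function(g) {
    pri <- if (is.null(prior)) log_baseline_prior(g)
           else log_prior_exact(g, prior)
    log_marginal_likelihood(xs, g) + pri
  }, numeric(1))
  w <- exp(lp - max(lp))
  list(partitions = parts, prob = w / sum(w),
       keys = vapply(parts, paste, character(1), collapse = ","))
}

# small correlated five-gene dataset used by several sampler tests
make_small_dataset <- function(N = 20) {
  z <- matrix(stats::rnorm(N * 3), N, 3)
  x <- cbind(z[, 1] + stats::rnorm(N, 0, 0.3),
             z[, 1] + stats::rnorm(N, 0, 0.3),
             z[, 2],
             z[, 2] + stats::rnorm(N, 0, 0.4),
             z[, 3])
  xs <- standardize_expression(x)
  colnames(xs) <- paste0("g", 1:5)
  xs
}
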