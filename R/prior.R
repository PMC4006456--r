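# Informative prior over partitions from pairwise "must-link" knowledge.
#
# A prior pair (i, j, p) forces genes i and j into the same group with
# probability p. With q pairs the prior is a 2^q-component mixture: each
# enforcement mask X in {0,1}^q forces the pairs with X_m = 1 together,
# merging the n genes into n - x units (x = sum X), and places the baseline
# measure on partitions of those units:
#
#   P(g | M) = sum_X prod_m p_m^X_m (1-p_m)^(1-X_m)
#              * I(K_g <= n-x, all forced pairs co-grouped in g)
#              / ((n-x) N(n-x, K_g)).
#
# The unit-count n - x is only valid when the enforced edges never close a
# cycle, which is why the pair set must be a forest (see remove_cycles).

#' Build a validated prior-pair set
#'
#' @param pairs data frame with columns \code{gene_a}, \code{gene_b},
#'   \code{p} (enforcement probability) and optionally \code{source}.
#' @param genes character vector of the full gene universe. All pair
#'   members must belong to it.
#' @param require_forest if TRUE (default) error on cyclic input; run
#'   \code{\link{remove_cycles}} first for raw database extracts.
#' @return an object of class \code{prior_set}: list with \code{pairs}
#'   (data frame), \code{genes}, and integer index columns \code{ia},
#'   \code{ib} into \code{genes}. Probabilities equal to 1 are clamped to
#'   1 - 1e-12 so mixture weights (1-p) stay positive; a truly certain
#'   pair is better expressed by merging the genes before analysis.
#' @export
prior_set <- function(pairs, genes, require_forest = TRUE) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicated gene identifiers in 'genes'")
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                        p = numeric(0), source = character(0),
                        stringsAsFactors = FALSE)
  }
  need <- c("gene_a", "gene_b", "p")
  if (!all(need %in% names(pairs)))
    stop("'pairs' must have columns gene_a, gene_b, p")
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  if (is.null(pairs$source)) pairs$source <- rep("unknown", nrow(pairs))
  if (any(pairs$gene_a == pairs$gene_b))
    stop("self-pair (gene_a == gene_b) in prior pairs")
  if (any(pairs$p < 0 | pairs$p > 1) || anyNA(pairs$p))
    stop("prior probabilities must lie in [0, 1]")
  pairs$p <- pmin(pairs$p, 1 - 1e-12)
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)]))
    stop("prior pair gene(s) not in gene universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  if (anyDuplicated(key))
    stop("duplicate unordered prior pairs; merge duplicates first ",
         "(merge_prior_sources keeps the maximum probability)")
  if (require_forest && nrow(pairs) > 0L && .has_cycle(ia, ib, length(genes)))
    stop("prior pairs contain a cycle; apply remove_cycles() first")
  structure(list(pairs = pairs, genes = genes,
                 ia = as.integer(ia), ib = as.integer(ib)),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat("Prior pair set:", nrow(x$pairs), "pair(s) over", length(x$genes),
      "genes\n")
  if (nrow(x$pairs) > 0L) {
    cat("  sources:", paste(names(table(x$pairs$source)), collapse = ", "),
        "\n  p range: [", format(min(x$pairs$p), digits = 3), ",",
        format(max(x$pairs$p), digits = 3), "]\n")
  }
  invisible(x)
}

# union-find with path compression
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.has_cycle <- function(ia, ib, n) {
  parent <- .uf_new(n)
  for (m in seq_along(ia)) {
    ra <- .uf_find(parent, ia[m]); rb <- .uf_find(parent, ib[m])
    if (ra == rb) return(TRUE)
    parent[ra] <- rb
  }
  FALSE
}

#' Remove cycles from a set of prior pairs
#'
#' Repeatedly deleting the smallest-probability edge of any remaining
#' cycle leaves the maximum-weight spanning forest, so this is implemented
#' as Kruskal's algorithm: edges are taken in decreasing p (stable input
#' order on ties) and kept only when they join two distinct components.
#'
#' @param pairs data frame with columns gene_a, gene_b, p (and optionally
#'   source); duplicates must already be merged.
#' @return list with \code{kept} and \code{removed} data frames.
#' @export
remove_cycles <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(kept = pairs, removed = pairs))
  genes <- unique(c(as.character(pairs$gene_a), as.character(pairs$gene_b)))
  ia <- match(as.character(pairs$gene_a), genes)
  ib <- match(as.character(pairs$gene_b), genes)
  ord <- order(-pairs$p)            # stable: ties keep input order
  parent <- .uf_new(length(genes))
  keep <- logical(nrow(pairs))
  for (m in ord) {
    ra <- .uf_find(parent, ia[m]); rb <- .uf_find(parent, ib[m])
    if (ra != rb) { keep[m] <- TRUE; parent[ra] <- rb }
  }
  list(kept = pairs[keep, , drop = FALSE],
       removed = pairs[!keep, , drop = FALSE])
}

#' Probability that two genes are forced together
#'
#' Enumerates all 2^q enforcement masks of the given pairs and sums the
#' probability of those whose enforced edges connect \code{a} and
#' \code{b}. This is the "forcing" probability only; the baseline measure
#' is disregarded. With the all-0.8 triangle A-B, B-C, A-C, the force
#' probability for (A, B) is 0.8 + 0.2*(0.8*0.8) = 0.928 — the reason
#' cyclic prior sets are disallowed: the pairwise p would no longer be
#' interpretable as the forcing probability.
#'
#' @param pairs data frame with gene_a, gene_b, p (cycles allowed here).
#' @param a,b gene identifiers to query.
#' @return a probability.
#' @export
pair_force_probability <- function(pairs, a, b) {
  q <- nrow(pairs)
  if (q > 20L) stop("enumeration over 2^q masks refused for q > 20")
  genes <- unique(c(as.character(pairs$gene_a), as.character(pairs$gene_b),
                    as.character(a), as.character(b)))
  ia <- match(as.character(pairs$gene_a), genes)
  ib <- match(as.character(pairs$gene_b), genes)
  ta <- match(as.character(a), genes); tb <- match(as.character(b), genes)
  if (q == 0L) return(0)
  p <- pairs$p
  total <- 0
  for (mask in 0:(2^q - 1L)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(q) - 1L)))
    w <- prod(ifelse(on, p, 1 - p))
    parent <- .uf_new(length(genes))
    for (m in which(on)) {
      ra <- .uf_find(parent, ia[m]); rb <- .uf_find(parent, ib[m])
      if (ra != rb) parent[ra] <- rb
    }
    if (.uf_find(parent, ta) == .uf_find(parent, tb)) total <- total + w
  }
  total
}

#' Total prior co-grouping probability of a pair
#'
#' The prior pair probability p is the probability the pair is *forced*
#' together; even unforced, the pair can be co-grouped under the baseline
#' measure with probability P_b, giving the mixture p + (1-p) * P_b.
#'
#' @param p enforcement probability in [0, 1].
#' @param P_b baseline co-grouping probability in [0, 1]
#'   (see \code{\link{baseline_pair_probability}}).
#' @return the total probability the pair ends up co-grouped a priori.
#' @export
total_pair_prior_probability <- function(p, P_b) {
  if (any(p < 0 | p > 1) || any(P_b < 0 | P_b > 1))
    stop("'p' and 'P_b' must lie in [0, 1]")
  p + (1 - p) * P_b
}

# indices (into prior$pairs) of pairs whose two genes share a group in g
.cogrouped_pairs <- function(labels, prior) {
  if (length(prior$ia) == 0L) return(integer(0))
  which(labels[prior$ia] == labels[prior$ib])
}

#' Exact log informative prior of a partition
#'
#' Evaluates the 2^q mixture exactly. Pairs whose genes are split in
#' \code{labels} can only appear unenforced and contribute the scalar
#' factor (1 - p_m); over the co-grouped pairs S, every enforcement subset
#' is a forest (the pair set is), so a mask with x enforced pairs always
#' merges the genes into n - x units and its partition term depends on x
#' only. The sum therefore collapses to a Poisson-binomial expectation
#'
#'   prod_{m not in S} (1 - p_m) *
#'   sum_x P_PB(x) I(K_g <= n-x) / ((n-x) N(n-x, K_g)),
#'
#' computed by an O(|S|^2) convolution — identical to full mask
#' enumeration but polynomial in q.
#'
#' @param labels group membership vector.
#' @param prior a \code{\link{prior_set}} (must be a forest).
#' @return log P(g | M).
#' @export
log_prior_exact <- function(labels, prior) {
  stopifnot(inherits(prior, "prior_set"))
  g <- canonical_labels(labels)
  n <- length(g)
  if (n != length(prior$genes))
    stop("length of 'labels' does not match the prior's gene universe")
  K <- max(g)
  p <- prior$pairs$p
  S <- .cogrouped_pairs(g, prior)
  off <- sum(log1p(-p[setdiff(seq_along(p), S)]))
  pb_w <- .poisson_binomial(p[S])       # weights over x = 0..|S|
  xs <- seq_along(pb_w) - 1L
  L <- partition_count_table(n)
  ok <- (n - xs) >= K & pb_w > 0
  if (!any(ok)) return(-Inf)
  terms <- log(pb_w[ok]) - log(n - xs[ok]) - L[cbind(n - xs[ok], K)]
  m <- max(terms)
  off + m + log(sum(exp(terms - m)))
}

# Poisson-binomial pmf over the number of successes of independent
# Bernoulli(p_i); returns vector of length(p)+1 (x = 0..q)
.poisson_binomial <- function(p) {
  w <- 1
  for (pi in p) w <- c(w * (1 - pi), 0) + c(0, w * pi)
  w
}

#' Monte-Carlo estimate of the log informative prior
#'
#' Unbiased estimator of the same mixture sum as
#' \code{\link{log_prior_exact}}: pairs split in \code{labels} are
#' factored out deterministically (variance reduction; the estimate is
#' exact when no prior pair is co-grouped), and enforcement masks over the
#' co-grouped pairs are drawn from their Bernoulli prior, averaging the
#' partition term I(K_g <= n-x) / ((n-x) N(n-x, K_g)).
#'
#' Uses the current R random-number state; call \code{set.seed} for
#' reproducibility.
#'
#' @param labels group membership vector.
#' @param prior a \code{\link{prior_set}}.
#' @param n_samples number of Bernoulli mask draws (default 200).
#' @return log of the estimate of P(g | M).
#' @export
log_prior_mc <- function(labels, prior, n_samples = 200) {
  stopifnot(inherits(prior, "prior_set"))
  if (!is.numeric(n_samples) || n_samples < 1) stop("'n_samples' must be >= 1")
  n_samples <- as.integer(n_samples)
  g <- canonical_labels(labels)
  n <- length(g)
  K <- max(g)
  p <- prior$pairs$p
  S <- .cogrouped_pairs(g, prior)
  off <- if (length(p)) sum(log1p(-p[setdiff(seq_along(p), S)])) else 0
  if (length(S) == 0L)
    return(off - log(n) - log_partition_count(n, K))
  pS <- p[S]
  draws <- matrix(stats::runif(n_samples * length(pS)), n_samples) <
    matrix(pS, n_samples, length(pS), byrow = TRUE)
  x <- rowSums(draws)
  L <- partition_count_table(n)
  lterm <- rep(-Inf, n_samples)
  ok <- (n - x) >= K
  lterm[ok] <- -log(n - x[ok]) - L[cbind(n - x[ok], K)]
  m <- max(lterm)
  if (!is.finite(m)) return(-Inf)
  off + m + log(mean(exp(lterm - m)))
}
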