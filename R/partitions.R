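# Set-partition combinatorics, all in log space.
#
# N(n, K) -- the number of ways to divide n genes into K non-empty groups
# (Stirling numbers of the second kind) -- satisfies
#   N(n, K) = K * N(n-1, K) + N(n-1, K-1),  N(K, K) = 1, N(n, 1) = 1,
# and underlies both the uninformative ("baseline") prior over partitions
# and the baseline co-grouping probability P_b.

# memoised log-count table, grown lazily
.partition_env <- new.env(parent = emptyenv())

#' Table of log partition counts
#'
#' Computes (and memoises) the full triangle of log N(n, K) for
#' 1 <= K <= n <= max_n, where N(n, K) is the number of partitions of n
#' items into K non-empty unlabelled groups.
#'
#' @param max_n largest n required.
#' @return a \code{max_n x max_n} matrix \code{L} with \code{L[n, K]} =
#'   log N(n, K); entries with K > n are \code{-Inf}.
#' @export
partition_count_table <- function(max_n) {
  if (!is.numeric(max_n) || length(max_n) != 1L || is.na(max_n) || max_n < 1)
    stop("'max_n' must be a positive integer")
  max_n <- as.integer(max_n)
  tab <- .partition_env$table
  if (!is.null(tab) && nrow(tab) >= max_n)
    return(tab[seq_len(max_n), seq_len(max_n), drop = FALSE])
  size <- max(max_n, 128L)
  L <- matrix(-Inf, size, size)
  L[, 1L] <- 0
  for (n in seq_len(size)) {
    L[n, n] <- 0
    if (n >= 3L) for (K in 2:(n - 1L)) {
      a <- log(K) + L[n - 1L, K]
      b <- L[n - 1L, K - 1L]
      m <- max(a, b)
      L[n, K] <- m + log(exp(a - m) + exp(b - m))
    }
  }
  .partition_env$table <- L
  L[seq_len(max_n), seq_len(max_n), drop = FALSE]
}

#' Log number of partitions of n items into K groups
#'
#' @param n number of items (positive integer).
#' @param K number of groups (positive integer).
#' @return log N(n, K); \code{-Inf} when K > n (no such partition).
#' @examples
#' exp(log_partition_count(4, 2))  # 7
#' @export
log_partition_count <- function(n, K) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer")
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1)
    stop("'K' must be a positive integer")
  n <- as.integer(n); K <- as.integer(K)
  if (K > n) return(-Inf)
  partition_count_table(n)[n, K]
}

#' Log total number of partitions of n items
#'
#' Bell-number total, log-sum-exp over K of N(n, K).
#'
#' @param n number of items.
#' @return log of the total partition count.
#' @examples
#' exp(log_total_partitions(4))  # 15
#' @export
log_total_partitions <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer")
  n <- as.integer(n)
  lx <- partition_count_table(n)[n, seq_len(n)]
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

#' Baseline probability that two genes are co-grouped
#'
#' Under the uninformative prior (number of groups K uniform on 1..n, then
#' uniform over partitions with K groups), the probability that two
#' arbitrary genes land in the same group is
#' (1/n) * sum_K N(n-1, K) / N(n, K). It decreases with n: 0.25 at n = 10
#' down to 0.048 at n = 100.
#'
#' @param n total number of genes (>= 2).
#' @return a probability in (0, 1).
#' @export
baseline_pair_probability <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2)
    stop("'n' must be an integer >= 2")
  n <- as.integer(n)
  L <- partition_count_table(n)
  # K = n term has N(n-1, n) = 0, contributing nothing
  Ks <- seq_len(n - 1L)
  sum(exp(L[n - 1L, Ks] - L[n, Ks])) / n
}

#' Canonical group labels
#'
#' Relabels a membership vector so that group 1 is the group of the first
#' gene, group 2 the first subsequently-appearing new group, and so on.
#' Group labels are exchangeable in every formula of the model, so all
#' partition comparisons are done on this canonical form.
#'
#' @param labels vector of group identifiers, one per gene.
#' @return integer vector of canonical labels in 1..K.
#' @export
canonical_labels <- function(labels) {
  if (length(labels) < 1L || anyNA(labels))
    stop("'labels' must be a non-empty vector without NA")
  match(labels, unique(labels))
}

#' Log baseline prior of a partition
#'
#' P(g | no prior pairs) = 1 / (n * N(n, K_g)): uniform over the number of
#' groups, then uniform over partitions with that many groups.
#'
#' @param labels group membership vector (any labelling; canonicalised
#'   internally).
#' @return log prior probability.
#' @export
log_baseline_prior <- function(labels) {
  g <- canonical_labels(labels)
  n <- length(g)
  K <- max(g)
  -log(n) - log_partition_count(n, K)
}

#' Enumerate all partitions of n items
#'
#' Exhaustive enumeration in canonical-label form, used by the exact
#' posterior enumeration on small instances and by test oracles.
#'
#' @param n number of items (kept small; the count is the Bell number).
#' @return list of integer label vectors, each canonical.
#' @export
all_partitions <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer")
  n <- as.integer(n)
  if (n > 12L) stop("refusing to enumerate partitions for n > 12")
  parts <- list(1L)
  if (n >= 2L) for (i in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      K <- max(p)
      lapply(seq_len(K + 1L), function(k) c(p, k))
    }), recursive = FALSE)
  }
  parts
}

# Draw one partition from the baseline prior: K uniform on 1..n, then a
# uniform partition with K groups via the count recursion (gene n starts a
# new group with probability N(n-1, K-1)/N(n, K), otherwise joins one of
# the K groups of a uniform partition of the first n-1 genes).
sample_baseline_partition <- function(n) {
  K <- sample.int(n, 1L)
  L <- partition_count_table(n)
  labels <- integer(n)
  new_group <- logical(n)
  new_group[1L] <- TRUE
  kk <- K
  if (n >= 2L) for (i in n:2) {
    if (kk == i) {            # all remaining genes must open groups
      new_group[i] <- TRUE; kk <- kk - 1L
    } else if (kk > 1L) {
      p_new <- exp(L[i - 1L, kk - 1L] - L[i, kk])
      if (stats::runif(1) < p_new) { new_group[i] <- TRUE; kk <- kk - 1L }
    }                          # kk == 1: gene i joins the single group
  }
  next_label <- 0L
  open <- integer(0)
  for (i in seq_len(n)) {
    if (new_group[i]) {
      next_label <- next_label + 1L
      labels[i] <- next_label
      open <- c(open, next_label)
    } else {
      labels[i] <- open[sample.int(length(open), 1L)]
    }
  }
  canonical_labels(labels)
}
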