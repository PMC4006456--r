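# From MCMC partition samples to a clustering: posterior similarity
# matrix, posterior expected loss, and loss-minimising cluster selection.

#' Posterior similarity matrix
#'
#' Entry (i, j) is the proportion of samples in which genes i and j share
#' a group. Symmetric with unit diagonal.
#'
#' @param samples list of membership vectors over the same genes, or a
#'   \code{priorclust_chain}.
#' @return n x n numeric matrix.
#' @export
posterior_similarity <- function(samples) {
  if (inherits(samples, "priorclust_chain")) samples <- samples$samples
  if (length(samples) < 1L) stop("at least one sample required")
  n <- length(samples[[1L]])
  acc <- matrix(0, n, n)
  for (s in samples) {
    if (length(s) != n) stop("samples have inconsistent gene counts")
    acc <- acc + outer(s, s, "==")
  }
  p <- acc / length(samples)
  diag(p) <- 1
  p
}

#' Posterior expected loss of a candidate partition
#'
#' Absolute-difference loss between the partition's co-clustering
#' indicators and the posterior similarity matrix, summed over unordered
#' pairs: e_K = sum_{i<j} |I(i, j) - p_ij|.
#'
#' @param psm posterior similarity matrix.
#' @param labels candidate membership vector.
#' @return non-negative loss.
#' @export
posterior_expected_loss <- function(psm, labels) {
  n <- length(labels)
  if (!is.matrix(psm) || nrow(psm) != n || ncol(psm) != n)
    stop("'psm' dimensions must match 'labels'")
  ind <- outer(labels, labels, "==")
  sum(abs(ind - psm)[upper.tri(psm)])
}

#' Infer a clustering from the posterior similarity matrix
#'
#' Hierarchical clustering on the dissimilarity 1 - p generates candidate
#' partitions for K = 1..L via tree cutting; the candidate minimising the
#' posterior expected loss is returned (ties broken toward smaller K).
#'
#' @param psm posterior similarity matrix.
#' @param L maximum number of clusters to consider (default 30, capped
#'   at n).
#' @param linkage agglomeration method, "average" (default) or
#'   "complete".
#' @return list of class \code{priorclust_clustering} with
#'   \code{labels} (canonical), \code{K_hat}, and \code{loss_curve}
#'   (e_K for K = 1..L).
#' @export
infer_clusters <- function(psm, L = 30, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (L < 1) stop("'L' must be >= 1")
  n <- nrow(psm)
  L <- min(as.integer(L), n)
  hc <- stats::hclust(stats::as.dist(1 - psm), method = linkage)
  cuts <- stats::cutree(hc, k = seq_len(L))
  loss <- vapply(seq_len(L), function(K) {
    posterior_expected_loss(psm, cuts[, K])
  }, numeric(1))
  K_hat <- which.min(loss)          # which.min takes the first (smallest K)
  labels <- canonical_labels(cuts[, K_hat])
  if (!is.null(rownames(psm))) names(labels) <- rownames(psm)
  structure(list(labels = labels, K_hat = as.integer(K_hat),
                 loss_curve = loss),
            class = "priorclust_clustering")
}

#' @export
print.priorclust_clustering <- function(x, ...) {
  cat("Inferred clustering: K =", x$K_hat, "clusters over",
      length(x$labels), "genes\n")
  cat("  posterior expected loss:",
      format(x$loss_curve[x$K_hat], digits = 5), "\n")
  cat("  cluster sizes:", paste(tabulate(x$labels), collapse = ", "), "\n")
  invisible(x)
}
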