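# The user-facing model fit: standardize -> sample -> summarise.

#' Bayesian clustering with informative pairwise priors
#'
#' Fits the partition model to an expression matrix: genes within a group
#' are zero-mean multivariate normal with an inverse-Wishart covariance
#' prior, and the prior over partitions mixes a uniform baseline with
#' components that force prior pairs together. Posterior sampling uses
#' split/merge/move Metropolis-Hastings with parallel tempering; the
#' returned clustering minimises the posterior expected loss computed
#' from the posterior similarity matrix.
#'
#' @param x numeric expression matrix, genes in rows and samples in
#'   columns (log scale). Standardization (per-gene mean 0, variance 1)
#'   is applied internally.
#' @param priors optional prior knowledge: a \code{\link{prior_set}}, or
#'   a data frame with columns gene_a, gene_b and either \code{p}
#'   (probabilities) or \code{score} + \code{source} (raw database
#'   scores, see \code{\link{merge_prior_sources}}). NULL fits with the
#'   baseline prior only.
#' @param control a \code{\link{sampler_control}}.
#' @param max_clusters maximum K examined when cutting the posterior
#'   similarity tree (default 30).
#' @param linkage agglomeration method for candidate generation.
#' @return object of class \code{priorclust}: the inferred clustering
#'   (\code{$labels}, \code{$K_hat}, \code{$loss_curve}), the posterior
#'   similarity matrix (\code{$psm}), the chain (\code{$chain}), the
#'   prior set used, and the call. Uses the R random-number state; call
#'   \code{set.seed} first for reproducibility.
#' @seealso \code{\link{run_chain}}, \code{\link{infer_clusters}},
#'   \code{\link{simulate_clustered_dataset}}
#' @examples
#' set.seed(1)
#' sim <- simulate_clustered_dataset("C",
#'   sim_control(n_clusters = 2, lambda = 3, n_samples = 20), q = 3)
#' fit <- priorclust(t(sim$expression), sim$prior,
#'   control = sampler_control(n_iterations = 2000, burn_in = 500,
#'                             thin = 5, n_temperatures = 1))
#' fit
#' @export
priorclust <- function(x, priors = NULL, control = sampler_control(),
                       max_clusters = 30,
                       linkage = c("average", "complete")) {
  cl <- match.call()
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  genes <- rownames(x)
  xs <- standardize_expression(t(x))   # samples x genes internally
  colnames(xs) <- genes
  prior <- NULL
  if (!is.null(priors)) {
    prior <- if (inherits(priors, "prior_set")) {
      if (!identical(priors$genes, genes))
        prior_set(priors$pairs, genes)  # re-anchor to this gene universe
      else priors
    } else if (!is.null(priors$p)) {
      rc <- remove_cycles(priors)
      prior_set(rc$kept, genes)
    } else {
      merge_prior_sources(priors, genes)
    }
  }
  chain <- if (control$n_temperatures > 1L)
    run_tempered(xs, prior, control)
  else run_chain(xs, prior, control)
  psm <- posterior_similarity(chain$samples)
  dimnames(psm) <- list(genes, genes)
  clus <- infer_clusters(psm, L = max_clusters, linkage = linkage)
  structure(list(labels = clus$labels, K_hat = clus$K_hat,
                 loss_curve = clus$loss_curve, psm = psm, chain = chain,
                 prior = prior, gene_ids = genes, call = cl,
                 control = control),
            class = "priorclust")
}

#' @export
print.priorclust <- function(x, ...) {
  cat("Bayesian partition clustering with informative pairwise priors\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(length(x$gene_ids), "genes,",
      if (is.null(x$prior)) 0L else nrow(x$prior$pairs), "prior pair(s),",
      length(x$chain$samples), "posterior samples\n")
  cat("Inferred K =", x$K_hat, "clusters; sizes:",
      paste(tabulate(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.priorclust <- function(object, ...) {
  tr <- object$chain$trace
  post <- tr$log_lik + tr$log_prior
  out <- list(K_hat = object$K_hat,
              sizes = tabulate(object$labels),
              loss = object$loss_curve[object$K_hat],
              loss_curve = object$loss_curve,
              acceptance = object$chain$acceptance,
              swap_rate = object$chain$swap_rate,
              n_samples = length(object$chain$samples),
              K_posterior = table(vapply(object$chain$samples, max,
                                         integer(1))),
              log_posterior_range = range(post))
  class(out) <- "summary.priorclust"
  out
}

#' @export
print.summary.priorclust <- function(x, ...) {
  cat("Inferred clustering: K =", x$K_hat, "(posterior expected loss",
      format(x$loss, digits = 5), ")\n")
  cat("Cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("Posterior over K (sampled):\n")
  print(x$K_posterior)
  cat("Move acceptance rates:",
      paste(names(x$acceptance), format(x$acceptance, digits = 2),
            collapse = ", "), "\n")
  if (!is.na(x$swap_rate))
    cat("Tempering swap rate:", format(x$swap_rate, digits = 2), "\n")
  invisible(x)
}

#' Plot diagnostics for a fitted clustering
#'
#' Two base-graphics panels: the posterior expected loss across candidate
#' cluster counts (with the selected K marked), and the log-posterior
#' trace of the cold chain.
#'
#' @param x a \code{priorclust} fit.
#' @param which subset of panels, 1 = loss curve, 2 = trace.
#' @param ... passed to \code{plot}.
#' @export
plot.priorclust <- function(x, which = 1:2, ...) {
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::plot(seq_along(x$loss_curve), x$loss_curve, type = "b",
                   xlab = "number of clusters K",
                   ylab = "posterior expected loss", ...)
    graphics::abline(v = x$K_hat, lty = 2)
  }
  if (2 %in% which) {
    tr <- x$chain$trace
    graphics::plot(tr$iteration, tr$log_lik + tr$log_prior, type = "l",
                   xlab = "iteration", ylab = "log posterior (unnorm.)",
                   ...)
    graphics::abline(v = x$control$burn_in, lty = 2)
  }
  invisible(x)
}

#' Cluster memberships of a fit
#'
#' @param object a \code{priorclust} fit.
#' @param ... unused.
#' @return named integer vector of cluster labels.
#' @export
clusters <- function(object, ...) UseMethod("clusters")

#' @rdname clusters
#' @export
clusters.priorclust <- function(object, ...) object$labels
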