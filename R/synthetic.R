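# Benchmark data generator: clustered expression profiles from a
# hierarchical log-normal model, plus prior-pair scenarios.
#
# Each cluster c receives a template of four constant-expression periods
# spanning the N samples; the period levels are log mu_kc ~ N(mu, sigma^2),
# per-sample templates log T_jc ~ N(log mu_{k(j),c}, sigma_s^2) add sample
# variability, and individual genes scatter around the template with
# log x_ij ~ N(log T_jc, sigma_0^2). Optional extra measurement noise
# N(0, extra_sd^2) is added to every log value. Cluster sizes are drawn
# as 2 x Poisson(lambda), redrawn until at least 2, so lambda = 10 with
# five clusters yields roughly 100 genes per dataset.

#' Simulation configuration
#'
#' @param n_clusters number of gene clusters (default 5).
#' @param lambda Poisson rate for half the cluster size (default 10).
#' @param n_samples number of samples N (default 100).
#' @param mu mean of the log period level (default 6).
#' @param sigma SD of the log period level (default 1).
#' @param sigma_s sample-variability SD (default 1).
#' @param sigma_0 gene-variability SD (default 1).
#' @param extra_sd extra measurement-noise SD on each log value
#'   (default 0; the benchmark grid uses 0, 1, 2).
#' @param n_periods number of constant-expression periods (default 4).
#' @return list of class \code{sim_control}.
#' @export
sim_control <- function(n_clusters = 5, lambda = 10, n_samples = 100,
                        mu = 6, sigma = 1, sigma_s = 1, sigma_0 = 1,
                        extra_sd = 0, n_periods = 4) {
  if (any(c(sigma, sigma_s, sigma_0, extra_sd) < 0))
    stop("standard deviations must be non-negative")
  if (n_clusters < 1 || lambda <= 0) stop("invalid cluster configuration")
  if (n_samples < n_periods)
    stop("'n_samples' must be at least 'n_periods'")
  structure(as.list(environment()), class = "sim_control")
}

# uniform composition of N into k parts each >= minimum, via uniformly
# chosen cut points of the reduced stars-and-bars problem
.sample_periods <- function(N, k, minimum) {
  slack <- N - k * minimum
  if (slack < 0) stop("'N' too small for ", k, " periods of >= ", minimum)
  if (slack == 0) return(rep(minimum, k))
  cuts <- sort(sample.int(slack + k - 1L, k - 1L))
  diff(c(0L, cuts, slack + k)) - 1L + minimum
}

#' Simulate clustered expression profiles
#'
#' @param config a \code{\link{sim_control}}.
#' @return list with \code{expression} (N samples x n genes, log scale,
#'   not standardized; gene columns named g1..gn), \code{true_labels}
#'   (integer cluster per gene), and \code{config}. Uses the R
#'   random-number state.
#' @export
simulate_expression_profiles <- function(config = sim_control()) {
  stopifnot(inherits(config, "sim_control"))
  N <- config$n_samples
  # periods of >= 3 samples as in the benchmark design; relaxed to >= 1
  # when N is too small for that (e.g. N = 10 with 4 periods)
  minimum <- if (N >= 3 * config$n_periods) 3L else 1L
  cluster_of <- integer(0)
  cols <- list()
  for (cl in seq_len(config$n_clusters)) {
    repeat {
      n_c <- 2L * stats::rpois(1L, config$lambda)
      if (n_c >= 2L) break
    }
    m <- .sample_periods(N, config$n_periods, minimum)
    period_of <- rep(seq_len(config$n_periods), times = m)
    log_mu <- stats::rnorm(config$n_periods, config$mu, config$sigma)
    log_T <- stats::rnorm(N, log_mu[period_of], config$sigma_s)
    vals <- matrix(stats::rnorm(N * n_c, rep(log_T, n_c), config$sigma_0),
                   nrow = N)
    cols[[cl]] <- vals
    cluster_of <- c(cluster_of, rep(cl, n_c))
  }
  expr <- do.call(cbind, cols)
  if (config$extra_sd > 0)
    expr <- expr + stats::rnorm(length(expr), 0, config$extra_sd)
  colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  rownames(expr) <- paste0("s", seq_len(N))
  list(expression = expr, true_labels = cluster_of, config = config)
}

#' Generate prior pairs from true cluster labels
#'
#' Draws \code{round(q * (1 - misspec_fraction))} correct pairs (both
#' genes in the same true cluster) and \code{round(q * misspec_fraction)}
#' mis-specified pairs (different clusters), without replacement among
#' unordered pairs, with enforcement probabilities from Uniform(0.5, 1).
#' Cycles are removed before returning (largest-p spanning forest).
#'
#' Benchmark scenarios: A = no priors (use \code{q = 0} or a NULL prior),
#' B = \code{misspec_fraction = 0.2}, C = \code{misspec_fraction = 0}.
#'
#' @param true_labels integer cluster membership per gene.
#' @param q number of prior pairs before cycle removal (default 50).
#' @param misspec_fraction fraction of pairs crossing cluster boundaries.
#' @param gene_ids gene identifiers (default g1..gn).
#' @return list with \code{prior} (a \code{\link{prior_set}}),
#'   \code{pairs} (data frame incl. logical \code{correct} flag), and
#'   \code{removed} (pairs dropped by cycle removal).
#' @export
simulate_prior_pairs <- function(true_labels, q = 50, misspec_fraction = 0,
                                 gene_ids = paste0("g", seq_along(true_labels))) {
  n <- length(true_labels)
  if (misspec_fraction < 0 || misspec_fraction > 1)
    stop("'misspec_fraction' must lie in [0, 1]")
  if (q == 0) {
    empty <- data.frame(gene_a = character(0), gene_b = character(0),
                        p = numeric(0), source = character(0),
                        correct = logical(0), stringsAsFactors = FALSE)
    return(list(prior = prior_set(NULL, gene_ids), pairs = empty,
                removed = empty))
  }
  idx <- t(utils::combn(n, 2L))
  same <- true_labels[idx[, 1L]] == true_labels[idx[, 2L]]
  n_correct <- round(q * (1 - misspec_fraction))
  n_wrong <- round(q * misspec_fraction)
  if (sum(same) < n_correct || sum(!same) < n_wrong)
    stop("not enough same/different-cluster pairs for the requested q")
  pick_c <- sample(which(same), n_correct)
  pick_w <- sample(which(!same), n_wrong)
  pick <- c(pick_c, pick_w)
  pairs <- data.frame(gene_a = gene_ids[idx[pick, 1L]],
                      gene_b = gene_ids[idx[pick, 2L]],
                      p = stats::runif(length(pick), 0.5, 1),
                      source = "simulated",
                      correct = c(rep(TRUE, n_correct), rep(FALSE, n_wrong)),
                      stringsAsFactors = FALSE)
  rc <- remove_cycles(pairs)
  list(prior = prior_set(rc$kept, gene_ids), pairs = rc$kept,
       removed = rc$removed)
}

#' Simulate a full benchmark dataset for one prior scenario
#'
#' Convenience wrapper combining \code{\link{simulate_expression_profiles}}
#' and \code{\link{simulate_prior_pairs}}.
#'
#' @param scenario "A" (no priors), "B" (20\% mis-specified) or "C" (all
#'   correct).
#' @param config a \code{\link{sim_control}}.
#' @param q number of prior pairs for scenarios B and C.
#' @return list with \code{expression}, \code{true_labels}, \code{prior}
#'   (NULL for scenario A), \code{pairs}, \code{scenario}.
#' @export
simulate_clustered_dataset <- function(scenario = c("A", "B", "C"),
                                       config = sim_control(), q = 50) {
  scenario <- match.arg(scenario)
  sim <- simulate_expression_profiles(config)
  if (scenario == "A") {
    prior <- NULL; pairs <- NULL
  } else {
    f <- if (scenario == "B") 0.2 else 0
    pp <- simulate_prior_pairs(sim$true_labels, q = q, misspec_fraction = f)
    prior <- pp$prior; pairs <- pp$pairs
  }
  list(expression = sim$expression, true_labels = sim$true_labels,
       prior = prior, pairs = pairs, scenario = scenario, config = config)
}
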