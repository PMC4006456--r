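# Metropolis-Hastings sampling over set partitions.
#
# Three move types: split a group into two, merge two groups, or move one
# gene between groups. Each admissible type is proposed with probability
# 1/3 (splitting is the only option when K = 1, merging the only option
# when K = n; moves additionally require a non-singleton source, i.e.
# K < n). Proposal probabilities:
#
#   split:  q = P(type) * n_k/(n - n_s) * 1/N(n_k, 2)
#   merge:  q = P(type) * [n_k/n * n_l/(n-n_k) + n_l/n * n_k/(n-n_l)]
#   move:   q = P(type) * n_k / ((n - n_s)(n - n_l))
#
# with n_s the number of singleton groups, n_k/n_l the sizes of the
# groups involved (for a move, l is the source and k the target).
# Acceptance uses the likelihood x prior ratio times the reverse/forward
# proposal ratio; split and merge are mutual reverses, a move is its own
# reverse type.

.move_type_log_prob <- function(K, n) if (K > 1L && K < n) -log(3) else 0

# Internal single proposal. labels use contiguous ids 1..K.
# Returns new_labels (contiguous), move, log_q_forward, log_q_reverse,
# and the member index sets of groups changed (old state and new state)
# for incremental likelihood updates.
.propose <- function(labels, n) {
  K <- max(labels)
  sizes <- tabulate(labels, K)
  n_s <- sum(sizes == 1L)
  can_split <- K < n
  can_merge <- K > 1L
  can_move <- K > 1L && K < n
  types <- c(if (can_split) "split", if (can_merge) "merge",
             if (can_move) "move")
  type <- if (length(types) == 1L) types else types[sample.int(3L, 1L)]
  lp_type <- .move_type_log_prob(K, n)
  L <- partition_count_table(n)

  if (type == "split") {
    nonsing <- which(sizes >= 2L)
    k <- if (length(nonsing) == 1L) nonsing else {
      nonsing[sample.int(length(nonsing), 1L, prob = sizes[nonsing])]
    }
    members <- which(labels == k)
    nk <- sizes[k]
    repeat {
      bits <- stats::runif(nk) < 0.5
      if (any(bits) && !all(bits)) break
    }
    new_labels <- labels
    new_labels[members[bits]] <- K + 1L
    lq_f <- lp_type + log(nk) - log(n - n_s) - L[nk, 2L]
    # reverse: merge the two parts in the new state (K+1 groups)
    n1 <- sum(bits); n2 <- nk - n1
    lp_type_rev <- .move_type_log_prob(K + 1L, n)
    lq_r <- lp_type_rev +
      log(n1 / n * n2 / (n - n1) + n2 / n * n1 / (n - n2))
    list(new_labels = new_labels, move = "split",
         log_q_forward = lq_f, log_q_reverse = lq_r,
         old_groups = list(members),
         new_groups = list(members[!bits], members[bits]))
  } else if (type == "merge") {
    g1 <- sample.int(n, 1L)
    k <- labels[g1]
    outside <- which(labels != k)
    g2 <- outside[sample.int(length(outside), 1L)]
    l <- labels[g2]
    nk <- sizes[k]; nl <- sizes[l]
    mem_k <- which(labels == k); mem_l <- which(labels == l)
    new_labels <- labels
    new_labels[new_labels == l] <- k
    if (l != K) new_labels[new_labels == K] <- l   # keep ids contiguous
    lq_f <- lp_type +
      log(nk / n * nl / (n - nk) + nl / n * nk / (n - nl))
    # reverse: split the merged group back into exactly these two parts
    new_sizes <- tabulate(new_labels, K - 1L)
    n_s_new <- sum(new_sizes == 1L)
    lp_type_rev <- .move_type_log_prob(K - 1L, n)
    lq_r <- lp_type_rev + log(nk + nl) - log(n - n_s_new) - L[nk + nl, 2L]
    list(new_labels = new_labels, move = "merge",
         log_q_forward = lq_f, log_q_reverse = lq_r,
         old_groups = list(mem_k, mem_l),
         new_groups = list(sort(c(mem_k, mem_l))))
  } else {
    nonsing <- which(sizes >= 2L)
    l <- if (length(nonsing) == 1L) nonsing else {
      nonsing[sample.int(length(nonsing), 1L, prob = sizes[nonsing])]
    }
    outside <- which(labels != l)
    g2 <- outside[sample.int(length(outside), 1L)]
    k <- labels[g2]
    mem_l <- which(labels == l)
    x <- mem_l[sample.int(length(mem_l), 1L)]
    nk <- sizes[k]; nl <- sizes[l]
    new_labels <- labels
    new_labels[x] <- k
    lq_f <- lp_type + log(nk) - log(n - n_s) - log(n - nl)
    # reverse: move x from (k + x) back to (l - x); same K
    new_sizes <- tabulate(new_labels, K)
    n_s_new <- sum(new_sizes == 1L)
    lq_r <- lp_type + log(nl - 1L) - log(n - n_s_new) - log(n - (nk + 1L))
    list(new_labels = new_labels, move = "move",
         log_q_forward = lq_f, log_q_reverse = lq_r,
         old_groups = list(mem_l, which(labels == k)),
         new_groups = list(setdiff(mem_l, x), sort(c(which(labels == k), x))))
  }
}

#' Propose one split/merge/move transition
#'
#' Draws a single proposal from the partition proposal kernel. Exposed
#' mainly for inspection and testing; \code{\link{run_chain}} drives the
#' full sampler.
#'
#' @param labels current group membership vector (any labelling).
#' @return list with \code{new_labels} (canonical), \code{move},
#'   \code{log_q_forward}, \code{log_q_reverse}.
#' @export
propose_move <- function(labels) {
  g <- canonical_labels(labels)
  n <- length(g)
  if (n < 2L) stop("no admissible move for a single gene")
  pr <- .propose(g, n)
  pr$new_labels <- canonical_labels(pr$new_labels)
  pr[c("new_labels", "move", "log_q_forward", "log_q_reverse")]
}

# Enumerate every distinct proposal (new state, total forward probability)
# reachable from `labels`, for kernel checks and exact detailed-balance
# tests on small n.
.enumerate_proposals <- function(labels) {
  g <- canonical_labels(labels)
  n <- length(g)
  K <- max(g)
  sizes <- tabulate(g, K)
  n_s <- sum(sizes == 1L)
  lp_type <- .move_type_log_prob(K, n)
  L <- partition_count_table(n)
  out <- list()
  add <- function(new_labels, lq, move) {
    key <- paste(canonical_labels(new_labels), collapse = ",")
    cur <- out[[key]]
    if (is.null(cur)) out[[key]] <<- list(labels = canonical_labels(new_labels),
                                          q = exp(lq), move = move)
    else out[[key]]$q <<- cur$q + exp(lq)
  }
  if (K < n) {
    for (k in which(sizes >= 2L)) {
      members <- which(g == k)
      nk <- sizes[k]
      # unordered bipartitions: subsets containing the first member
      for (mask in 0:(2^(nk - 1L) - 1L)) {
        bits <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(nk - 1L) - 1L))))
        if (all(bits)) next
        nl <- g
        nl[members[!bits]] <- K + 1L
        add(nl, lp_type + log(nk) - log(n - n_s) - L[nk, 2L], "split")
      }
    }
  }
  if (K > 1L) {
    for (k in seq_len(K - 1L)) for (l in (k + 1L):K) {
      nk <- sizes[k]; nl2 <- sizes[l]
      nlab <- g
      nlab[nlab == l] <- k
      add(nlab, lp_type +
            log(nk / n * nl2 / (n - nk) + nl2 / n * nk / (n - nl2)), "merge")
    }
  }
  if (K > 1L && K < n) {
    for (l in which(sizes >= 2L)) for (x in which(g == l)) {
      for (k in seq_len(K)[-l]) {
        nlab <- g
        nlab[x] <- k
        add(nlab, lp_type + log(sizes[k]) - log(n - n_s) - log(n - sizes[l]),
            "move")
      }
    }
  }
  unname(out)
}

#' Sampler configuration
#'
#' Defaults follow the method's standard run lengths: 150000 iterations
#' with a 50000-iteration burn-in, keeping every 100th sample, and 200
#' Monte-Carlo draws when the prior is estimated stochastically.
#'
#' @param n_iterations total MCMC iterations (sweeps, for tempering).
#' @param burn_in iterations discarded before sampling begins.
#' @param thin keep every \code{thin}-th post-burn-in state.
#' @param n_temperatures number of tempered chains (1 = plain chain).
#' @param temperature_ratio geometric ladder ratio in (0, 1); chain i runs
#'   at inverse temperature \code{temperature_ratio^i}.
#' @param prior_method "exact" (Poisson-binomial collapse of the mixture)
#'   or "mc" (Monte-Carlo estimator, re-estimated for both states at
#'   every step).
#' @param mc_prior_samples draws per Monte-Carlo prior estimate.
#' @param rho prior covariance scale of the likelihood.
#' @param audit_every recompute cached quantities from scratch every this
#'   many iterations and error on drift > 1e-6 (0 disables).
#' @param verbose print progress every 10000 iterations.
#' @return list of class \code{sampler_control}.
#' @export
sampler_control <- function(n_iterations = 150000, burn_in = 50000,
                            thin = 100, n_temperatures = 4,
                            temperature_ratio = 0.7,
                            prior_method = c("exact", "mc"),
                            mc_prior_samples = 200, rho = 1,
                            audit_every = 10000, verbose = FALSE) {
  prior_method <- match.arg(prior_method)
  if (burn_in >= n_iterations) stop("'burn_in' must be < 'n_iterations'")
  if (thin < 1) stop("'thin' must be >= 1")
  if (n_temperatures < 1) stop("'n_temperatures' must be >= 1")
  if (n_temperatures > 1 &&
      (temperature_ratio <= 0 || temperature_ratio >= 1))
    stop("'temperature_ratio' must lie in (0, 1)")
  if (mc_prior_samples < 1) stop("'mc_prior_samples' must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_temperatures = as.integer(n_temperatures),
                 temperature_ratio = temperature_ratio,
                 prior_method = prior_method,
                 mc_prior_samples = as.integer(mc_prior_samples),
                 rho = rho, audit_every = as.integer(audit_every),
                 verbose = isTRUE(verbose)),
            class = "sampler_control")
}

# per-group marginal likelihood with member-set cache (labelling-agnostic)
.group_loglik <- function(x, members, rho, cache) {
  key <- paste(members, collapse = ",")
  v <- cache[[key]]
  if (is.null(v)) {
    v <- log_marginal_likelihood_group(x[, members, drop = FALSE], rho = rho)
    cache[[key]] <- v
  }
  v
}

.state_loglik <- function(x, labels, rho, cache) {
  K <- max(labels)
  tot <- 0
  for (k in seq_len(K))
    tot <- tot + .group_loglik(x, which(labels == k), rho, cache)
  tot
}

.log_prior_fn <- function(prior, control) {
  if (is.null(prior) || nrow(prior$pairs) == 0L) {
    function(labels) log_baseline_prior(labels)
  } else if (control$prior_method == "exact") {
    function(labels) log_prior_exact(labels, prior)
  } else {
    function(labels) log_prior_mc(labels, prior,
                                  n_samples = control$mc_prior_samples)
  }
}

# Core loop shared by run_chain (betas = 1) and run_tempered.
.run_mcmc <- function(x, prior, control, betas, init = NULL) {
  if (!.is_standardized(x))
    stop("'x' must be standardized; see standardize_expression()")
  n <- ncol(x)
  if (!is.null(prior) && length(prior$genes) != n)
    stop("prior gene universe does not match the expression matrix")
  n_chains <- length(betas)
  cache <- new.env(parent = emptyenv())
  lp_fun <- .log_prior_fn(prior, control)
  fresh_prior <- control$prior_method == "mc" && !is.null(prior) &&
    nrow(prior$pairs) > 0L

  states <- vector("list", n_chains)
  for (c_i in seq_len(n_chains)) {
    labels <- if (is.null(init)) sample_baseline_partition(n)
              else canonical_labels(init)
    states[[c_i]] <- list(labels = labels,
                          loglik = .state_loglik(x, labels, control$rho, cache),
                          logprior = lp_fun(labels))
  }

  n_keep <- (control$n_iterations - control$burn_in) %/% control$thin
  samples <- vector("list", n_keep)
  s_i <- 0L
  tr_n <- control$n_iterations %/% control$thin
  trace <- list(iteration = integer(tr_n), log_lik = numeric(tr_n),
                log_prior = numeric(tr_n), K = integer(tr_n),
                move = character(tr_n), accepted = logical(tr_n))
  t_i <- 0L
  n_prop <- integer(3); n_acc <- integer(3)
  names(n_prop) <- names(n_acc) <- c("split", "merge", "move")
  swap_att <- 0L; swap_acc <- 0L
  last_move <- "none"; last_accept <- NA

  for (it in seq_len(control$n_iterations)) {
    for (c_i in seq_len(n_chains)) {
      st <- states[[c_i]]
      pr <- .propose(st$labels, n)
      d_lik <- 0
      for (mem in pr$new_groups)
        d_lik <- d_lik + .group_loglik(x, mem, control$rho, cache)
      for (mem in pr$old_groups)
        d_lik <- d_lik - .group_loglik(x, sort(mem), control$rho, cache)
      lp_old <- if (fresh_prior) lp_fun(st$labels) else st$logprior
      lp_new <- lp_fun(pr$new_labels)
      log_alpha <- betas[c_i] * (d_lik + lp_new - lp_old) +
        pr$log_q_reverse - pr$log_q_forward
      acc <- log(stats::runif(1)) < log_alpha
      if (acc) {
        states[[c_i]] <- list(labels = pr$new_labels,
                              loglik = st$loglik + d_lik,
                              logprior = lp_new)
      } else if (fresh_prior) {
        states[[c_i]]$logprior <- lp_old
      }
      if (c_i == 1L) {
        n_prop[pr$move] <- n_prop[pr$move] + 1L
        if (acc) n_acc[pr$move] <- n_acc[pr$move] + 1L
        last_move <- pr$move; last_accept <- acc
      }
    }
    if (n_chains > 1L) {
      i <- sample.int(n_chains - 1L, 1L)
      j <- i + 1L
      si <- states[[i]]; sj <- states[[j]]
      lpi <- si$loglik + si$logprior
      lpj <- sj$loglik + sj$logprior
      swap_att <- swap_att + 1L
      if (log(stats::runif(1)) < (betas[i] - betas[j]) * (lpj - lpi)) {
        states[[i]] <- sj; states[[j]] <- si
        swap_acc <- swap_acc + 1L
      }
    }
    if (control$audit_every > 0L && it %% control$audit_every == 0L) {
      st <- states[[1L]]
      fresh <- sum(vapply(seq_len(max(st$labels)), function(k) {
        log_marginal_likelihood_group(
          x[, st$labels == k, drop = FALSE], rho = control$rho)
      }, numeric(1)))
      if (abs(fresh - st$loglik) > 1e-6)
        stop("cache audit failed at iteration ", it,
             ": cached log-likelihood drifted by ",
             format(fresh - st$loglik))
      states[[1L]]$loglik <- fresh
    }
    if (it %% control$thin == 0L) {
      st <- states[[1L]]
      t_i <- t_i + 1L
      trace$iteration[t_i] <- it
      trace$log_lik[t_i] <- st$loglik
      trace$log_prior[t_i] <- st$logprior
      trace$K[t_i] <- max(st$labels)
      trace$move[t_i] <- last_move
      trace$accepted[t_i] <- last_accept
      if (it > control$burn_in) {
        s_i <- s_i + 1L
        samples[[s_i]] <- canonical_labels(st$labels)
      }
    }
    if (control$verbose && it %% 10000L == 0L)
      message("iteration ", it, " K=", max(states[[1L]]$labels),
              " logpost=", format(states[[1L]]$loglik +
                                    states[[1L]]$logprior, digits = 8))
  }
  structure(list(samples = samples[seq_len(s_i)],
                 trace = as.data.frame(trace)[seq_len(t_i), , drop = FALSE],
                 n = n, gene_ids = colnames(x),
                 acceptance = ifelse(n_prop > 0, n_acc / n_prop, NA_real_),
                 swap_rate = if (swap_att > 0) swap_acc / swap_att else NA_real_,
                 betas = betas, control = control),
            class = "priorclust_chain")
}

#' Run a single Metropolis-Hastings chain over partitions
#'
#' @param x standardized expression matrix (samples x genes).
#' @param prior a \code{\link{prior_set}} or NULL (baseline prior only).
#' @param control a \code{\link{sampler_control}}.
#' @param init optional starting membership vector; default draws a
#'   random partition from the baseline prior.
#' @return object of class \code{priorclust_chain}: thinned post-burn-in
#'   partition samples, a trace data frame, and acceptance statistics.
#'   Uses the R random-number state; call \code{set.seed} first for
#'   reproducible runs.
#' @export
run_chain <- function(x, prior = NULL, control = sampler_control(),
                      init = NULL) {
  .run_mcmc(x, prior, control, betas = 1, init = init)
}

#' Run parallel-tempered chains
#'
#' Runs \code{control$n_temperatures} chains at inverse temperatures
#' \code{temperature_ratio^(i-1)} (both likelihood and prior are
#' tempered). After every sweep one uniformly chosen adjacent pair
#' proposes a state swap, accepted with probability
#' min(1, exp((b_i - b_j)(logpost_j - logpost_i))). Only the cold (b = 1)
#' chain's samples are returned. With a single temperature this is
#' exactly \code{\link{run_chain}}.
#'
#' @inheritParams run_chain
#' @return object of class \code{priorclust_chain}.
#' @export
run_tempered <- function(x, prior = NULL, control = sampler_control(),
                         init = NULL) {
  betas <- control$temperature_ratio^(seq_len(control$n_temperatures) - 1L)
  .run_mcmc(x, prior, control, betas = betas, init = init)
}

#' @export
print.priorclust_chain <- function(x, ...) {
  cat("Partition MCMC chain: ", length(x$samples), " retained samples over ",
      x$n, " genes\n", sep = "")
  cat("  acceptance rates:",
      paste(names(x$acceptance),
            format(x$acceptance, digits = 2), collapse = ", "), "\n")
  if (!is.na(x$swap_rate))
    cat("  tempering: ", length(x$betas), " chains, swap rate ",
        format(x$swap_rate, digits = 2), "\n", sep = "")
  invisible(x)
}
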