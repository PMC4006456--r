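test_that("forward proposal probabilities sum to one from every small state", {
  for (n in 2:4) {
    for (g in all_partitions(n)) {
      en <- priorclust:::.enumerate_proposals(g)
      expect_equal(sum(vapply(en, `[[`, numeric(1), "q")), 1,
                   tolerance = 1e-12,
                   info = paste("state", paste(g, collapse = ",")))
    }
  }
})

test_that("single proposals agree with the enumerated kernel", {
  set.seed(3)
  for (g0 in list(c(1, 1, 2), c(1, 2, 2, 1), c(1, 1, 1, 1), 1:3)) {
    en <- priorclust:::.enumerate_proposals(g0)
    keys <- vapply(en, function(e) paste(e$labels, collapse = ","),
                   character(1))
    qs <- vapply(en, `[[`, numeric(1), "q")
    draws <- replicate(3000, {
      pr <- propose_move(g0)
      paste(pr$new_labels, collapse = ",")
    })
    emp <- as.numeric(table(factor(draws, levels = keys))) / length(draws)
    expect_lt(0.5 * sum(abs(emp - qs)), 0.04)
    # every draw lands on an enumerated state
    expect_true(all(draws %in% keys))
  }
})

test_that("every proposal has a structurally valid reverse move", {
  set.seed(5)
  for (r in 1:200) {
    n <- sample(3:7, 1)
    g <- canonical_labels(sample.int(3, n, replace = TRUE))
    pr <- propose_move(g)
    expect_true(is.finite(pr$log_q_forward))
    expect_true(is.finite(pr$log_q_reverse))
    # reverse probability must match enumerating back from the new state
    back <- priorclust:::.enumerate_proposals(pr$new_labels)
    key0 <- paste(canonical_labels(g), collapse = ",")
    qback <- 0
    for (e in back)
      if (paste(e$labels, collapse = ",") == key0) qback <- qback + e$q
    # the reverse transition is unique (split<->merge, move<->move), so
    # the stored reverse probability must equal the enumerated kernel mass
    expect_gt(qback, 0)
    expect_equal(exp(pr$log_q_reverse), qback, tolerance = 1e-10)
  }
})

test_that("boundary states admit only the legal move types", {
  set.seed(6)
  # K = 1: only splits
  for (r in 1:20) {
    pr <- propose_move(rep(1, 4))
    expect_equal(pr$move, "split")
  }
  # K = n: only merges
  for (r in 1:20) {
    pr <- propose_move(1:4)
    expect_equal(pr$move, "merge")
  }
  # n = 2, K = 1: the unique split has probability 1
  pr <- propose_move(c(1, 1))
  expect_equal(pr$new_labels, c(1, 2))
  expect_equal(pr$log_q_forward, 0)
  expect_error(propose_move(1L), "single gene")
})

test_that("the transition kernel satisfies detailed balance on an enumerable instance", {
  set.seed(11)
  xs <- make_small_dataset(N = 12)[, 1:4]
  colnames(xs) <- paste0("g", 1:4)
  xs <- standardize_expression(xs)
  ps <- prior_set(data.frame(gene_a = "g1", gene_b = "g2", p = 0.8),
                  paste0("g", 1:4))
  post <- enumerate_posterior(xs, ps)
  nstates <- length(post$prob)
  P <- matrix(0, nstates, nstates)
  for (i in seq_len(nstates)) {
    en <- priorclust:::.enumerate_proposals(post$partitions[[i]])
    for (e in en) {
      j <- match(paste(e$labels, collapse = ","), post$keys)
      back <- priorclust:::.enumerate_proposals(post$partitions[[j]])
      qr <- 0
      for (b in back)
        if (paste(b$labels, collapse = ",") == post$keys[i]) qr <- b$q
      a <- min(1, post$prob[j] * qr / (post$prob[i] * e$q))
      P[i, j] <- P[i, j] + e$q * a
    }
    P[i, i] <- 1 - sum(P[i, -i])
  }
  flow <- post$prob * P
  expect_lt(max(abs(flow - t(flow))), 1e-8)
})

test_that("chains are reproducible and audits pass", {
  set.seed(19)
  xs <- make_small_dataset(N = 15)
  ps <- prior_set(data.frame(gene_a = "g1", gene_b = "g2", p = 0.7),
                  paste0("g", 1:5))
  ctrl <- sampler_control(n_iterations = 3000, burn_in = 500, thin = 10,
                          n_temperatures = 1, audit_every = 1000)
  set.seed(99); ch1 <- run_chain(xs, ps, ctrl)
  set.seed(99); ch2 <- run_chain(xs, ps, ctrl)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$trace, ch2$trace)
  expect_equal(nrow(ch1$trace), 300)
  expect_length(ch1$samples, 250)
  # cached log posterior in the trace matches fresh recomputation
  last <- ch1$samples[[length(ch1$samples)]]
  i <- nrow(ch1$trace)
  expect_equal(ch1$trace$log_lik[i], log_marginal_likelihood(xs, last),
               tolerance = 1e-8)
  expect_equal(ch1$trace$log_prior[i], log_prior_exact(last, ps),
               tolerance = 1e-8)
})

test_that("a strongly enforced pair of correlated genes stays co-grouped", {
  set.seed(23)
  z <- rnorm(25)
  x <- cbind(z + rnorm(25, 0, 0.2), z + rnorm(25, 0, 0.2),
             rnorm(25), rnorm(25))
  xs <- standardize_expression(x)
  colnames(xs) <- paste0("g", 1:4)
  ps <- prior_set(data.frame(gene_a = "g1", gene_b = "g2", p = 0.99),
                  paste0("g", 1:4))
  ch <- run_chain(xs, ps, sampler_control(n_iterations = 20000,
                                          burn_in = 5000, thin = 10,
                                          n_temperatures = 1,
                                          audit_every = 0))
  together <- mean(vapply(ch$samples, function(g) g[1] == g[2], logical(1)))
  expect_gt(together, 0.9)
})

test_that("Monte-Carlo prior sampling leaves the chain near the exact-prior posterior", {
  set.seed(27)
  xs <- make_small_dataset(N = 12)[, 1:4]
  xs <- standardize_expression(xs)
  colnames(xs) <- paste0("g", 1:4)
  ps <- prior_set(data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"),
                             p = c(0.8, 0.5)), paste0("g", 1:4))
  post <- enumerate_posterior(xs, ps)
  ctrl <- sampler_control(n_iterations = 60000, burn_in = 5000, thin = 1,
                          n_temperatures = 1, prior_method = "mc",
                          mc_prior_samples = 200, audit_every = 0)
  ch <- run_chain(xs, ps, ctrl)
  emp <- table(factor(vapply(ch$samples, paste, character(1),
                             collapse = ","), levels = post$keys))
  emp <- as.numeric(emp) / length(ch$samples)
  expect_lt(0.5 * sum(abs(emp - post$prob)), 0.08)
})

test_that("tempering with one temperature degenerates to the plain chain", {
  set.seed(31)
  xs <- make_small_dataset(N = 10)
  ctrl <- sampler_control(n_iterations = 2000, burn_in = 200, thin = 10,
                          n_temperatures = 1, audit_every = 0)
  set.seed(55); a <- run_chain(xs, NULL, ctrl)
  set.seed(55); b <- run_tempered(xs, NULL, ctrl)
  expect_identical(a$samples, b$samples)
})

test_that("tempered chains mix across modes and report swap statistics", {
  set.seed(37)
  # two well-separated blocks
  z1 <- rnorm(15); z2 <- rnorm(15)
  x <- cbind(z1 + rnorm(15, 0, .1), z1 + rnorm(15, 0, .1),
             z2 + rnorm(15, 0, .1), z2 + rnorm(15, 0, .1))
  xs <- standardize_expression(x)
  colnames(xs) <- paste0("g", 1:4)
  ctrl <- sampler_control(n_iterations = 8000, burn_in = 1000, thin = 5,
                          n_temperatures = 3, temperature_ratio = 0.5,
                          audit_every = 0)
  ch <- run_tempered(xs, NULL, ctrl)
  expect_false(is.na(ch$swap_rate))
  expect_gte(ch$swap_rate, 0)
  # the dominant two-block structure is recovered in most samples
  frac <- mean(vapply(ch$samples, function(g) {
    g[1] == g[2] && g[3] == g[4] && g[1] != g[3]
  }, logical(1)))
  expect_gt(frac, 0.5)
})

test_that("sampler_control validates its arguments", {
  expect_error(sampler_control(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(sampler_control(thin = 0), "thin")
  expect_error(sampler_control(n_temperatures = 2, temperature_ratio = 1.2),
               "temperature_ratio")
  expect_error(sampler_control(mc_prior_samples = 0), "mc_prior_samples")
})
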