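genes6 <- paste0("g", 1:6)

test_that("remove_cycles keeps the maximum-weight spanning forest", {
  tri <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
                    p = c(0.8, 0.8, 0.7))
  rc <- remove_cycles(tri)
  expect_equal(nrow(rc$kept), 2)
  expect_equal(rc$removed$p, 0.7)       # smallest edge of the cycle goes
  expect_setequal(paste(rc$removed$gene_a, rc$removed$gene_b), "A C")

  forest <- data.frame(gene_a = c("A", "B", "D"), gene_b = c("B", "C", "E"),
                       p = c(0.9, 0.5, 0.7))
  rc2 <- remove_cycles(forest)
  expect_equal(rc2$kept, forest)
  expect_equal(nrow(rc2$removed), 0)

  # two triangles sharing edge B-C: exactly two removals, result acyclic
  two_tri <- data.frame(
    gene_a = c("A", "B", "A", "B", "C"), gene_b = c("B", "C", "C", "D", "D"),
    p = c(0.9, 0.8, 0.6, 0.7, 0.5))
  two_tri <- rbind(two_tri, data.frame(gene_a = "B", gene_b = "E", p = 0.4))
  rc3 <- remove_cycles(two_tri)
  expect_equal(nrow(rc3$removed), 2)
  expect_equal(nrow(rc3$kept), 4)
  expect_false(priorclust:::.has_cycle(
    match(rc3$kept$gene_a, LETTERS), match(rc3$kept$gene_b, LETTERS), 26))
})

test_that("remove_cycles output weight dominates all spanning forests", {
  # brute force over edge subsets on random small graphs
  set.seed(13)
  for (rep in 1:20) {
    m <- sample(4:7, 1)
    ed <- t(combn(5, 2))[sample(10, m), , drop = FALSE]
    pairs <- data.frame(gene_a = letters[ed[, 1]], gene_b = letters[ed[, 2]],
                        p = round(runif(m), 3))
    kept <- remove_cycles(pairs)$kept
    best <- 0
    for (mask in seq_len(2^m) - 1L) {
      on <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
      if (!any(on)) next
      if (!priorclust:::.has_cycle(ed[on, 1], ed[on, 2], 5))
        best <- max(best, sum(pairs$p[on]))
    }
    expect_equal(sum(kept$p), best, tolerance = 1e-12)
  }
})

test_that("pair forcing probability enumerates enforcement masks", {
  tri <- data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
                    p = 0.8)
  expect_equal(pair_force_probability(tri, "A", "B"), 0.928)
  one <- data.frame(gene_a = "A", gene_b = "B", p = 0.37)
  expect_equal(pair_force_probability(one, "A", "B"), 0.37)
  chain <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"), p = 0.5)
  expect_equal(pair_force_probability(chain, "A", "C"), 0.25)
  # transitivity at p = 1 (clamping happens downstream in prior_set only)
  chain1 <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"), p = 1)
  expect_equal(pair_force_probability(chain1, "A", "C"), 1)
  big <- data.frame(gene_a = paste0("x", 1:25), gene_b = paste0("y", 1:25),
                    p = 0.5)
  expect_error(pair_force_probability(big, "x1", "y1"), "q > 20")
})

test_that("total pair prior probability mixes enforcement with baseline", {
  expect_equal(total_pair_prior_probability(0.8, 0.1), 0.82)
  expect_equal(total_pair_prior_probability(1, 0.3), 1)
  expect_equal(total_pair_prior_probability(0, 0.3), 0.3)
  expect_error(total_pair_prior_probability(1.2, 0.5), "\\[0, 1\\]")
})

test_that("prior_set validates input and clamps certain pairs", {
  ps <- prior_set(data.frame(gene_a = "g1", gene_b = "g2", p = 1), genes6)
  expect_equal(ps$pairs$p, 1 - 1e-12)
  expect_error(prior_set(data.frame(gene_a = "g1", gene_b = "g1", p = .5),
                         genes6), "self-pair")
  expect_error(prior_set(data.frame(gene_a = "g1", gene_b = "zz", p = .5),
                         genes6), "not in gene universe")
  cyc <- data.frame(gene_a = c("g1", "g2", "g1"),
                    gene_b = c("g2", "g3", "g3"), p = .5)
  expect_error(prior_set(cyc, genes6), "cycle")
})

test_that("exact prior equals literal mask enumeration and normalises", {
  set.seed(7)
  pairs <- data.frame(gene_a = c("g1", "g2", "g4"),
                      gene_b = c("g2", "g3", "g5"),
                      p = c(0.7, 0.4, 0.9))
  ps <- prior_set(pairs, genes6)
  parts <- all_partitions(6)
  tot <- 0
  for (g in parts) {
    le <- log_prior_exact(g, ps)
    expect_equal(le, brute_force_log_prior(g, pairs, genes6),
                 tolerance = 1e-10)
    tot <- tot + exp(le)
  }
  expect_equal(tot, 1, tolerance = 1e-8)
  # empty prior reduces to the baseline measure
  ps0 <- prior_set(NULL, genes6)
  g <- c(1, 1, 2, 2, 3, 3)
  expect_equal(log_prior_exact(g, ps0), log_baseline_prior(g))
})

test_that("exact prior normalises for several q <= 3 configurations", {
  configs <- list(
    data.frame(gene_a = "g1", gene_b = "g2", p = 0.99),
    data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"),
               p = c(0.5, 0.8)),
    data.frame(gene_a = c("g1", "g2", "g4"), gene_b = c("g2", "g3", "g5"),
               p = c(0.9, 0.6, 0.3)))
  for (n in 4:6) {
    genes <- paste0("g", seq_len(n))
    parts <- all_partitions(n)
    for (pairs in configs) {
      if (!all(c(pairs$gene_a, pairs$gene_b) %in% genes)) next
      ps <- prior_set(pairs, genes)
      tot <- sum(vapply(parts, function(g) exp(log_prior_exact(g, ps)),
                        numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-8)
    }
  }
})

test_that("prior mass is monotone in the probability of a co-grouped pair", {
  g <- c(1, 1, 2, 2, 3, 3)  # co-groups g1-g2
  vals <- vapply(seq(0.05, 0.95, by = 0.1), function(pp) {
    ps <- prior_set(data.frame(gene_a = c("g1", "g3"),
                               gene_b = c("g2", "g5"),
                               p = c(pp, 0.4)), genes6)
    log_prior_exact(g, ps)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("near-certain pair concentrates prior mass on merged units", {
  genes3 <- paste0("g", 1:3)
  ps <- prior_set(data.frame(gene_a = "g1", gene_b = "g2", p = 1), genes3)
  # enforced mask dominates: P = 1/((n-1) N(n-1, K)) = 1/2
  expect_equal(log_prior_exact(c(1, 1, 2), ps), log(0.5), tolerance = 1e-9)
})

test_that("Monte-Carlo prior estimator is exact in degenerate cases and unbiased", {
  set.seed(21)
  pairs <- data.frame(gene_a = c("g1", "g2", "g4"),
                      gene_b = c("g2", "g3", "g5"),
                      p = c(0.7, 0.4, 0.9))
  ps <- prior_set(pairs, genes6)
  # no co-grouped prior pair -> zero-variance single term
  g_split <- c(1, 2, 1, 3, 4, 3)  # g1-g2, g2-g3, g4-g5 all split
  expected <- sum(log1p(-ps$pairs$p)) - log(6) -
    log_partition_count(6, max(g_split))
  expect_equal(log_prior_mc(g_split, ps, 5), expected)
  # all p = 0 -> baseline prior exactly
  ps0 <- prior_set(data.frame(gene_a = "g1", gene_b = "g2", p = 0), genes6)
  g <- c(1, 1, 2, 2, 3, 3)
  expect_equal(log_prior_mc(g, ps0, 5), log_baseline_prior(g))
  # unbiasedness: mean of exp(estimate) matches exact value
  ex <- exp(log_prior_exact(g, ps))
  est <- mean(replicate(400, exp(log_prior_mc(g, ps, 100))))
  expect_equal(est, ex, tolerance = 0.05)
  expect_error(log_prior_mc(g, ps, 0), ">= 1")
})

test_that("Monte-Carlo estimator variance shrinks like 1/n_samples", {
  set.seed(33)
  pairs <- data.frame(gene_a = paste0("g", 1:3),
                      gene_b = paste0("g", 4:6),
                      p = c(0.6, 0.7, 0.8))
  ps <- prior_set(pairs, genes6)
  g <- c(1, 1, 1, 1, 2, 2)   # co-groups g1-g4 and g2-g5... check co-grouping
  v_small <- var(replicate(300, exp(log_prior_mc(g, ps, 20))))
  v_big <- var(replicate(300, exp(log_prior_mc(g, ps, 400))))
  expect_lt(v_big, v_small / 5)
})
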