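test_that("simulated trees validate and obey the stop-on-taxa rule", {
  Q <- matrix(c(0, 0.05, 0.05, 0), 2L, 2L)
  p <- musse_parameters(c(0.4, 0.3), c(0.1, 0.05), Q)
  for (seed in c(1, 2, 3)) {
    sim <- sim_with_retry(p, stop_taxa = 40, seed = seed)
    expect_silent(validate_phylogeny(sim$phy))
    expect_equal(length(sim$phy$tip.label), 40L)
    expect_true(all(sim$phy$edge.length >= 0))
    expect_true(ape::is.ultrametric(sim$phy, tol = 1e-8))
    expect_true(all(sim$states %in% 0:1))
  }
})

test_that("simulation is reproducible and pure birth equals complete tree", {
  p <- musse_parameters(c(0.5, 0.5), c(0, 0),
                        matrix(c(0, 0.1, 0.1, 0), 2L, 2L))
  cfg <- simulation_config(p, stop_taxa = 30, seed = 17,
                           include_complete = TRUE)
  s1 <- simulate_musse_tree(cfg)
  s2 <- simulate_musse_tree(cfg)
  expect_identical(write_newick(s1$phy), write_newick(s2$phy))
  expect_identical(as.integer(s1$states), as.integer(s2$states))
  # with mu = 0 nothing is pruned: complete tree == returned tree
  expect_equal(length(s1$complete$tip.label), length(s1$phy$tip.label))
  expect_equal(sum(s1$complete$edge.length), sum(s1$phy$edge.length),
               tolerance = 1e-9)
})

test_that("degenerate simulations fail loudly", {
  p0 <- musse_parameters(0, 0)
  expect_error(simulate_musse_tree(simulation_config(p0, stop_taxa = 5,
                                                     seed = 1)),
               "froze|extinction")
  # certain extinction
  pex <- musse_parameters(0, 1)
  expect_error(simulate_musse_tree(simulation_config(pex, stop_time = 50,
                                                     seed = 1)),
               "extinction")
  expect_error(simulation_config(p0, stop_taxa = 5, stop_time = 1),
               "exactly one")
})

test_that("pure-birth tip counts match the branching-process expectation", {
  # E[N(T)] = e^{lambda T} for a Yule process from one lineage
  p <- musse_parameters(1, 0)
  set.seed(404)
  n <- vapply(1:2000, function(i) {
    rec <- guilddiv:::gillespie_musse_cpp(1, 0, matrix(0, 1, 1), 0L, 0L, 1,
                                          1e6)
    sum(rec$type == 2L)
  }, numeric(1L))
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - exp(1)), 3 * se)
})

test_that("fast symmetric switching drives tip states to the uniform mix", {
  q <- 8
  p <- musse_parameters(c(0.5, 0.5), c(0, 0),
                        matrix(c(0, q, q, 0), 2L, 2L))
  set.seed(99)
  freqs <- vapply(1:30, function(i) {
    sim <- simulate_musse_tree(simulation_config(p, stop_taxa = 100,
                                                 seed = 6000 + i))
    mean(sim$states == 0L)
  }, numeric(1L))
  se <- stats::sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 3 * se + 0.01)
})

test_that("Mk simulation inherits, mixes and decays with distance", {
  phy <- oracle_random_tree(60, height = 1)
  # q = 0: every tip inherits the root state
  st0 <- simulate_mk_character(phy, matrix(0, 2L, 2L), root_state = 1L,
                               seed = 1)
  expect_true(all(st0 == 1L))
  # long branches with symmetric q: frequencies near 1/2
  phy_long <- phy
  phy_long$edge.length <- phy_long$edge.length * 100
  set.seed(2)
  f <- vapply(1:40, function(i)
    mean(simulate_mk_character(phy_long, matrix(c(0, 1, 1, 0), 2L, 2L),
                               root_state = 0L) == 0L), numeric(1L))
  expect_lt(abs(mean(f) - 0.5), 3 * stats::sd(f) / sqrt(40) + 0.01)
  # states of close tips agree more often than states of distant tips
  set.seed(3)
  Q <- matrix(c(0, 1.5, 1.5, 0), 2L, 2L)
  dmat <- patristic_distances(phy)
  agree <- matrix(0, 60, 60)
  for (i in 1:60) {
    st <- simulate_mk_character(phy, Q, root_state = 0L)
    v <- as.integer(st[rownames(dmat)])
    agree <- agree + outer(v, v, "==")
  }
  ut <- upper.tri(dmat)
  expect_lt(stats::cor(dmat[ut], agree[ut], method = "spearman"), 0)
})

test_that("adequacy envelopes behave at the edges and flag impossible data", {
  p <- musse_parameters(c(0.4, 0.4), c(0.05, 0.05),
                        matrix(c(0, 0.1, 0.1, 0), 2L, 2L))
  # n_trees = 1: envelope collapses onto that tree's proportions
  ad1 <- adequacy_test(p, n_trees = 1L, stop_taxa = 50,
                       empirical_props = c(0.5, 0.5), seed = 4)
  expect_equal(ad1$envelope["low", ], ad1$props[1L, ])
  expect_equal(ad1$envelope["high", ], ad1$props[1L, ])
  # a state that cannot persist (lambda 0, high mu) cannot reach 100%
  p_dead <- musse_parameters(c(0.5, 0), c(0.01, 0.6),
                             matrix(c(0, 0.05, 0.05, 0), 2L, 2L))
  ad2 <- adequacy_test(p_dead, n_trees = 30L, stop_taxa = 60,
                       empirical_props = c(0, 1), root_state = 0L, seed = 5)
  expect_false(ad2$inside[2L])
  expect_true(all(abs(rowSums(ad2$props) - 1) < 1e-9))
})

test_that("neutral characters on rate-equal fits yield no flagged differences", {
  # constrained sanity case: identical marginals cannot be flagged
  n <- 500L
  df <- data.frame(iter = seq_len(n), tree_tag = "t", loglik = 0,
                   logpost = 0,
                   lambda_0 = stats::rnorm(n, 0.3, 0.02),
                   mu_0 = stats::rnorm(n, 0.1, 0.02), check.names = FALSE)
  df$lambda_1 <- df$lambda_0
  df$mu_1 <- df$mu_0
  class(df) <- c("posterior_trace", "data.frame")
  attr(df, "k") <- 2L
  rc <- rate_differences(df, 0L)
  expect_false(any(unlist(rc$significant)))
  expect_error(neutral_association_test(list(), matrix(0, 2, 2)), "empty")
})

test_that("the neutral-character pipeline runs end to end on a small tree", {
  set.seed(11)
  p <- musse_parameters(c(0.5, 0.5), c(0.1, 0.1),
                        matrix(c(0, 0.3, 0.3, 0), 2L, 2L))
  sim <- simulate_musse_tree(simulation_config(p, stop_taxa = 60, seed = 21))
  res <- neutral_association_test(
    list(sim$phy), q_hat = p$Q,
    cfg = mcmc_config(steps = 600, thin = 2, burnin = 0.2, seed = 9),
    opts = likelihood_options(rtol = 1e-4, atol = 1e-7), seed = 13)
  expect_length(res$flagged, 1L)
  expect_true(res$false_positive_fraction %in% c(0, 1))
})
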