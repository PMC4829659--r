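test_that("branch integration honours trivial identities", {
  p <- musse_parameters(c(0.3, 0.1), c(0.05, 0.02),
                        matrix(c(0, 0.1, 0.2, 0), 2L, 2L, byrow = TRUE))
  s0 <- ode_state(E = c(0.1, 0.2), D = c(0.5, 0.4))
  # t = 0 is the identity
  s1 <- branch_integrate(s0, 0, p)
  expect_equal(s1$E, s0$E)
  expect_equal(s1$D, s0$D)
  # all rates zero: the vector field vanishes
  p0 <- musse_parameters(c(0, 0), c(0, 0))
  s2 <- branch_integrate(s0, 3.7, p0)
  expect_equal(s2$E, s0$E, tolerance = 1e-12)
  expect_equal(s2$D, s0$D, tolerance = 1e-12)
})

test_that("k=1 pure-death branch matches the closed-form linear solution", {
  mu <- 0.3
  p <- musse_parameters(0, mu)
  for (t in c(0.1, 1, 5)) {
    out <- branch_integrate(ode_state(0.2, 0.7), t, p)
    expect_equal(out$E, 1 + (0.2 - 1) * exp(-mu * t), tolerance = 1e-8)
    expect_equal(out$D, 0.7 * exp(-mu * t), tolerance = 1e-8)
  }
})

test_that("k=1 likelihood matches the closed-form birth-death likelihood", {
  set.seed(101)
  for (i in 1:5) {
    phy <- oracle_random_tree(sample(5:15, 1L), height = 2)
    lam <- stats::runif(1, 0.3, 0.8)
    mu <- stats::runif(1, 0.05, 0.25)
    states <- tip_state_map(phy$tip.label,
                            rep(0L, length(phy$tip.label)), k = 1L)
    ll <- musse_loglik(phy, states, musse_parameters(lam, mu))
    expect_equal(ll, oracle_bd_loglik(phy, lam, mu), tolerance = 1e-6)
    # and without conditioning
    ll2 <- musse_loglik(phy, states, musse_parameters(lam, mu),
                        likelihood_options(condition_surv = FALSE))
    expect_equal(ll2, oracle_bd_loglik(phy, lam, mu, condition = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("random 3-state instances match the brute-force RK4 oracle", {
  set.seed(202)
  for (i in 1:5) {
    n <- sample(4:6, 1L)
    phy <- oracle_random_tree(n, height = 1)
    k <- 3L
    lambda <- stats::runif(k, 0.1, 0.5)
    mu <- stats::runif(k, 0.01, 0.2)
    Q <- matrix(stats::runif(k * k, 0.01, 0.15), k, k)
    diag(Q) <- 0
    st <- tip_state_map(phy$tip.label, sample(0:(k - 1L), n, TRUE), k = k)
    ll <- musse_loglik(phy, st, musse_parameters(lambda, mu, Q))
    ll_oracle <- oracle_musse_loglik(phy, st, lambda, mu, Q, h = 1e-4)
    expect_equal(ll, ll_oracle, tolerance = 1e-5)
  }
})

test_that("state-independent rates factorize into birth-death x Mk", {
  set.seed(303)
  for (i in 1:3) {
    phy <- oracle_random_tree(10, height = 2)
    lam <- stats::runif(1, 0.3, 0.6)
    mu <- stats::runif(1, 0.05, 0.2)
    q <- stats::runif(1, 0.1, 0.5)
    Q <- matrix(c(0, q, q, 0), 2L, 2L)
    st <- tip_state_map(phy$tip.label, sample(0:1, 10, TRUE), k = 2L)
    ll <- musse_loglik(phy, st, musse_parameters(c(lam, lam), c(mu, mu), Q))
    expect_equal(ll, oracle_bd_loglik(phy, lam, mu) +
                   oracle_mk_loglik(phy, st, Q),
                 tolerance = 1e-6)
  }
})

test_that("likelihood is invariant to child order and consistent relabeling", {
  set.seed(404)
  phy <- oracle_random_tree(12, height = 1.5)
  k <- 2L
  p <- musse_parameters(c(0.4, 0.2), c(0.1, 0.05),
                        matrix(c(0, 0.1, 0.05, 0), 2L, 2L, byrow = TRUE))
  st <- tip_state_map(phy$tip.label, sample(0:1, 12, TRUE), k = k)
  ll <- musse_loglik(phy, st, p)
  # rotate children at every node (ape stores the same tree, children swapped)
  rot <- ape::rotateConstr(phy, rev(phy$tip.label))
  expect_equal(musse_loglik(rot, st, p), ll, tolerance = 1e-8)
  # relabel tips preserving states
  phy2 <- phy
  phy2$tip.label <- paste0("x_", phy$tip.label)
  st2 <- tip_state_map(phy2$tip.label, as.integer(st[phy$tip.label]), k = k)
  expect_equal(musse_loglik(phy2, st2, p), ll, tolerance = 1e-12)
})

test_that("unreachable states cannot influence the likelihood", {
  phy <- oracle_random_tree(8, height = 1)
  st <- tip_state_map(phy$tip.label, rep(0L, 8L), k = 2L)
  base <- musse_loglik(phy, st, musse_parameters(c(0.5, 0.5), c(0.1, 0.1)))
  moved <- musse_loglik(phy, st, musse_parameters(c(0.5, 0.5), c(0.1, 5)))
  expect_equal(base, moved, tolerance = 1e-9)
})

test_that("unknown tip states and full sampling fractions behave as defined", {
  set.seed(505)
  phy <- oracle_random_tree(8, height = 1)
  k <- 2L
  p <- musse_parameters(c(0.4, 0.2), c(0.1, 0.05),
                        matrix(c(0, 0.1, 0.1, 0), 2L, 2L))
  st <- tip_state_map(phy$tip.label, sample(0:1, 8, TRUE), k = k)
  # f = 1 equals the default
  p_f <- musse_parameters(p$lambda, p$mu, p$Q, f = c(1, 1))
  expect_equal(musse_loglik(phy, st, p_f), musse_loglik(phy, st, p))
  # an unknown tip marginalises over both states: likelihood is the sum of
  # the two fully observed alternatives
  st_na <- st
  st_na[[1L]] <- NA_integer_
  attr(st_na, "k") <- k
  alt <- vapply(0:1, function(s) {
    sti <- st
    sti[[1L]] <- s
    attr(sti, "k") <- k
    exp(musse_loglik(phy, sti, p))
  }, numeric(1L))
  expect_equal(exp(musse_loglik(phy, st_na, p)), sum(alt), tolerance = 1e-6)
})

test_that("E stays within [0,1] during integration on random instances", {
  set.seed(606)
  for (i in 1:20) {
    k <- sample(1:3, 1L)
    p <- musse_parameters(stats::runif(k, 0, 1), stats::runif(k, 0, 1),
                          matrix(stats::runif(k * k, 0, 0.5), k, k))
    out <- branch_integrate(ode_state(stats::runif(k), stats::runif(k)),
                            stats::runif(1, 0, 5), p)
    expect_true(all(out$E >= -1e-8 & out$E <= 1 + 1e-8))
    expect_true(all(out$D >= 0))
  }
})

test_that("parameter accounting matches the model structure", {
  expect_equal(parameter_count(9, 3), 93L)
  expect_equal(parameter_count(1, 0), 2L)
  expect_equal(parameter_count(2, 3), 9L)
  expect_length(musse_param_names(3), parameter_count(3, 3))
})

test_that("flat parameter vectors round-trip", {
  Q <- matrix(c(0, 0.1, 0.2, 0.3, 0, 0.4, 0.5, 0.6, 0), 3L, 3L,
              byrow = TRUE)
  p <- musse_parameters(c(0.3, 0.2, 0.1), c(0.05, 0.04, 0.03), Q)
  v <- flatten_parameters(p)
  expect_named(v, musse_param_names(3, hyper = FALSE))
  p2 <- unflatten_parameters(v, 3L)
  expect_equal(p2$lambda, p$lambda)
  expect_equal(p2$Q, p$Q)
})

test_that("polytomies and unmapped tips are rejected by the likelihood", {
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  st <- tip_state_map(c("A", "B", "C"), c(0L, 0L, 0L), k = 1L)
  expect_error(musse_loglik(poly, st, musse_parameters(0.5, 0.1)),
               "polytomy|binary")
  phy <- read_newick("((A:1,B:1):1,C:2);")
  st2 <- tip_state_map(c("A", "B"), c(0L, 1L), k = 2L)
  expect_error(musse_loglik(phy, st2, musse_parameters(c(0.5, 0.5),
                                                       c(0.1, 0.1))),
               "missing")
})
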