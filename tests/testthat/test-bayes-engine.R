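test_that("half-Cauchy prior density has the right closed-form properties", {
  s <- 0.7
  expect_equal(exp(dhalfcauchy(1e-12, s)), 2 / (pi * s), tolerance = 1e-6)
  # doubling the scale halves the density at 0
  expect_equal(exp(dhalfcauchy(1e-12, 2 * s)),
               exp(dhalfcauchy(1e-12, s)) / 2, tolerance = 1e-6)
  expect_identical(dhalfcauchy(-0.1, s), -Inf)
  p <- musse_parameters(c(0.1, -1), c(0.1, 0.1)) |> try(silent = TRUE)
  expect_s3_class(p, "try-error") # negative rates never reach the prior
  expect_identical(
    log_prior(musse_parameters(c(0.1, 0.2), c(0.1, 0.1)),
              c(s_lambda = 1, s_mu = 1, s_q = 1e6)), -Inf)
})

test_that("thinning accounting and determinism hold for short chains", {
  phy <- oracle_random_tree(10, height = 1)
  st <- tip_state_map(phy$tip.label, rep(0L, 10L), k = 1L)
  cfg <- mcmc_config(steps = 10000, thin = 1000, seed = 99)
  expect_equal(n_retained(cfg), 10L)
  tr1 <- run_mcmc(phy, st, cfg, likelihood_options(rtol = 1e-5, atol = 1e-8))
  tr2 <- run_mcmc(phy, st, cfg, likelihood_options(rtol = 1e-5, atol = 1e-8))
  expect_equal(nrow(tr1), 10L)
  expect_identical(tr1, tr2) # same seed, same trace
  expect_true(all(is.finite(tr1$loglik)))
  # default configuration accounting, without running it
  expect_equal(n_retained(mcmc_config()), 1500L)
})

test_that("a prior-only chain reproduces half-Cauchy marginal quantiles", {
  phy <- oracle_random_tree(6, height = 1)
  st <- tip_state_map(phy$tip.label, rep(0L, 6L), k = 1L)
  cfg <- mcmc_config(steps = 6000, thin = 2, burnin = 0.1, seed = 42,
                     widths = c(lambda = 1, mu = 1, q = 1, hyper = 1))
  tr <- run_mcmc(phy, st, cfg, k = 1L, prior_only = TRUE,
                 fixed = c(s_lambda = 1, s_mu = 1, s_q = 1))
  tr <- combine_traces(list(tr), burnin = 0.1)
  qs <- stats::quantile(tr$lambda_0, c(0.25, 0.5, 0.75))
  theory <- tan(pi / 2 * c(0.25, 0.5, 0.75)) # half-Cauchy(1) quartiles
  expect_equal(unname(qs), theory, tolerance = 0.12)
})

test_that("posterior mean matches a grid-posterior oracle on one parameter", {
  set.seed(77)
  sim <- simulate_musse_tree(simulation_config(musse_parameters(0.4, 0.1),
                                               stop_taxa = 60, seed = 31))
  fixed <- c(mu_0 = 0.1, s_lambda = 1, s_mu = 1, s_q = 1)
  cfg <- mcmc_config(steps = 3000, thin = 2, burnin = 0.1, seed = 8)
  tr <- run_mcmc(sim$phy, sim$states, cfg,
                 likelihood_options(rtol = 1e-6, atol = 1e-9),
                 fixed = fixed)
  tr <- combine_traces(list(tr), burnin = 0.1)
  # independent oracle: closed-form BD likelihood on a lambda grid
  lam_g <- seq(0.05, 1.2, length.out = 600)
  lp <- vapply(lam_g, function(l)
    oracle_bd_loglik(sim$phy, l, 0.1) + dhalfcauchy(l, 1), numeric(1L))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  grid_mean <- sum(w * lam_g)
  grid_sd <- sqrt(sum(w * (lam_g - grid_mean)^2))
  expect_equal(mean(tr$lambda_0), grid_mean, tolerance = 3 * grid_sd /
                 sqrt(effective_size(tr$lambda_0)) + 0.01)
})

test_that("combine_traces trims burn-in, concatenates and refuses mismatches", {
  mk_trace <- function(val, n = 100L, k = 1L) {
    df <- data.frame(iter = seq_len(n), tree_tag = "t", loglik = 0,
                     logpost = 0, lambda_0 = val, mu_0 = val / 2,
                     s_lambda = 1, s_mu = 1, s_q = 1, check.names = FALSE)
    class(df) <- c("posterior_trace", "data.frame")
    attr(df, "k") <- k
    df
  }
  t1 <- mk_trace(1)
  t2 <- mk_trace(3)
  comb <- combine_traces(list(t1, t2), burnin = 0.1)
  expect_equal(nrow(comb), 180L)
  # combined mean is the weighted mean of trace means
  expect_equal(mean(comb$lambda_0), 2)
  expect_equal(nrow(combine_traces(list(t1), burnin = 0.1)), 90L)
  t3 <- mk_trace(1)
  names(t3)[5L] <- "lambda_X"
  expect_error(combine_traces(list(t1, t3), burnin = 0), "mismatch")
  t4 <- mk_trace(1, k = 2L)
  expect_error(combine_traces(list(t1, t4)), "different k")
})

test_that("net diversification is the per-sample rate difference", {
  df <- data.frame(iter = 1:3, tree_tag = "t", loglik = 0, logpost = 0,
                   lambda_0 = c(0.2, 0.3, 0.1), mu_0 = c(0.05, 0.3, 0.1),
                   check.names = FALSE)
  class(df) <- c("posterior_trace", "data.frame")
  attr(df, "k") <- 1L
  r <- net_diversification(df)
  expect_equal(as.numeric(r[, "r_0"]), c(0.15, 0, 0))
  expect_equal(stats::median(r[, "r_0"]),
               stats::median(df$lambda_0 - df$mu_0))
})

test_that("HPD intervals are shortest windows with nested widths", {
  expect_equal(hpd_interval(rep(2, 10), 0.95), c(2, 2))
  set.seed(12)
  u <- stats::runif(10000)
  h <- hpd_interval(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.02)
  x <- stats::rnorm(5000)
  w <- vapply(c(0.80, 0.90, 0.95), function(m) diff(hpd_interval(x, m)),
              numeric(1L))
  expect_true(all(diff(w) > 0))
  # a clearly skewed sample: HPD hugs the mode, unlike the central interval
  y <- stats::rexp(5000)
  expect_lt(hpd_interval(y, 0.9)[1], stats::quantile(y, 0.05))
  expect_error(hpd_interval(numeric(0)), "2 samples")
})

test_that("rate differences flag separation correctly", {
  n <- 1500L
  mk <- function(l0, l1, m0, m1) {
    df <- data.frame(iter = seq_len(n), tree_tag = "t", loglik = 0,
                     logpost = 0, lambda_0 = l0, lambda_1 = l1,
                     mu_0 = m0, mu_1 = m1, check.names = FALSE)
    class(df) <- c("posterior_trace", "data.frame")
    attr(df, "k") <- 2L
    df
  }
  set.seed(3)
  base <- stats::rnorm(n, 0.3, 0.05)
  # identical marginals: differences exactly zero
  rc0 <- rate_differences(mk(base, base, base / 2, base / 2), focal = 0L)
  expect_true(all(rc0$diffs$speciation == 0))
  expect_false(any(unlist(rc0$significant)))
  # constant offset: significant at every level
  rc1 <- rate_differences(mk(base, base + 1, base / 2, base / 2), focal = 0L)
  expect_true(all(rc1$significant$speciation))
  # independent normals separated by 5 sd: significant at 95%
  a <- stats::rnorm(n, 0.5, 0.1)
  b <- stats::rnorm(n, 0.0, 0.1)
  rc2 <- rate_differences(mk(b, a, abs(b) / 2, abs(b) / 2), focal = 0L)
  expect_true(rc2$significant$speciation["state_1", "hpd95"])
  expect_error(rate_differences(mk(base, base, base, base), focal = 5L),
               "0..k-1")
})

test_that("traces round-trip through the CSV schema", {
  phy <- oracle_random_tree(8, height = 1)
  st <- tip_state_map(phy$tip.label, rep(0L, 8L), k = 1L)
  tr <- run_mcmc(phy, st, mcmc_config(steps = 400, thin = 40, seed = 5),
                 likelihood_options(rtol = 1e-5, atol = 1e-8))
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  expect_match(readLines(f, n = 1L), "guilddiv-trace-1 k=1")
  back <- read_trace(f)
  expect_equal(attr(back, "k"), 1L)
  expect_equal(back$lambda_0, tr$lambda_0, tolerance = 1e-12)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("iter,tree_tag", "1,t"), f2)
  expect_error(read_trace(f2), "schema")
})
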