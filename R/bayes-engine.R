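## Bayesian MCMC over MuSSE parameters.  Each of the three rate families
## (speciation, extinction, transition) gets a half-Cauchy prior located at
## zero whose scale is itself estimated (a hyperprior per family), which lets
## rates be very small but never exactly zero.  Sampling is univariate slice
## sampling on the natural, positive scale -- robust for heavy-tailed priors
## and free of proposal tuning.

#' Log density of the half-Cauchy distribution (location 0)
#'
#' Density `2 / (pi s (1 + (x/s)^2))` for `x > 0`; `-Inf` for `x <= 0`.
#'
#' @param x quantiles.
#' @param scale scale parameter `s > 0`.
#' @return log densities.
#' @export
dhalfcauchy <- function(x, scale) {
  out <- rep(-Inf, length(x))
  ok <- x > 0
  out[ok] <- log(2) - log(pi) - log(scale) - log1p((x[ok] / scale)^2)
  out
}

#' Joint log prior of a MuSSE parameter set under the hyperprior structure
#'
#' Each speciation rate is half-Cauchy(0, `s_lambda`), each extinction rate
#' half-Cauchy(0, `s_mu`), each transition rate half-Cauchy(0, `s_q`); the
#' three scales carry a log-uniform prior on `bounds`.  Any non-positive rate
#' or out-of-bounds scale gives `-Inf`.
#'
#' @param pars a [musse_parameters()].
#' @param scales named vector or list with `s_lambda`, `s_mu`, `s_q`.
#' @param bounds lower and upper bound of the log-uniform hyper-scale prior.
#' @return the log prior density.
#' @export
log_prior <- function(pars, scales, bounds = c(1e-2, 1e2)) {
  stopifnot(inherits(pars, "musse_parameters"))
  s <- c(scales[["s_lambda"]], scales[["s_mu"]], scales[["s_q"]])
  if (any(s < bounds[1] | s > bounds[2])) return(-Inf)
  qv <- pars$Q[row(pars$Q) != col(pars$Q)]
  lp <- sum(dhalfcauchy(pars$lambda, s[1])) +
    sum(dhalfcauchy(pars$mu, s[2])) - 3 * log(log(bounds[2] / bounds[1])) -
    sum(log(s))
  if (length(qv)) lp <- lp + sum(dhalfcauchy(qv, s[3]))
  lp
}

#' MCMC configuration
#'
#' @param steps total number of MCMC steps (one step = a full slice-sampling
#'   cycle over all free parameters).  Default 1,500,000.
#' @param thin sampling interval; every `thin`-th step is retained, so a run
#'   keeps `floor(steps / thin)` samples.  Default 1,000.
#' @param burnin fraction of retained samples discarded by downstream
#'   analysis (applied after thinning); the same fraction of steps is used
#'   for slice-width adaptation, after which widths are frozen.
#' @param seed optional RNG seed for a reproducible chain.
#' @param widths initial slice widths per parameter family.
#' @param hyper_bounds support of the log-uniform hyper-scale prior.
#' @param tune adapt slice widths during burn-in.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(steps = 1500000L, thin = 1000L, burnin = 0.1,
                        seed = NULL,
                        widths = c(lambda = 0.2, mu = 0.2, q = 0.05,
                                   hyper = 1),
                        hyper_bounds = c(1e-2, 1e2), tune = TRUE) {
  steps <- as.integer(steps); thin <- as.integer(thin)
  if (thin < 1L || steps < thin) stop("need steps >= thin >= 1")
  if (burnin < 0 || burnin >= 1) stop("burnin must lie in [0, 1)")
  structure(list(steps = steps, thin = thin, burnin = burnin, seed = seed,
                 widths = widths, hyper_bounds = hyper_bounds,
                 tune = isTRUE(tune)),
            class = "mcmc_config")
}

#' Number of samples a configuration retains
#' @param cfg an [mcmc_config()].
#' @return `floor(steps / thin)`.
#' @export
n_retained <- function(cfg) {
  as.integer(cfg$steps %/% cfg$thin)
}

# one univariate slice-sampling update (Neal 2003, stepping out + shrinkage)
.slice1 <- function(x0, f0, logf, w, lower = 0, upper = Inf,
                    max_step = 50L) {
  y <- f0 - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  i <- max_step
  while (L > lower && i > 0L && logf(L) > y) { L <- L - w; i <- i - 1L }
  i <- max_step
  while (R < upper && i > 0L && logf(R) > y) { R <- R + w; i <- i - 1L }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    f1 <- logf(x1)
    if (f1 >= y) return(list(x = x1, f = f1))
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-300) return(list(x = x0, f = f0))
  }
}

#' Run the MuSSE MCMC on one tree
#'
#' Univariate slice sampling cycles over all speciation, extinction and
#' transition rates and the three hyper-scales.  Hyper-scale updates use the
#' conditional prior only (the likelihood does not involve them), so they are
#' cheap; every rate update re-evaluates the tree likelihood.
#'
#' @param phy a validated binary `phylo`.
#' @param states a [tip_state_map()]; `k` is taken from it unless `k` is
#'   given.
#' @param cfg an [mcmc_config()].
#' @param opts a [likelihood_options()].
#' @param k number of states (optional override).
#' @param init optional named vector of starting values in
#'   [musse_param_names()] layout (rates and/or scales).
#' @param fixed optional named vector of parameters to hold fixed.
#' @param prior_only replace the likelihood by a constant (prior-predictive
#'   chain, used for sampler validation).
#' @param tree_tag tag recorded with every sample (defaults to the tree's
#'   [tree_tag()], or `"tree"`).
#' @param verbose print progress every 10% of steps.
#' @return a `posterior_trace` data frame of `floor(steps / thin)` samples
#'   with columns `iter, tree_tag, loglik, logpost`, all parameters and the
#'   three hyper-scales; effective sample sizes are in `attr(, "ess")`.
#' @export
run_mcmc <- function(phy, states, cfg = mcmc_config(),
                     opts = likelihood_options(), k = NULL, init = NULL,
                     fixed = NULL, prior_only = FALSE, tree_tag = NULL,
                     verbose = FALSE) {
  validate_phylogeny(phy)
  if (is.null(k)) k <- attr(states, "k")
  if (is.null(k)) stop("k not given and not recoverable from the state map")
  k <- as.integer(k)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(tree_tag)) tree_tag <- tree_tag(phy)
  if (is.null(tree_tag)) tree_tag <- "tree"

  st <- .states_for_tree(phy, states)
  if (any(!is.na(st) & st >= k)) stop("tip state exceeds k - 1")
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  rp <- if (is.null(opts$root_prior)) rep(1 / k, k) else opts$root_prior
  root_mode <- match(opts$root_mode, c("weighted", "equal", "given")) - 1L
  fvec <- rep(1, k)

  nm <- musse_param_names(k)
  n_rate <- 2L * k + k * (k - 1L)
  fam <- c(rep("lambda", k), rep("mu", k), rep("q", k * (k - 1L)),
           rep("hyper", 3L))
  names(fam) <- nm
  qidx <- which(startsWith(nm, "q_"))

  theta <- stats::setNames(numeric(length(nm)), nm)
  th <- max(ape::node.depth.edgelength(phy))
  lam0 <- max(log(ntip) / max(th, 1e-8), 0.05)
  theta[seq_len(k)] <- lam0
  theta[k + seq_len(k)] <- lam0 / 2
  if (n_rate > 2L * k) theta[(2L * k + 1L):n_rate] <- lam0 / 10
  theta[c("s_lambda", "s_mu", "s_q")] <- 1
  if (!is.null(init)) theta[names(init)] <- init
  if (!is.null(fixed)) theta[names(fixed)] <- fixed
  free <- setdiff(nm, names(fixed))

  Qm <- matrix(0, k, k)
  qcells <- if (length(qidx)) {
    ij <- do.call(rbind, strsplit(nm[qidx], "_", fixed = TRUE))
    cbind(as.integer(ij[, 2L]) + 1L, as.integer(ij[, 3L]) + 1L)
  } else NULL
  fill_Q <- function(v) {
    if (!is.null(qcells)) Qm[qcells] <<- v[qidx]
  }
  loglik_fun <- function(v) {
    if (prior_only) return(0)
    fill_Q(v)
    musse_loglik_cpp(po$edge, po$edge.length, ntip, as.integer(st),
                     v[seq_len(k)], v[k + seq_len(k)], Qm, fvec,
                     root_mode, isTRUE(opts$condition_surv), rp,
                     opts$rtol, opts$atol)
  }

  bounds <- cfg$hyper_bounds
  widths <- cfg$widths
  move_avg <- c(lambda = widths[["lambda"]] / 2, mu = widths[["mu"]] / 2,
                q = widths[["q"]] / 2, hyper = widths[["hyper"]] / 2)

  cur_ll <- loglik_fun(theta)
  if (!is.finite(cur_ll))
    stop("initial likelihood is not finite; offending parameters: ",
         paste(sprintf("%s=%.4g", nm, theta), collapse = ", "))

  nkeep <- n_retained(cfg)
  out <- matrix(NA_real_, nkeep, length(nm),
                dimnames = list(NULL, nm))
  out_ll <- numeric(nkeep)
  out_lp <- numeric(nkeep)
  out_iter <- integer(nkeep)
  tune_until <- if (cfg$tune) floor(cfg$burnin * cfg$steps) else 0L
  row <- 0L

  for (step in seq_len(cfg$steps)) {
    for (pn in free) {
      fm <- fam[[pn]]
      x0 <- theta[[pn]]
      if (fm == "hyper") {
        rfam <- switch(pn, s_lambda = theta[seq_len(k)],
                       s_mu = theta[k + seq_len(k)],
                       s_q = if (n_rate > 2L * k)
                         theta[(2L * k + 1L):n_rate] else numeric(0))
        logf <- function(s) {
          if (s < bounds[1] || s > bounds[2]) return(-Inf)
          sum(dhalfcauchy(rfam, s)) - log(s)
        }
        res <- .slice1(x0, logf(x0), logf, widths[["hyper"]],
                       lower = bounds[1], upper = bounds[2])
        theta[[pn]] <- res$x
      } else {
        sfam <- theta[[paste0("s_", fm)]]
        last_ll <- cur_ll
        logf <- function(x) {
          if (x <= 0) return(-Inf)
          v <- theta
          v[[pn]] <- x
          ll <- loglik_fun(v)
          last_ll <<- ll
          ll + dhalfcauchy(x, sfam)
        }
        f0 <- cur_ll + dhalfcauchy(x0, sfam)
        res <- .slice1(x0, f0, logf, widths[[fm]], lower = 0, upper = Inf)
        if (res$x != x0) {
          theta[[pn]] <- res$x
          cur_ll <- last_ll
        }
      }
      if (step <= tune_until)
        move_avg[[fm]] <- 0.95 * move_avg[[fm]] +
          0.05 * abs(theta[[pn]] - x0)
    }
    if (step == tune_until && tune_until > 0L)
      for (fm in names(widths))
        widths[[fm]] <- max(2.5 * move_avg[[fm]], 1e-8)
    if (step %% cfg$thin == 0L) {
      row <- row + 1L
      out[row, ] <- theta
      out_ll[row] <- cur_ll
      out_lp[row] <- cur_ll +
        log_prior(unflatten_parameters(theta, k),
                  theta[c("s_lambda", "s_mu", "s_q")], bounds)
      out_iter[row] <- step
    }
    if (verbose && step %% max(1L, cfg$steps %/% 10L) == 0L)
      message(sprintf("step %d / %d  loglik %.3f", step, cfg$steps, cur_ll))
  }

  trace <- data.frame(iter = out_iter, tree_tag = tree_tag,
                      loglik = out_ll, logpost = out_lp,
                      out, check.names = FALSE,
                      stringsAsFactors = FALSE)
  class(trace) <- c("posterior_trace", "data.frame")
  attr(trace, "k") <- k
  attr(trace, "burnin") <- cfg$burnin
  attr(trace, "schema") <- "guilddiv-trace-1"
  attr(trace, "ess") <- vapply(nm[!nm %in% names(fixed)],
                               function(p) effective_size(trace[[p]]),
                               numeric(1L))
  trace
}

#' Effective sample size by initial positive autocorrelation sequence
#' @param x a numeric sample vector.
#' @return the estimated ESS.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 2L, 500L),
                               plot = FALSE)$acf)[-1L]
  s <- 0
  for (r in rho) {
    if (r < 0.01) break
    s <- s + r
  }
  max(1, n / (1 + 2 * s))
}

#' Combine posterior traces across trees
#'
#' Removes the leading burn-in fraction of each trace, then concatenates;
#' source-tree tags are preserved.  Traces must agree in parameter names
#' (mixed `k` is refused).
#'
#' @param traces a list of `posterior_trace` objects.
#' @param burnin fraction of each trace dropped from the front; defaults to
#'   the burn-in recorded in each trace (0.1 when absent).
#' @return a combined `posterior_trace`.
#' @export
combine_traces <- function(traces, burnin = NULL) {
  if (!length(traces)) stop("no traces to combine")
  nm <- names(traces[[1L]])
  ks <- vapply(traces, function(tr) as.integer(attr(tr, "k")), integer(1L))
  if (length(unique(ks)) != 1L)
    stop("refusing to combine traces with different k: ",
         paste(unique(ks), collapse = ", "))
  trimmed <- lapply(traces, function(tr) {
    if (!identical(names(tr), nm)) stop("parameter name mismatch across traces")
    b <- if (is.null(burnin)) {
      bb <- attr(tr, "burnin"); if (is.null(bb)) 0.1 else bb
    } else burnin
    drop <- floor(b * nrow(tr))
    if (drop > 0L) tr[-seq_len(drop), , drop = FALSE] else tr
  })
  out <- do.call(rbind, lapply(trimmed, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("posterior_trace", "data.frame")
  attr(out, "k") <- ks[1L]
  attr(out, "burnin") <- 0
  attr(out, "schema") <- "guilddiv-trace-1"
  out
}

#' Per-state net diversification samples
#'
#' `r_i = lambda_i - mu_i`, computed sample by sample.
#'
#' @param trace a `posterior_trace`.
#' @return a matrix with one column `r_i` per state, `nrow(trace)` rows.
#' @export
net_diversification <- function(trace) {
  k <- attr(trace, "k")
  if (is.null(k)) stop("trace lacks a k attribute")
  lam <- paste0("lambda_", seq_len(k) - 1L)
  mu <- paste0("mu_", seq_len(k) - 1L)
  miss <- setdiff(c(lam, mu), names(trace))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- as.matrix(trace[, lam, drop = FALSE]) -
    as.matrix(trace[, mu, drop = FALSE])
  colnames(out) <- paste0("r_", seq_len(k) - 1L)
  out
}

#' Highest posterior density interval of an empirical sample
#'
#' The shortest contiguous window of `ceiling(mass * n)` sorted samples; by
#' construction a single interval.
#'
#' @param x sample vector (`length >= 2`).
#' @param mass probability mass, e.g. 0.95, 0.90 or 0.80.
#' @return `c(low, high)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  xs <- sort(x)
  m <- min(n, ceiling(mass * n))
  starts <- seq_len(n - m + 1L)
  widths <- xs[starts + m - 1L] - xs[starts]
  i <- starts[which.min(widths)]
  c(xs[i], xs[i + m - 1L])
}

#' Posterior rate differences of every state against a focal state
#'
#' Builds, per MCMC sample, the differences `state rate - focal rate` for
#' speciation, extinction and net diversification, with HPD intervals at the
#' 95/90/80% levels.  A difference is flagged significant at a level when 0
#' lies outside that HPD interval.
#'
#' @param trace a `posterior_trace`.
#' @param focal focal state index (0-based), e.g. the omnivore state.
#' @param levels HPD masses.
#' @return a `rate_comparison` object.
#' @export
rate_differences <- function(trace, focal, levels = c(0.95, 0.90, 0.80)) {
  k <- attr(trace, "k")
  if (is.null(k)) stop("trace lacks a k attribute")
  focal <- as.integer(focal)
  if (focal < 0L || focal >= k) stop("focal state not in 0..k-1")
  others <- setdiff(seq_len(k) - 1L, focal)
  r <- net_diversification(trace)
  get <- function(prefix, s)
    if (prefix == "r") r[, paste0("r_", s)] else trace[[paste0(prefix, "_", s)]]
  types <- c(speciation = "lambda", extinction = "mu",
             net_diversification = "r")
  diffs <- lapply(types, function(pfx) {
    m <- vapply(others, function(s) get(pfx, s) - get(pfx, focal),
                numeric(nrow(trace)))
    colnames(m) <- paste0("state_", others)
    m
  })
  hpd <- lapply(diffs, function(m) {
    lapply(stats::setNames(levels, paste0("hpd", levels * 100)), function(lv) {
      t(apply(m, 2L, hpd_interval, mass = lv))
    })
  })
  signif <- lapply(hpd, function(h) {
    m <- vapply(h, function(ints) ints[, 1L] > 0 | ints[, 2L] < 0,
                logical(length(others)))
    matrix(m, nrow = length(others),
           dimnames = list(paste0("state_", others), names(h)))
  })
  structure(list(focal = focal, others = others, levels = levels,
                 diffs = diffs, hpd = hpd, significant = signif,
                 n_samples = nrow(trace)),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Rate differences vs focal state", x$focal,
      sprintf("(%d posterior samples)\n", x$n_samples))
  for (ty in names(x$diffs)) {
    cat("\n", ty, " (state - focal):\n", sep = "")
    med <- apply(x$diffs[[ty]], 2L, stats::median)
    h95 <- x$hpd[[ty]][[1L]]
    sig <- x$significant[[ty]]
    for (i in seq_along(med))
      cat(sprintf("  state_%d: median %+.4f  95%% HPD [%+.4f, %+.4f]%s\n",
                  x$others[i], med[i], h95[i, 1L], h95[i, 2L],
                  if (sig[i, 1L]) " *" else ""))
  }
  invisible(x)
}

#' Write a rate comparison as JSON
#'
#' Per guild and rate type: the HPD bounds per level and the significance
#' flag.
#'
#' @param rc a `rate_comparison`.
#' @param path output path.
#' @return `rc`, invisibly.
#' @export
write_rate_comparison_json <- function(rc, path) {
  out <- lapply(names(rc$diffs), function(ty) {
    per_state <- lapply(seq_along(rc$others), function(i) {
      lv <- lapply(seq_along(rc$levels), function(j) {
        ints <- rc$hpd[[ty]][[j]]
        list(interval = as.numeric(ints[i, ]),
             significant = unname(rc$significant[[ty]][i, j]))
      })
      names(lv) <- paste0("level_", rc$levels * 100)
      lv
    })
    names(per_state) <- paste0("state_", rc$others)
    per_state
  })
  names(out) <- names(rc$diffs)
  jsonlite::write_json(list(focal = rc$focal, comparisons = out), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(rc)
}

#' Write / read a posterior trace as CSV
#'
#' The file carries a schema comment line
#' (`# guilddiv-trace-1 k=<k>`) followed by the standard header
#' `iter,tree_tag,loglik,logpost,lambda_0,...,s_lambda,s_mu,s_q`.
#'
#' @param trace a `posterior_trace`.
#' @param path CSV path.
#' @return the trace, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# guilddiv-trace-1 k=%d", attr(trace, "k")), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(trace)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# guilddiv-trace-1", first))
    stop("not a guilddiv trace file (schema line missing)")
  k <- as.integer(sub(".*k=(\\d+).*", "\\1", first))
  tr <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  class(tr) <- c("posterior_trace", "data.frame")
  attr(tr, "k") <- k
  attr(tr, "schema") <- "guilddiv-trace-1"
  tr
}
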