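## Forward simulation under MuSSE (Gillespie event simulation on lineages),
## neutral Mk character simulation on fixed trees, and the two
## simulation-based checks: model adequacy (do the fitted rates reproduce the
## observed state proportions?) and the neutral-character false-positive
## test.

#' Simulation configuration
#'
#' Exactly one stop rule must be given.  Stop-on-taxa samples the tree at the
#' moment the (n+1)-th birth would occur, which avoids the bias of stopping
#' exactly at the n-th birth.  Simulation starts from a single stem lineage;
#' the returned tree's root is the first surviving bifurcation.
#'
#' @param pars a [musse_parameters()].
#' @param stop_taxa target number of extant tips (or `NULL`).
#' @param stop_time target simulation time (or `NULL`).
#' @param root_state starting state (0-based), or `"stationary"` to draw from
#'   the stationary distribution of the transition chain.
#' @param seed optional RNG seed.
#' @param max_events event cap guarding against runaway simulations.
#' @param include_complete also return the complete tree with extinct tips.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(pars, stop_taxa = NULL, stop_time = NULL,
                              root_state = 0L, seed = NULL,
                              max_events = 1e6, include_complete = FALSE) {
  stopifnot(inherits(pars, "musse_parameters"))
  if (is.null(stop_taxa) == is.null(stop_time))
    stop("give exactly one of stop_taxa, stop_time")
  if (!is.null(stop_taxa) && stop_taxa < 2L) stop("stop_taxa must be >= 2")
  if (!is.null(stop_time) && stop_time <= 0) stop("stop_time must be > 0")
  if (max_events <= 0) stop("max_events must be positive")
  structure(list(pars = pars, stop_taxa = stop_taxa, stop_time = stop_time,
                 root_state = root_state, seed = seed,
                 max_events = max_events,
                 include_complete = isTRUE(include_complete)),
            class = "simulation_config")
}

.stationary_state <- function(Q) {
  k <- nrow(Q)
  G <- Q
  diag(G) <- -rowSums(Q)
  A <- rbind(t(G), rep(1, k))
  pi_ <- tryCatch(as.numeric(qr.solve(A, c(rep(0, k), 1))),
                  error = function(e) rep(1 / k, k))
  pi_ <- pmax(pi_, 0)
  pi_ / sum(pi_)
}

# lineage records -> ape phylo (complete tree, including extinct tips)
.records_to_phylo <- function(rec) {
  type <- rec$type
  m <- length(type)
  is_tip <- type != 0L
  ntip <- sum(is_tip)
  if (ntip < 2L) stop("simulation produced fewer than 2 tips")
  nnode <- m - ntip
  id <- integer(m)
  id[is_tip] <- seq_len(ntip)
  id[!is_tip] <- ntip + seq_len(nnode) # root lineage (index 1) is first split
  if (type[1L] != 0L) stop("stem lineage never split")
  stopifnot(id[1L] == ntip + 1L)
  child <- which(rec$parent > 0L)
  edge <- cbind(id[rec$parent[child]], id[child])
  edge_len <- rec$tend[child] - rec$tstart[child]
  labs <- character(ntip)
  labs[id[is_tip]] <- ifelse(type[is_tip] == 2L,
                             paste0("sp", seq_len(m)[is_tip]),
                             paste0("ex", seq_len(m)[is_tip]))
  structure(list(edge = edge, edge.length = edge_len,
                 tip.label = labs, Nnode = nnode,
                 root.edge = rec$tend[1L] - rec$tstart[1L]),
            class = "phylo")
}

#' Simulate a phylogeny under a MuSSE process
#'
#' Gillespie event simulation from a single stem lineage: per-lineage rates
#' `lambda_i` (speciation), `mu_i` (extinction) and `q_ij` (state change).
#' Extinct lineages are pruned from the returned tree; tip states are the
#' states at stop time.  Complete extinction (or a surviving tree with fewer
#' than 2 tips) is an error, which the caller may catch and retry.
#'
#' @param cfg a [simulation_config()].
#' @return a list with `phy` (pruned ultrametric-in-time tree), `states`
#'   (a [tip_state_map()]), `t_stop`, and when requested `complete` (the
#'   un-pruned tree) and `complete_states`.
#' @export
simulate_musse_tree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- cfg$pars
  root_state <- cfg$root_state
  if (identical(root_state, "stationary"))
    root_state <- sample(seq_len(p$k) - 1L, 1L,
                         prob = .stationary_state(p$Q))
  root_state <- as.integer(root_state)
  if (root_state < 0L || root_state >= p$k) stop("root_state not in 0..k-1")

  rec <- gillespie_musse_cpp(p$lambda, p$mu, p$Q, root_state,
                             if (is.null(cfg$stop_taxa)) 0L else
                               as.integer(cfg$stop_taxa),
                             if (is.null(cfg$stop_time)) Inf else
                               cfg$stop_time,
                             cfg$max_events)
  if (!is.finite(rec$t_stop))
    stop("simulation froze before reaching the stop rule (all rates zero?)")
  if (!any(rec$type == 2L))
    stop("complete extinction before the stop rule")

  complete <- .records_to_phylo(rec)
  extinct <- complete$tip.label[startsWith(complete$tip.label, "ex")]
  if (length(complete$tip.label) - length(extinct) < 2L)
    stop("fewer than 2 surviving tips")
  phy <- if (length(extinct)) ape::drop.tip(complete, extinct) else complete
  phy$root.edge <- NULL
  validate_phylogeny(phy)

  idx <- as.integer(sub("^sp", "", phy$tip.label))
  states <- tip_state_map(phy$tip.label, rec$state[idx], k = p$k)
  out <- list(phy = phy, states = states, t_stop = rec$t_stop)
  if (cfg$include_complete) {
    out$complete <- complete
    tipi <- as.integer(sub("^(sp|ex)", "", complete$tip.label))
    out$complete_states <- tip_state_map(complete$tip.label,
                                         rec$state[tipi], k = p$k)
  }
  out
}

#' Simulate a discrete (Mk) character along a fixed tree
#'
#' The state evolves along each branch as a continuous-time Markov chain
#' with generator off-diagonals `Q[i, j]`; diversification is unaffected
#' (the character is neutral).
#'
#' @param phy a validated `phylo`.
#' @param Q `k x k` transition-rate matrix (diagonal ignored).
#' @param root_state starting state (0-based) or `"stationary"`.
#' @param seed optional RNG seed.
#' @return a [tip_state_map()] over the tips.
#' @export
simulate_mk_character <- function(phy, Q, root_state = 0L, seed = NULL) {
  validate_phylogeny(phy)
  if (!is.null(seed)) set.seed(seed)
  Q <- as.matrix(Q)
  k <- nrow(Q)
  diag(Q) <- 0
  if (any(Q < 0)) stop("negative transition rate")
  qrow <- rowSums(Q)
  if (identical(root_state, "stationary"))
    root_state <- sample(seq_len(k) - 1L, 1L, prob = .stationary_state(Q))
  root_state <- as.integer(root_state)
  if (root_state < 0L || root_state >= k) stop("root_state not in 0..k-1")

  ntip <- length(phy$tip.label)
  cw <- ape::reorder.phylo(phy, "cladewise")
  node_state <- integer(ntip + phy$Nnode)
  node_state[ntip + 1L] <- root_state + 1L
  for (e in seq_len(nrow(cw$edge))) {
    s <- node_state[cw$edge[e, 1L]]
    len <- cw$edge.length[e]
    t <- 0
    repeat {
      if (qrow[s] <= 0) break
      t <- t + stats::rexp(1, qrow[s])
      if (t > len) break
      s <- sample.int(k, 1L, prob = Q[s, ])
    }
    node_state[cw$edge[e, 2L]] <- s
  }
  tip_state_map(phy$tip.label, node_state[seq_len(ntip)] - 1L, k = k)
}

#' Model adequacy check by posterior-predictive tip-state proportions
#'
#' Simulates `n_trees` trees under the supplied parameters, records the
#' tip-state proportions of each, and flags whether each empirical
#' proportion lies inside the central 95% envelope.  Envelope endpoints are
#' the order statistics `floor(0.025 (m + 1))` and `ceiling(0.975 (m + 1))`
#' of the `m` simulated proportions, so nominal coverage is guaranteed.
#'
#' @param pars a [musse_parameters()].
#' @param n_trees number of simulated trees.
#' @param stop_taxa,stop_time stop rule forwarded to [simulation_config()].
#' @param empirical_props observed per-state proportions (length `k`,
#'   summing to 1).
#' @param root_state forwarded to the simulator (default `"stationary"`).
#' @param seed optional RNG seed.
#' @param max_retry retries per tree on complete extinction.
#' @return an `adequacy_result` with `props` (trees x states), `envelope`
#'   (2 x k), `empirical`, and `inside` flags.
#' @export
adequacy_test <- function(pars, n_trees, stop_taxa = NULL, stop_time = NULL,
                          empirical_props, root_state = "stationary",
                          seed = NULL, max_retry = 100L) {
  stopifnot(inherits(pars, "musse_parameters"))
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (length(empirical_props) != pars$k ||
      abs(sum(empirical_props) - 1) > 1e-6)
    stop("empirical_props must be k proportions summing to 1")
  if (!is.null(seed)) set.seed(seed)
  k <- pars$k
  props <- matrix(NA_real_, n_trees, k,
                  dimnames = list(NULL, paste0("state_", seq_len(k) - 1L)))
  for (i in seq_len(n_trees)) {
    sim <- NULL
    for (a in seq_len(max_retry)) {
      sim <- tryCatch(
        simulate_musse_tree(simulation_config(pars, stop_taxa = stop_taxa,
                                              stop_time = stop_time,
                                              root_state = root_state)),
        error = function(e) NULL)
      if (!is.null(sim)) break
    }
    if (is.null(sim)) stop("all simulations went extinct for tree ", i)
    props[i, ] <- tabulate(sim$states + 1L, nbins = k) / length(sim$states)
  }
  m <- n_trees
  lo_i <- max(1L, floor(0.025 * (m + 1)))
  hi_i <- min(m, ceiling(0.975 * (m + 1)))
  env <- apply(props, 2L, function(x) sort(x)[c(lo_i, hi_i)])
  rownames(env) <- c("low", "high")
  inside <- empirical_props >= env["low", ] & empirical_props <= env["high", ]
  structure(list(props = props, envelope = env,
                 empirical = as.numeric(empirical_props), inside = inside),
            class = "adequacy_result")
}

#' @export
print.adequacy_result <- function(x, ...) {
  cat("Adequacy check over", nrow(x$props), "simulated trees\n")
  for (j in seq_len(ncol(x$props)))
    cat(sprintf("  %s: empirical %.3f, envelope [%.3f, %.3f] -> %s\n",
                colnames(x$props)[j], x$empirical[j],
                x$envelope["low", j], x$envelope["high", j],
                if (x$inside[j]) "inside" else "OUTSIDE"))
  invisible(x)
}

#' Write an adequacy result as JSON
#' @param x an `adequacy_result`.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_adequacy_json <- function(x, path) {
  jsonlite::write_json(
    list(n_trees = nrow(x$props),
         empirical = x$empirical,
         envelope_low = as.numeric(x$envelope["low", ]),
         envelope_high = as.numeric(x$envelope["high", ]),
         inside = as.logical(x$inside)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' Neutral-character false-positive test
#'
#' For each tree, simulates a diversification-neutral character under the
#' supplied transition rates, fits the full MuSSE model by MCMC, and reports
#' whether any between-state speciation or extinction difference is flagged
#' significant -- i.e. whether the model finds trait-rate associations where
#' none exist.
#'
#' @param trees list of validated `phylo` objects.
#' @param q_hat `k x k` transition-rate matrix used to simulate the neutral
#'   character (for example, posterior median transition rates).
#' @param cfg an [mcmc_config()] for the per-tree fits.
#' @param opts a [likelihood_options()].
#' @param level HPD mass used for the significance flag.
#' @param seed optional RNG seed.
#' @return a `neutral_test_result` with per-tree flags and the aggregate
#'   false-positive fraction.
#' @export
neutral_association_test <- function(trees, q_hat, cfg = mcmc_config(),
                                     opts = likelihood_options(),
                                     level = 0.95, seed = NULL) {
  if (!length(trees)) stop("empty tree list")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(as.matrix(q_hat))
  flagged <- logical(length(trees))
  details <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    phy <- trees[[i]]
    states <- simulate_mk_character(phy, q_hat, root_state = "stationary")
    tr <- run_mcmc(phy, states, cfg = cfg, opts = opts, k = k,
                   tree_tag = paste0("neutral_", i))
    tr <- combine_traces(list(tr))
    any_sig <- FALSE
    per_focal <- list()
    for (focal in seq_len(k) - 1L) {
      rc <- rate_differences(tr, focal, levels = level)
      sig <- rc$significant$speciation[, 1L] | rc$significant$extinction[, 1L]
      per_focal[[as.character(focal)]] <- sig
      if (any(sig)) any_sig <- TRUE
    }
    flagged[i] <- any_sig
    details[[i]] <- per_focal
  }
  structure(list(flagged = flagged,
                 false_positive_fraction = mean(flagged),
                 details = details, level = level),
            class = "neutral_test_result")
}
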