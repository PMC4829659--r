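## Exact log-likelihood of a k-state MuSSE model: per-branch integration of
## the coupled extinction-probability (E) and data-density (D) ODEs with an
## adaptive embedded Runge-Kutta scheme, pruning joins at internal nodes with
## running log-compensation against underflow, and configurable root
## treatment.  The numerical core lives in src/musse.cpp.

#' MuSSE parameter set
#'
#' Per-state speciation and extinction rates, off-diagonal transition rates,
#' and optional per-state sampling fractions.
#'
#' @param lambda numeric vector of speciation rates (per unit time, `>= 0`),
#'   one per state.
#' @param mu numeric vector of extinction rates, same length.
#' @param Q `k x k` matrix of transition rates; the diagonal is ignored and
#'   stored as zero.  For `k = 1` may be omitted.
#' @param f per-state sampling fractions in `(0, 1]`; default 1 (complete
#'   sampling).
#' @return an object of class `musse_parameters`.
#' @export
musse_parameters <- function(lambda, mu, Q = NULL, f = 1) {
  k <- length(lambda)
  if (k < 1L) stop("k must be >= 1")
  if (length(mu) != k) stop("mu must have length k")
  if (is.null(Q)) Q <- matrix(0, k, k)
  Q <- as.matrix(Q)
  if (!all(dim(Q) == k)) stop("Q must be k x k")
  diag(Q) <- 0
  if (length(f) == 1L) f <- rep(f, k)
  if (length(f) != k) stop("f must have length k")
  vals <- c(lambda, mu, Q)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rates must be finite and non-negative")
  if (any(f <= 0 | f > 1)) stop("sampling fractions must lie in (0, 1]")
  structure(list(k = k, lambda = as.numeric(lambda), mu = as.numeric(mu),
                 Q = Q, f = as.numeric(f)),
            class = "musse_parameters")
}

#' Likelihood options: root treatment and solver tolerances
#'
#' @param root_mode `"weighted"` (weights proportional to the root D values,
#'   the data-informed default), `"equal"`, or `"given"` with `root_prior`.
#' @param root_prior probability vector over states, used when
#'   `root_mode = "given"`.
#' @param condition_surv condition the likelihood on survival of the two
#'   crown lineages (divides each root D by `lambda_i (1 - E_i)^2` before
#'   weighting).  Default `TRUE`.
#' @param rtol,atol relative and absolute ODE tolerances.
#' @return an object of class `likelihood_options`.
#' @export
likelihood_options <- function(root_mode = c("weighted", "equal", "given"),
                               root_prior = NULL, condition_surv = TRUE,
                               rtol = 1e-8, atol = 1e-10) {
  root_mode <- match.arg(root_mode)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  if (root_mode == "given") {
    if (is.null(root_prior) || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-8)
      stop("root_mode 'given' needs a probability vector root_prior")
  }
  structure(list(root_mode = root_mode, root_prior = root_prior,
                 condition_surv = condition_surv, rtol = rtol, atol = atol),
            class = "likelihood_options")
}

#' A per-branch ODE state
#'
#' @param E extinction probabilities per state, each in `[0, 1]`.
#' @param D likelihood densities per state, each `>= 0`.
#' @param logcomp accumulated log-compensation scalar.
#' @return an `ode_state` list.
#' @export
ode_state <- function(E, D, logcomp = 0) {
  if (length(E) != length(D)) stop("E and D must have equal length")
  if (any(E < 0 | E > 1)) stop("E values must lie in [0, 1]")
  if (any(D < 0)) stop("D values must be non-negative")
  structure(list(E = as.numeric(E), D = as.numeric(D),
                 logcomp = as.numeric(logcomp)), class = "ode_state")
}

#' Integrate an ODE state along a branch
#'
#' Propagates `(E, D)` tipward-to-rootward over a duration `t` under the
#' MuSSE equations.  `t = 0` returns the state unchanged; a solver failure is
#' an error, never a silent clamp.
#'
#' @param state an [ode_state()].
#' @param t branch duration (`>= 0`).
#' @param pars a [musse_parameters()].
#' @param opts a [likelihood_options()] (tolerances are used).
#' @return the propagated `ode_state`.
#' @export
branch_integrate <- function(state, t, pars, opts = likelihood_options()) {
  stopifnot(inherits(state, "ode_state"), inherits(pars, "musse_parameters"))
  if (length(state$E) != pars$k) stop("state dimension does not match k")
  if (t < 0) stop("negative duration")
  out <- musse_branch_cpp(state$E, state$D, t, pars$lambda, pars$mu, pars$Q,
                          opts$rtol, opts$atol)
  ode_state(out$E, out$D, state$logcomp + out$logcomp)
}

#' MuSSE log-likelihood of tip states on a phylogeny
#'
#' Post-order pruning: tips are initialised with `D_i = f_i` for the observed
#' state (all states for an unknown tip) and `E_i = 1 - f_i`; branches are
#' integrated under the MuSSE ODEs; at each node the two daughter D vectors
#' are joined as `lambda_i * D_left * D_right` and rescaled to a maximum of 1
#' with the log factor accumulated.  The root is aggregated according to
#' `opts`.
#'
#' @param phy a validated binary `phylo`.
#' @param states a [tip_state_map()] covering every tip (`NA` = unknown).
#' @param pars a [musse_parameters()].
#' @param opts a [likelihood_options()].
#' @return the log-likelihood (finite, or `-Inf` for impossible data).
#' @export
musse_loglik <- function(phy, states, pars, opts = likelihood_options()) {
  validate_phylogeny(phy)
  stopifnot(inherits(pars, "musse_parameters"))
  st <- .states_for_tree(phy, states)
  kmap <- attr(states, "k")
  if (!is.null(kmap) && kmap != pars$k)
    stop("state map has k = ", kmap, " but parameters have k = ", pars$k)
  if (any(!is.na(st) & st >= pars$k))
    stop("tip state exceeds k - 1")
  po <- ape::reorder.phylo(phy, "postorder")
  root_mode <- match(opts$root_mode, c("weighted", "equal", "given")) - 1L
  rp <- if (is.null(opts$root_prior)) rep(1 / pars$k, pars$k) else opts$root_prior
  musse_loglik_cpp(po$edge, po$edge.length, length(phy$tip.label),
                   as.integer(st), pars$lambda, pars$mu, pars$Q, pars$f,
                   root_mode, isTRUE(opts$condition_surv), rp,
                   opts$rtol, opts$atol)
}

#' Number of free parameters of the Bayesian MuSSE model
#'
#' `k` speciation rates, `k` extinction rates, `k (k - 1)` transition rates,
#' plus the hyperprior scale parameters.
#'
#' @param k number of states.
#' @param hyper_scales number of estimated hyperprior scales (3 in the
#'   standard setup: one per rate family).
#' @return an integer count.
#' @export
parameter_count <- function(k, hyper_scales = 3L) {
  if (k < 1L) stop("k must be >= 1")
  as.integer(k + k + k * (k - 1L) + hyper_scales)
}

#' Canonical flat parameter names
#'
#' `lambda_0..lambda_{k-1}, mu_0.., q_i_j (i != j, row-wise), s_lambda, s_mu,
#' s_q` -- the column layout used by trace files.
#'
#' @param k number of states.
#' @param hyper include the three hyper-scale names.
#' @return character vector of names.
#' @export
musse_param_names <- function(k, hyper = TRUE) {
  qn <- character(0)
  for (i in seq_len(k) - 1L)
    for (j in seq_len(k) - 1L)
      if (i != j) qn <- c(qn, paste0("q_", i, "_", j))
  out <- c(paste0("lambda_", seq_len(k) - 1L), paste0("mu_", seq_len(k) - 1L),
           qn)
  if (hyper) out <- c(out, "s_lambda", "s_mu", "s_q")
  out
}

#' Flatten parameters to the named-vector trace format
#' @param pars a [musse_parameters()].
#' @return named numeric vector (no hyper scales).
#' @export
flatten_parameters <- function(pars) {
  stopifnot(inherits(pars, "musse_parameters"))
  k <- pars$k
  qv <- numeric(0)
  for (i in seq_len(k))
    for (j in seq_len(k))
      if (i != j) qv <- c(qv, pars$Q[i, j])
  stats::setNames(c(pars$lambda, pars$mu, qv), musse_param_names(k, FALSE))
}

#' Rebuild parameters from a flat named vector
#' @param x named numeric vector in [musse_param_names()] layout.
#' @param k number of states.
#' @param f sampling fractions passed through to [musse_parameters()].
#' @return a `musse_parameters` object.
#' @export
unflatten_parameters <- function(x, k, f = 1) {
  nm <- musse_param_names(k, FALSE)
  if (!all(nm %in% names(x)))
    stop("missing parameter(s): ", paste(setdiff(nm, names(x)), collapse = ", "))
  lambda <- x[paste0("lambda_", seq_len(k) - 1L)]
  mu <- x[paste0("mu_", seq_len(k) - 1L)]
  Q <- matrix(0, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k))
      if (i != j) Q[i, j] <- x[[paste0("q_", i - 1L, "_", j - 1L)]]
  musse_parameters(unname(lambda), unname(mu), Q, f)
}
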