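# Independent oracles used by the likelihood tests.  These deliberately
# avoid the package's C++ ODE path: a fixed-step classical RK4 integrator in
# plain R, the closed-form constant-rate birth-death likelihood, and an Mk
# character likelihood via matrix exponentials.

# MuSSE right-hand side in R
oracle_musse_rhs <- function(y, lambda, mu, Q) {
  k <- length(lambda)
  E <- y[seq_len(k)]
  D <- y[k + seq_len(k)]
  qrow <- rowSums(Q)
  tot <- lambda + mu + qrow
  dE <- mu - tot * E + lambda * E^2 + as.numeric(Q %*% E)
  dD <- -tot * D + 2 * lambda * E * D + as.numeric(Q %*% D)
  c(dE, dD)
}

# fixed-step classical RK4 over a branch
oracle_branch_rk4 <- function(E0, D0, t, lambda, mu, Q, h = 1e-4) {
  y <- c(E0, D0)
  if (t == 0) return(y)
  nstep <- ceiling(t / h)
  h <- t / nstep
  for (i in seq_len(nstep)) {
    k1 <- oracle_musse_rhs(y, lambda, mu, Q)
    k2 <- oracle_musse_rhs(y + h / 2 * k1, lambda, mu, Q)
    k3 <- oracle_musse_rhs(y + h / 2 * k2, lambda, mu, Q)
    k4 <- oracle_musse_rhs(y + h * k3, lambda, mu, Q)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# full-tree MuSSE log-likelihood by brute-force RK4 pruning (no rescaling:
# intended for small trees only).  Mirrors the package's root conventions:
# element-wise conditioning, then weights proportional to the conditioned D.
oracle_musse_loglik <- function(phy, states, lambda, mu, Q, h = 1e-4,
                                condition = TRUE) {
  k <- length(lambda)
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  st <- states[phy$tip.label]
  Dn <- matrix(NA_real_, ntip + phy$Nnode, k)
  En <- matrix(NA_real_, ntip + phy$Nnode, k)
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2L]
    pa <- po$edge[e, 1L]
    if (ch <= ntip) {
      D0 <- as.numeric(seq_len(k) - 1L == st[ch])
      E0 <- rep(0, k)
    } else {
      D0 <- Dn[ch, ]
      E0 <- En[ch, ]
    }
    y <- oracle_branch_rk4(E0, D0, po$edge.length[e], lambda, mu, Q, h)
    if (anyNA(Dn[pa, ])) {
      En[pa, ] <- y[seq_len(k)]
      Dn[pa, ] <- y[k + seq_len(k)]
    } else {
      Dn[pa, ] <- lambda * Dn[pa, ] * y[k + seq_len(k)]
    }
  }
  root <- ntip + 1L
  D <- Dn[root, ]
  if (condition) D <- D / (lambda * (1 - En[root, ])^2)
  log(sum(D * D / sum(D)))
}

# closed-form constant-rate birth-death log-likelihood (lambda != mu),
# conditioned on survival of both crown lineages, on an ultrametric tree.
# Uses E(t) = mu (e^{rt} - 1) / (lambda e^{rt} - mu) and the flow
# D(t2)/D(t1) = P(t2)/P(t1) with P(t) = e^{rt} / (lambda e^{rt} - mu)^2.
oracle_bd_loglik <- function(phy, lambda, mu, condition = TRUE) {
  stopifnot(abs(lambda - mu) > 1e-12)
  r <- lambda - mu
  Pf <- function(t) exp(r * t) / (lambda * exp(r * t) - mu)^2
  Ef <- function(t) mu * (exp(r * t) - 1) / (lambda * exp(r * t) - mu)
  dep <- ape::node.depth.edgelength(phy)
  H <- max(dep)
  age <- H - dep
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  logD <- c(rep(0, ntip), rep(NA_real_, phy$Nnode))
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2L]
    pa <- po$edge[e, 1L]
    contrib <- logD[ch] + log(Pf(age[pa]) / Pf(age[ch]))
    logD[pa] <- if (is.na(logD[pa])) contrib else
      logD[pa] + contrib + log(lambda)
  }
  ll <- logD[ntip + 1L]
  if (condition) ll <- ll - log(lambda * (1 - Ef(H))^2)
  ll
}

# Mk (neutral discrete character) log-likelihood by matrix-exponential
# pruning with FitzJohn root weighting.  Q has zero diagonal on input.
oracle_mk_loglik <- function(phy, states, Q) {
  k <- nrow(Q)
  G <- Q
  diag(G) <- -rowSums(Q)
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  st <- states[phy$tip.label]
  L <- matrix(NA_real_, ntip + phy$Nnode, k)
  logcomp <- 0
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2L]
    pa <- po$edge[e, 1L]
    v <- if (ch <= ntip) as.numeric(seq_len(k) - 1L == st[ch]) else L[ch, ]
    Pm <- as.matrix(Matrix::expm(G * po$edge.length[e]))
    w <- as.numeric(Pm %*% v)
    if (anyNA(L[pa, ])) L[pa, ] <- w else {
      L[pa, ] <- L[pa, ] * w
      m <- max(L[pa, ])
      L[pa, ] <- L[pa, ] / m
      logcomp <- logcomp + log(m)
    }
  }
  D <- L[ntip + 1L, ]
  log(sum(D * D / sum(D))) + logcomp
}

# random ultrametric tree of n tips scaled to a given height
oracle_random_tree <- function(n, height = 1) {
  phy <- ape::rcoal(n)
  phy$edge.length <- phy$edge.length / max(ape::node.depth.edgelength(phy)) *
    height
  phy$tip.label <- paste0("t", seq_len(n))
  phy
}
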