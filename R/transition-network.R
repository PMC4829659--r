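## Guild-level weighted directed transition network.  Nodes are guilds,
## directed link weights are posterior median transition rates.  A guild
## into which species from other guilds preferentially evolve behaves as an
## absorbing node and shows high eigenvector in-centrality; significance is
## judged against a null that reshuffles the observed weights over the link
## positions.

#' Construct a transition network
#'
#' @param w square non-negative weight matrix (`w[i, j]` = rate of
#'   transition from node `i` to node `j`); the diagonal is stored as zero.
#' @param labels node labels (defaults to the matrix dimnames).
#' @param display_cutoff weights below this are hidden by the DOT export
#'   only; every analysis uses the full matrix.
#' @return a `transition_network` object.
#' @export
transition_network <- function(w, labels = NULL, display_cutoff = 0.001) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative")
  diag(w) <- 0
  if (is.null(labels)) labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("node_", seq_len(nrow(w)) - 1L)
  dimnames(w) <- list(labels, labels)
  structure(list(w = w, labels = labels, display_cutoff = display_cutoff),
            class = "transition_network")
}

#' Build the transition network from a posterior trace
#'
#' Link weights are the posterior medians of the `q_i_j` columns.
#'
#' @param trace a `posterior_trace` containing all `q_i_j` columns.
#' @param labels optional guild labels in state order.
#' @param display_cutoff see [transition_network()].
#' @return a `transition_network`.
#' @export
build_network <- function(trace, labels = NULL, display_cutoff = 0.001) {
  k <- attr(trace, "k")
  if (is.null(k)) stop("trace lacks a k attribute")
  w <- matrix(0, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      if (i == j) next
      cn <- paste0("q_", i - 1L, "_", j - 1L)
      if (!cn %in% names(trace)) stop("missing transition column ", cn)
      w[i, j] <- stats::median(trace[[cn]])
    }
  if (is.null(labels)) labels <- paste0("state_", seq_len(k) - 1L)
  transition_network(w, labels, display_cutoff)
}

#' Eigenvector in-centrality of a transition network
#'
#' The leading non-negative eigenvector `x` with `x_j` proportional to
#' `sum_i w_ij x_i` ("how do the transition rates lead, directly or
#' indirectly, to node j"), computed by power iteration on the transposed
#' weight matrix from a uniform start and normalised so the maximum is
#' exactly 1.
#'
#' @param net a `transition_network` or a square weight matrix.
#' @param tol convergence tolerance (sup norm between iterates).
#' @param max_iter iteration cap; non-convergence is an error.
#' @return named numeric vector of centralities in `[0, 1]`, max 1.
#' @export
eigenvector_centrality <- function(net, tol = 1e-12, max_iter = 10000L) {
  w <- if (inherits(net, "transition_network")) net$w else {
    transition_network(net)$w
  }
  out <- power_centrality_cpp(w, tol, max_iter)
  names(out) <- rownames(w)
  out
}

# Perron vector by dense eigen-decomposition; used as a fallback for
# permutation replicas whose two leading eigenvalues are so close that power
# iteration stalls (the observed network always goes through the power
# iteration the centrality operation defines).
.centrality_eigen <- function(w) {
  ev <- eigen(t(w))
  v <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  v / max(v)
}

#' Permutation test for transition-network centrality
#'
#' Builds a null distribution by reassigning the observed multiset of
#' off-diagonal weights across the off-diagonal positions without
#' replacement (network topology fixed, values shuffled), recomputing all
#' centralities for each of `n_perm` replicas.  One-sided, add-one
#' corrected: `p_j = (1 + #replicas with null centrality_j >= observed_j)
#' / (1 + n_perm)`.
#'
#' Because reported centralities are normalised to a maximum of exactly 1,
#' the most central node's value carries no information about *how dominant*
#' it is; its null exceedance probability would degenerate to the chance of
#' being the argmax (about `1/n`) no matter how concentrated the observed
#' flows are.  The comparison therefore uses the sum-normalised leading
#' eigenvector (each node's centrality share), which preserves the ranking
#' while making dominance measurable; reported centralities keep the
#' max-1 scale.
#'
#' @param net a `transition_network`.
#' @param n_perm number of permutation replicas (the reference analysis used
#'   10,000).
#' @param seed optional RNG seed.
#' @param tol comparison tolerance when counting `null >= observed`.
#' @param max_iter power-iteration cap per replica; a replica whose leading
#'   eigenvalues are nearly tied falls back to a dense eigen-decomposition.
#' @return a `centrality_result` with observed centralities and per-node
#'   p-values.
#' @export
centrality_permutation_test <- function(net, n_perm = 10000L, seed = NULL,
                                        tol = 1e-9, max_iter = 20000L) {
  stopifnot(inherits(net, "transition_network"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  w <- net$w
  n <- nrow(w)
  off <- which(row(w) != col(w))
  vals <- w[off]
  obs <- eigenvector_centrality(net)
  obs_share <- obs / sum(obs)
  count_ge <- integer(n)
  wperm <- w
  for (r in seq_len(n_perm)) {
    wperm[off] <- vals[sample.int(length(vals))]
    cen <- tryCatch(power_centrality_cpp(wperm, 1e-12, max_iter),
                    error = function(e) .centrality_eigen(wperm))
    count_ge <- count_ge + as.integer(cen / sum(cen) >= obs_share - tol)
  }
  p <- (1 + count_ge) / (1 + n_perm)
  structure(list(centrality = obs,
                 p_value = stats::setNames(p, names(obs)),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat("Eigenvector centrality with permutation null (",
      x$n_perm, " replicas)\n", sep = "")
  for (i in seq_along(x$centrality))
    cat(sprintf("  %-14s centrality %.4f  p = %.4g\n",
                names(x$centrality)[i], x$centrality[i], x$p_value[i]))
  invisible(x)
}

#' Write a network as a dense CSV matrix with a label header
#' @param net a `transition_network`.
#' @param path output path.
#' @return `net`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  utils::write.csv(as.data.frame(net$w), path, row.names = TRUE)
  invisible(net)
}

#' DOT export for visualisation
#'
#' Links lighter than the display cutoff are omitted from the rendering (the
#' analysis always keeps them).
#'
#' @param net a `transition_network`.
#' @param path optional file; otherwise the DOT string is returned.
#' @return the DOT string, invisibly when written to file.
#' @export
network_dot <- function(net, path = NULL) {
  w <- net$w
  lines <- c("digraph transitions {")
  for (lab in net$labels) lines <- c(lines, sprintf("  \"%s\";", lab))
  for (i in seq_len(nrow(w)))
    for (j in seq_len(ncol(w)))
      if (i != j && w[i, j] >= net$display_cutoff)
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%.4g\"];",
                                  net$labels[i], net$labels[j], w[i, j]))
  lines <- c(lines, "}")
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
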