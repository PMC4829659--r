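## Phylogenetic signal of a binary trait: the D statistic of character
## dispersion.  The observed sum of sister-clade differences is scaled
## between two simulated references -- phylogenetically random states
## (tip shuffles; D = 1) and Brownian-threshold evolution (D = 0) -- so
## negative D indicates clustering and values above 1 overdispersion.

# Sum of sister-clade differences for each column of a tips x P matrix of
# trait values.  Nodal values are the means of the two children's values,
# computed post-order; d = sum over internal nodes of |v(left) - v(right)|.
.d_sums <- function(phy_post, vtips) {
  ntip <- length(phy_post$tip.label)
  nn <- ntip + phy_post$Nnode
  P <- ncol(vtips)
  V <- matrix(0, nn, P)
  V[seq_len(ntip), ] <- vtips
  first <- matrix(NA_real_, nn, P)
  dsum <- numeric(P)
  e1 <- phy_post$edge[, 1L]
  e2 <- phy_post$edge[, 2L]
  for (r in seq_along(e1)) {
    p <- e1[r]
    v <- V[e2[r], ]
    if (is.na(first[p, 1L])) {
      first[p, ] <- v
    } else {
      dsum <- dsum + abs(first[p, ] - v)
      V[p, ] <- (first[p, ] + v) / 2
    }
  }
  dsum
}

# Brownian motion tip values, P independent replicates, unit rate, root 0.
.bm_tips <- function(phy_cw, P) {
  ntip <- length(phy_cw$tip.label)
  nn <- ntip + phy_cw$Nnode
  X <- matrix(0, nn, P)
  e1 <- phy_cw$edge[, 1L]
  e2 <- phy_cw$edge[, 2L]
  len <- phy_cw$edge.length
  for (r in seq_along(e1))
    X[e2[r], ] <- X[e1[r], ] + stats::rnorm(P, sd = sqrt(max(len[r], 0)))
  X[seq_len(ntip), , drop = FALSE]
}

#' D statistic of phylogenetic signal for a binary trait
#'
#' Computes the observed sister-clade difference sum `d_obs`, its
#' expectation under `n_perm` random tip shuffles and under `n_sim`
#' Brownian-threshold simulations (unit-rate Brownian motion on the tree,
#' thresholded so the simulated prevalence matches the observed one), and
#' scales: `D = (d_obs - mean d_brownian) / (mean d_random - mean
#' d_brownian)`.  D near 1 indicates phylogenetically random states, near 0
#' Brownian-like clustering, negative values strong clustering.
#'
#' One-sided add-one-corrected p-values accompany the estimate: `p_random`
#' is the fraction of shuffles with `d <= d_obs` (small when the trait is
#' more clustered than random), `p_brownian` the fraction of Brownian
#' simulations with `d >= d_obs` (small when the trait is more overdispersed
#' than Brownian).
#'
#' @param phy a validated binary `phylo`.
#' @param trait named 0/1 vector over the tips (both states present).
#' @param n_perm number of tip shuffles.
#' @param n_sim number of Brownian-threshold simulations.
#' @param seed optional RNG seed.
#' @return a `d_stat_result`.
#' @export
d_statistic <- function(phy, trait, n_perm = 1000L, n_sim = 1000L,
                        seed = NULL) {
  validate_phylogeny(phy)
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(phy$tip.label, names(trait))
  if (length(miss)) stop("trait missing for tip(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  v <- as.numeric(trait[phy$tip.label])
  if (!all(v %in% c(0, 1))) stop("trait must be binary 0/1")
  m1 <- sum(v == 1)
  ntip <- length(v)
  if (m1 == 0L || m1 == ntip)
    stop("trait is constant; D is undefined")

  po <- ape::reorder.phylo(phy, "postorder")
  cw <- ape::reorder.phylo(phy, "cladewise")
  d_obs <- .d_sums(po, matrix(v, ncol = 1L))

  perm <- vapply(seq_len(n_perm), function(i) sample(v), numeric(ntip))
  d_rand <- .d_sums(po, perm)

  bm <- .bm_tips(cw, n_sim)
  thr <- apply(bm, 2L, function(x) rank(x, ties.method = "first") > ntip - m1)
  d_bm <- .d_sums(po, thr * 1)

  denom <- mean(d_rand) - mean(d_bm)
  if (denom <= 0)
    stop("degenerate references: mean shuffled d does not exceed mean ",
         "Brownian d on this tree")
  D <- (d_obs - mean(d_bm)) / denom
  p_random <- (1 + sum(d_rand <= d_obs)) / (1 + n_perm)
  p_brownian <- (1 + sum(d_bm >= d_obs)) / (1 + n_sim)
  structure(list(D = D, d_obs = d_obs,
                 mean_d_random = mean(d_rand), mean_d_brownian = mean(d_bm),
                 p_random = p_random, p_brownian = p_brownian,
                 n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
                 prevalence = m1 / ntip, seed = seed),
            class = "d_stat_result")
}

#' @export
print.d_stat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  (d_obs %.3f; random ref %.3f; Brownian ref %.3f)\n",
              x$D, x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("p (vs random) = %.4g   p (vs Brownian) = %.4g\n",
              x$p_random, x$p_brownian))
  invisible(x)
}

#' Per-guild D statistics averaged over a set of trees
#'
#' Encodes each guild one-vs-rest as a binary trait and computes D on every
#' tree; reports the per-tree values, the mean D, and majority significance
#' flags (`different_from_1`: trait more clustered than random;
#' `different_from_0`: trait departs from Brownian-threshold expectation).
#'
#' @param trees list of validated `phylo` objects.
#' @param assignment named species -> guild vector covering all tips.
#' @param guilds guilds to test (default: all present).
#' @param alpha significance level for the per-tree flags.
#' @param n_perm,n_sim,seed forwarded to [d_statistic()].
#' @return a data frame, one row per guild.
#' @export
d_statistic_guilds <- function(trees, assignment, guilds = NULL,
                               alpha = 0.05, n_perm = 1000L, n_sim = 1000L,
                               seed = NULL) {
  if (!length(trees)) stop("empty tree list")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(guilds)) guilds <- sort(unique(assignment))
  rows <- lapply(guilds, function(g) {
    bin <- stats::setNames(as.integer(assignment == g), names(assignment))
    res <- lapply(trees, function(phy)
      tryCatch(d_statistic(phy, bin, n_perm = n_perm, n_sim = n_sim),
               error = function(e) NULL)) # e.g. guild absent on this tree
    res <- Filter(Negate(is.null), res)
    if (!length(res))
      return(data.frame(guild = g, mean_D = NA_real_,
                        different_from_1 = NA, different_from_0 = NA,
                        n_trees = 0L))
    Ds <- vapply(res, `[[`, numeric(1L), "D")
    p1 <- vapply(res, `[[`, numeric(1L), "p_random")
    p0 <- vapply(res, `[[`, numeric(1L), "p_brownian")
    data.frame(guild = g, mean_D = mean(Ds),
               different_from_1 = mean(p1 < alpha) > 0.5,
               different_from_0 = mean(p0 < alpha) > 0.5,
               n_trees = length(res))
  })
  do.call(rbind, rows)
}
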