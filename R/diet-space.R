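## Multidimensional diet similarity: PCA of the 9-item diet-score vectors
## (covariance decomposition -- all items share the same 0..10 scale, so no
## standardisation), Euclidean distances in the first three components
## averaged within and between guilds, and per-item score-frequency
## histograms for a guild subset.

#' PCA of a diet-score table
#'
#' Columns are mean-centred; components come from the covariance
#' decomposition.  The sign of each component is fixed deterministically
#' (its largest-magnitude loading is made positive) so coordinates are
#' reproducible; distances are sign-invariant anyway.
#'
#' @param x a diet table accepted by [classify_table()] (data frame with a
#'   `species` column, or matrix with species rownames).
#' @return a `diet_space` object with `scores` (species x first 3 PCs),
#'   `loadings`, and `var_explained` (per component, summing to 1).
#' @export
diet_pca <- function(x) {
  m <- .diet_matrix(x)
  if (nrow(m) < 4L) stop("need at least 4 species")
  if (all(apply(m, 2L, stats::sd) == 0))
    stop("all score vectors identical: zero variance")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- min(3L, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
                 loadings = pc$rotation,
                 var_explained = ve),
            class = "diet_space")
}

#' Within- and between-guild mean Euclidean distances in diet space
#'
#' Distances are computed between every pair of species in the orthogonal
#' space of the first three principal components, then averaged within each
#' guild (over `n (n - 1) / 2` pairs) and between each pair of guilds (over
#' `n_a * n_b` pairs).  Standard errors are over pairs.
#'
#' @param coords species x coordinates matrix (e.g. `diet_pca(x)$scores`).
#' @param guilds named character vector species -> guild (e.g. the
#'   `assignment` of [classify_table()]).
#' @return a `diet_distance_summary` with symmetric matrices `mean` and `se`
#'   (within-guild entries on the diagonal; a within-guild entry for a guild
#'   with fewer than 2 members is `NA`).
#' @export
guild_distance_summary <- function(coords, guilds) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords))) stop("coords needs species rownames")
  miss <- setdiff(rownames(coords), names(guilds))
  if (length(miss)) stop("species without a guild: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  g <- guilds[rownames(coords)]
  gl <- sort(unique(g))
  d <- as.matrix(stats::dist(coords))
  n <- length(gl)
  mean_m <- matrix(NA_real_, n, n, dimnames = list(gl, gl))
  se_m <- mean_m
  for (a in seq_len(n))
    for (b in a:n) {
      ia <- which(g == gl[a])
      ib <- which(g == gl[b])
      if (a == b) {
        if (length(ia) < 2L) next
        vals <- d[ia, ia][upper.tri(diag(length(ia)))]
      } else {
        vals <- as.numeric(d[ia, ib, drop = FALSE])
      }
      mean_m[a, b] <- mean_m[b, a] <- mean(vals)
      se_m[a, b] <- se_m[b, a] <- stats::sd(vals) / sqrt(length(vals))
    }
  structure(list(mean = mean_m, se = se_m,
                 n_species = table(factor(g, levels = gl))),
            class = "diet_distance_summary")
}

#' @export
print.diet_distance_summary <- function(x, digits = 3L, ...) {
  cat("Mean pairwise diet-space distances (s.e.); diagonal = within guild\n")
  m <- x$mean
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- if (is.na(m[i, j])) "-" else
        sprintf("%.*f (%.*f)", digits, m[i, j], digits, x$se[i, j])
  print(out, quote = FALSE)
  invisible(x)
}

#' Per-item score-frequency histograms for a subset of species
#'
#' For each food item, counts species by score value within the subset
#' (typically the omnivores); each item's counts sum to the subset size.
#'
#' @param x a diet table accepted by [classify_table()].
#' @param species character vector of species to include, or a guild label
#'   combined with `assignment`.
#' @param assignment optional named guild vector, used when `species` is a
#'   guild label.
#' @return a named list, per item, of score-count tables.
#' @export
item_score_frequencies <- function(x, species, assignment = NULL) {
  m <- .diet_matrix(x)
  if (length(species) == 1L && !is.null(assignment) &&
      species %in% guild_labels())
    species <- names(assignment)[assignment == species]
  species <- intersect(species, rownames(m))
  if (!length(species)) stop("empty species subset")
  sub <- m[species, , drop = FALSE]
  out <- lapply(diet_items(), function(it) table(sub[, it]))
  names(out) <- diet_items()
  out
}

#' Write diet-space coordinates as CSV (`species,pc1,pc2,pc3`)
#' @param ds a `diet_space`.
#' @param path output path.
#' @return `ds`, invisibly.
#' @export
write_diet_coords <- function(ds, path) {
  df <- data.frame(species = rownames(ds$scores), ds$scores)
  names(df) <- c("species", paste0("pc", seq_len(ncol(ds$scores))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(ds)
}
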