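## Tree data model and I/O.  Trees are ape "phylo" objects throughout; this
## layer adds the validation contract every downstream computation relies on:
## rooted, strictly binary, branch lengths present and non-negative, tip
## labels unique and non-empty.

#' Validate a phylogeny for use in likelihood and simulation code
#'
#' Checks that `phy` is a rooted, strictly binary `phylo` object with a
#' branch length on every edge (all non-negative) and unique, non-empty tip
#' labels.  Polytomies are rejected rather than silently resolved because
#' resolution changes the likelihood; use [ape::multi2di()] explicitly if
#' zero-length resolution is intended.
#'
#' @param phy an object of class `phylo`.
#' @return `phy`, invisibly, after passing all checks.
#' @export
validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; durations are required")
  if (anyNA(phy$edge.length)) stop("missing branch length on some edge")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  deg <- tabulate(phy$edge[, 1L], nbins = ntip + phy$Nnode)
  poly <- which(deg > 2L)
  if (length(poly))
    stop("polytomy at internal node ", poly[1L], " (", deg[poly[1L]],
         " children); trees must be strictly binary")
  one <- which(deg == 1L)
  if (length(one))
    stop("internal node ", one[1L], " has a single child")
  labs <- trimws(phy$tip.label)
  if (any(!nzchar(labs))) stop("empty tip label")
  if (anyDuplicated(labs)) stop("duplicate tip label: ", labs[duplicated(labs)][1L])
  invisible(phy)
}

#' Read a phylogeny from a Newick string
#'
#' Parses a single Newick tree and validates it (binary, branch lengths on
#' every edge, unique tip labels).  Tip labels are trimmed of surrounding
#' whitespace; quoted labels follow the Newick convention.
#'
#' @param text a Newick string (must end with `;`).
#' @return a validated `phylo` object; child order is preserved as written.
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) stop("'text' must be a string")
  .newick_precheck(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("Newick parse error in: ", substr(text, 1, 60))
  if (inherits(phy, "multiPhylo")) stop("expected a single tree")
  phy$tip.label <- trimws(phy$tip.label)
  validate_phylogeny(phy)
  phy
}

# Cheap structural scan so parse failures can report a character position,
# which ape's parser does not.
.newick_precheck <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminating ';' at character ",
         nchar(text))
  invisible(TRUE)
}

#' Serialize a phylogeny to Newick
#'
#' Writes branch lengths at a fixed decimal precision, so a zero-length
#' branch serializes as `:0.0...`.  Labels containing Newick metacharacters
#' are single-quoted.
#'
#' @param phy a validated `phylo` object.
#' @param digits number of decimal places for branch lengths.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(phy, digits = 10L, file = NULL) {
  validate_phylogeny(phy)
  ntip <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  fmt_lab <- function(lab) {
    if (grepl("[ (),:;\\[\\]']", lab))
      paste0("'", gsub("'", "''", lab), "'") else lab
  }
  rec <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(fmt_lab(phy$tip.label[node]))
    parts <- vapply(rows, function(r) {
      paste0(rec(phy$edge[r, 2L]),
             ":", sprintf("%.*f", digits, phy$edge.length[r]))
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(rec(ntip + 1L), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read trees from a Nexus TREES block (read-only convenience)
#'
#' @param path path to a Nexus file.
#' @return a list of validated `phylo` objects.
#' @export
read_nexus_trees <- function(path) {
  trees <- ape::read.nexus(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(p) {
    p$tip.label <- trimws(p$tip.label)
    validate_phylogeny(p)
    p
  })
}

#' Prune a phylogeny to a set of tip labels
#'
#' Retains exactly the requested tips, suppressing the resulting degree-2
#' nodes with branch lengths summed, so patristic distances among retained
#' tips are preserved.
#'
#' @param phy a validated `phylo` object.
#' @param labels character vector of tip labels to keep (at least 2).
#' @return the pruned, validated `phylo`.
#' @export
prune_to_labels <- function(phy, labels) {
  validate_phylogeny(phy)
  labels <- unique(trimws(labels))
  if (length(labels) < 2L) stop("need at least 2 labels to keep")
  unknown <- setdiff(labels, phy$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  out <- ape::keep.tip(phy, labels)
  validate_phylogeny(out)
  out
}

#' Construct a tip-state map
#'
#' Associates each tip label with a state index in `0..k-1`; `NA` marks an
#' unknown state (every state is then allowed at that tip).
#'
#' @param labels character tip labels.
#' @param states integer states in `0..k-1` (or `NA`).
#' @param k number of states; inferred as `max(states) + 1` when missing.
#' @return a named integer vector with attribute `k`.
#' @export
tip_state_map <- function(labels, states, k = NULL) {
  labels <- trimws(labels)
  if (length(labels) != length(states)) stop("labels/states length mismatch")
  if (anyDuplicated(labels)) stop("duplicate tip labels in state map")
  states <- as.integer(states)
  if (is.null(k)) k <- max(states, na.rm = TRUE) + 1L
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  bad <- !is.na(states) & (states < 0L | states >= k)
  if (any(bad)) stop("state out of range 0..k-1 for: ",
                     paste(labels[bad], collapse = ", "))
  out <- stats::setNames(states, labels)
  attr(out, "k") <- k
  out
}

# states aligned to phy$tip.label order, erroring on unmapped tips
.states_for_tree <- function(phy, states) {
  miss <- setdiff(phy$tip.label, names(states))
  if (length(miss))
    stop("tip(s) missing from state map: ", paste(miss, collapse = ", "))
  out <- states[phy$tip.label]
  attr(out, "k") <- attr(states, "k")
  out
}

#' Patristic distance matrix between all tips
#'
#' @param phy a validated `phylo` object.
#' @return a symmetric matrix of path-length distances, tips in label order.
#' @export
patristic_distances <- function(phy) {
  validate_phylogeny(phy)
  stats::cophenetic(phy)
}

#' Attach or read an opaque per-tree tag (for example a backbone identity)
#'
#' @param phy a `phylo` object.
#' @param value tag to set; omit to read.
#' @return the tag, or the tagged tree when `value` is supplied.
#' @export
tree_tag <- function(phy, value) {
  if (missing(value)) return(attr(phy, "tree_tag"))
  attr(phy, "tree_tag") <- value
  phy
}
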