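## Dietary guild classification from 9-item diet-score vectors.  Scores sum
## to 10 per species and approximate the proportion of each food type in the
## diet; a species is a specialist of the single item whose score strictly
## exceeds the threshold, and an omnivore otherwise (which covers both the
## two-way tie and the no-dominant-item cases).

#' The nine food items, in canonical order
#' @return character vector of item names.
#' @export
diet_items <- function() {
  c("invertebrates", "fruits", "nectar", "seeds", "vertebrates",
    "fish", "carrion", "plants", "misc")
}

#' Map from food item to specialist guild
#'
#' `misc` has no specialist guild: a dominant miscellaneous score classifies
#' the species as an omnivore.
#' @return named character vector, item -> guild (`NA` for `misc`).
#' @export
item_guilds <- function() {
  c(invertebrates = "insectivore", fruits = "frugivore",
    nectar = "nectarivore", seeds = "granivore", vertebrates = "carnivore",
    fish = "piscivore", carrion = "scavenger", plants = "herbivore",
    misc = NA_character_)
}

#' All guild labels
#' @return character vector of the nine guilds.
#' @export
guild_labels <- function() {
  c("carnivore", "frugivore", "granivore", "herbivore", "insectivore",
    "nectarivore", "piscivore", "scavenger", "omnivore")
}

#' Classifier configuration
#'
#' @param threshold specialist threshold `t`: a species is a specialist only
#'   when exactly one item's score is strictly greater than `t`.  The default
#'   5 is the half-diet rule; raising it gives the more inclusive omnivory
#'   used for sensitivity analysis.
#' @param tol tolerance on the sum-to-10 constraint (scores may be reals).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(threshold = 5, tol = 1e-9) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 10)
    stop("threshold must lie strictly between 0 and 10")
  structure(list(threshold = threshold, tol = tol),
            class = "classifier_config")
}

.check_scores <- function(scores, tol) {
  items <- diet_items()
  if (length(scores) != 9L) stop("diet-score vector must have 9 items")
  if (!is.null(names(scores))) {
    if (!setequal(names(scores), items))
      stop("unexpected item names: ",
           paste(setdiff(names(scores), items), collapse = ", "))
    scores <- scores[items]
  } else names(scores) <- items
  if (any(scores < 0)) stop("negative diet score")
  if (abs(sum(scores) - 10) > tol)
    stop("diet scores must sum to 10 (got ", format(sum(scores)), ")")
  scores
}

#' Classify one species from its diet-score vector
#'
#' If exactly one item has a score strictly greater than the threshold the
#' species belongs to that item's guild; in every other case (ties, no
#' dominant item, or a dominant `misc` score) it is an omnivore.
#'
#' @param scores numeric vector of 9 non-negative scores summing to 10, in
#'   [diet_items()] order (or named by item).
#' @param config a [classifier_config()].
#' @return a single guild label.
#' @export
classify_species <- function(scores, config = classifier_config()) {
  scores <- .check_scores(scores, config$tol)
  over <- which(scores > config$threshold)
  if (length(over) == 1L) {
    g <- item_guilds()[[names(scores)[over]]]
    if (!is.na(g)) return(g)
  }
  "omnivore"
}

#' Classify a table of species and summarise guild composition
#'
#' @param x a data frame with a `species` column plus the 9 item columns, or
#'   a numeric matrix with species as rownames and items as columns.
#' @param config a [classifier_config()].
#' @return a `guild_assignment` list with elements `assignment` (named
#'   character vector species -> guild), `counts` and `proportions` (over all
#'   nine guilds; counts sum to the number of species, proportions to 1).
#' @export
classify_table <- function(x, config = classifier_config()) {
  m <- .diet_matrix(x)
  if (nrow(m) < 1L) stop("empty diet table")
  guilds <- vapply(seq_len(nrow(m)), function(i)
    classify_species(m[i, ], config), character(1L))
  names(guilds) <- rownames(m)
  counts <- table(factor(guilds, levels = guild_labels()))
  structure(list(assignment = guilds,
                 counts = as.integer(counts),
                 proportions = as.numeric(counts) / length(guilds),
                 guilds = guild_labels(),
                 threshold = config$threshold),
            class = "guild_assignment")
}

#' @export
print.guild_assignment <- function(x, ...) {
  cat("Guild assignment for", length(x$assignment), "species (threshold >",
      x$threshold, ")\n")
  df <- data.frame(guild = x$guilds, n = x$counts,
                   pct = sprintf("%.1f%%", 100 * x$proportions))
  print(df[df$n > 0L, ], row.names = FALSE)
  invisible(x)
}

# accepts data frame (species column) or matrix (rownames)
.diet_matrix <- function(x) {
  items <- diet_items()
  if (is.data.frame(x)) {
    if (!"species" %in% names(x)) stop("data frame needs a 'species' column")
    if (anyDuplicated(x$species))
      stop("duplicate species label: ", x$species[duplicated(x$species)][1L])
    miss <- setdiff(items, names(x))
    if (length(miss)) stop("missing item column(s): ",
                           paste(miss, collapse = ", "))
    m <- as.matrix(x[, items, drop = FALSE])
    rownames(m) <- as.character(x$species)
  } else if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("matrix input needs species rownames")
    if (anyDuplicated(rownames(x))) stop("duplicate species label")
    if (is.null(colnames(x))) colnames(x) <- items
    m <- x[, items, drop = FALSE]
  } else stop("unsupported diet table input")
  storage.mode(m) <- "double"
  m
}

#' Read a diet-score table from CSV
#'
#' Expects the header
#' `species,invertebrates,fruits,nectar,seeds,vertebrates,fish,carrion,plants,misc`.
#'
#' @param path CSV path.
#' @return a data frame in the layout [classify_table()] accepts.
#' @export
read_diet_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  miss <- setdiff(c("species", diet_items()), names(df))
  if (length(miss)) stop("diet CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write guild assignments and a JSON composition summary
#'
#' @param ga a `guild_assignment`.
#' @param csv_path path for the `species,guild` CSV.
#' @param json_path optional path for the counts/proportions JSON summary.
#' @return `ga`, invisibly.
#' @export
write_guild_assignment <- function(ga, csv_path, json_path = NULL) {
  utils::write.csv(data.frame(species = names(ga$assignment),
                              guild = unname(ga$assignment)),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_species = length(ga$assignment),
           threshold = ga$threshold,
           counts = stats::setNames(as.list(ga$counts), ga$guilds),
           proportions = stats::setNames(as.list(ga$proportions), ga$guilds)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(ga)
}
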