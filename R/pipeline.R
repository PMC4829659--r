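## Orchestration of the full analysis: classify diets, fit MuSSE per tree,
## combine posteriors, then the downstream analyses (rate comparisons,
## transition network, diet space, phylogenetic signal, adequacy).  Every
## run writes a manifest (configuration echo, package version, seed, input
## checksums) so results are reproducible artifacts.  The function surface
## is the interface; `inst/cli/guilddiv.R` is a thin script over it.

#' Load a run configuration from JSON (or normalise a list)
#'
#' Recognised fields: `trees` (Newick path, one tree per line), `diet`
#' (diet-score CSV path), `out_dir`, `threshold`, `seed`, `n_trees`
#' (subsample of the tree set), `mcmc` (list: steps, thin, burnin),
#' `focal_guild`, `exclude_guilds` (e.g. drop a tiny scavenger-like guild),
#' `analyses` (character subset of `"network"`, `"dietspace"`, `"signal"`,
#' `"adequacy"`).
#'
#' @param x a JSON path or a list.
#' @return a `run_config` list with defaults filled in.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
  else x
  defaults <- list(threshold = 5, seed = 1L, n_trees = NULL,
                   mcmc = list(steps = 1500000L, thin = 1000L, burnin = 0.1),
                   focal_guild = "omnivore", exclude_guilds = character(0),
                   analyses = c("network", "dietspace", "signal"))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  structure(cfg, class = "run_config")
}

.manifest <- function(cfg, inputs = character(0)) {
  list(package = "guilddiv",
       version = as.character(utils::packageVersion("guilddiv")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       seed = cfg$seed,
       config = unclass(cfg),
       input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])))
}

#' Run the full pipeline on trees plus a diet table
#'
#' Stages: guild classification; per-tree MuSSE MCMC; posterior combination;
#' rate differences against the focal guild; then any requested analyses.
#' All outputs land in `cfg$out_dir`; a `manifest.json` records the
#' configuration, seed and input checksums.  Inputs are never mutated.
#'
#' @param cfg a [run_config()] (or JSON path / list coercible to one).
#' @param trees optional list of `phylo` objects (otherwise read from
#'   `cfg$trees`).
#' @param diet optional diet data frame (otherwise read from `cfg$diet`).
#' @return invisibly, a list of the in-memory results.
#' @export
pipeline_run <- function(cfg, trees = NULL, diet = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  inputs <- c(if (is.character(cfg$trees)) cfg$trees,
              if (is.character(cfg$diet)) cfg$diet)
  if (is.null(trees)) {
    lines <- readLines(cfg$trees)
    lines <- lines[nzchar(trimws(lines))]
    trees <- lapply(lines, read_newick)
  }
  if (is.null(diet)) diet <- read_diet_csv(cfg$diet)
  if (!is.null(cfg$n_trees) && cfg$n_trees < length(trees))
    trees <- trees[seq_len(cfg$n_trees)]

  # 1. classification
  ga <- classify_table(diet, classifier_config(cfg$threshold))
  write_guild_assignment(ga, file.path(cfg$out_dir, "guilds.csv"),
                         file.path(cfg$out_dir, "guild_summary.json"))

  keep_guilds <- setdiff(ga$guilds[ga$counts > 0L], cfg$exclude_guilds)
  state_of_guild <- stats::setNames(seq_along(keep_guilds) - 1L, keep_guilds)
  k <- length(keep_guilds)
  if (k < 2L) stop("need at least 2 non-empty guilds after exclusions")

  # 2. per-tree fits on tips with retained guilds
  traces <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    phy <- trees[[i]]
    keep <- intersect(phy$tip.label,
                      names(ga$assignment)[ga$assignment %in% keep_guilds])
    miss <- setdiff(phy$tip.label, names(ga$assignment))
    if (length(miss))
      stop("tree ", i, " has tips absent from the diet table: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    if (length(keep) < length(phy$tip.label))
      phy <- prune_to_labels(phy, keep)
    states <- tip_state_map(phy$tip.label,
                            state_of_guild[ga$assignment[phy$tip.label]],
                            k = k)
    mc <- mcmc_config(steps = cfg$mcmc$steps, thin = cfg$mcmc$thin,
                      burnin = cfg$mcmc$burnin,
                      seed = cfg$seed + i)
    traces[[i]] <- run_mcmc(phy, states, cfg = mc,
                            tree_tag = paste0("tree_", i))
    write_trace(traces[[i]],
                file.path(cfg$out_dir, sprintf("trace_tree_%03d.csv", i)))
  }
  combined <- combine_traces(traces)
  write_trace(combined, file.path(cfg$out_dir, "trace_combined.csv"))

  results <- list(assignment = ga, trace = combined, guild_states = state_of_guild)

  # 3. rate comparison against the focal guild
  if (cfg$focal_guild %in% keep_guilds) {
    rc <- rate_differences(combined, state_of_guild[[cfg$focal_guild]])
    write_rate_comparison_json(rc,
                               file.path(cfg$out_dir, "rate_differences.json"))
    results$rate_comparison <- rc
  }

  # 4. optional analyses
  if ("network" %in% cfg$analyses) {
    net <- build_network(combined, labels = keep_guilds)
    write_network_csv(net, file.path(cfg$out_dir, "transition_network.csv"))
    ct <- centrality_permutation_test(net,
                                      n_perm = cfg$n_perm %||% 10000L,
                                      seed = cfg$seed)
    jsonlite::write_json(list(centrality = as.list(ct$centrality),
                              p_value = as.list(ct$p_value),
                              n_perm = ct$n_perm),
                         file.path(cfg$out_dir, "centrality.json"),
                         auto_unbox = TRUE, digits = NA)
    results$network <- net
    results$centrality <- ct
  }
  if ("dietspace" %in% cfg$analyses) {
    ds <- diet_pca(diet)
    write_diet_coords(ds, file.path(cfg$out_dir, "diet_coords.csv"))
    common <- intersect(rownames(ds$scores), names(ga$assignment))
    gd <- guild_distance_summary(ds$scores[common, , drop = FALSE],
                                 ga$assignment)
    utils::write.csv(gd$mean, file.path(cfg$out_dir, "guild_distances.csv"))
    results$diet_space <- ds
    results$guild_distances <- gd
  }
  if ("signal" %in% cfg$analyses) {
    sig <- d_statistic_guilds(trees, ga$assignment, guilds = keep_guilds,
                              n_perm = cfg$n_perm_signal %||% 1000L,
                              n_sim = cfg$n_perm_signal %||% 1000L)
    utils::write.csv(sig, file.path(cfg$out_dir, "phylo_signal.csv"),
                     row.names = FALSE)
    results$signal <- sig
  }
  if ("adequacy" %in% cfg$analyses) {
    med <- apply(combined[, musse_param_names(k, FALSE)], 2L, stats::median)
    pars_hat <- unflatten_parameters(med, k)
    emp <- tabulate(state_of_guild[ga$assignment[ga$assignment %in%
                                                   keep_guilds]] + 1L,
                    nbins = k)
    ad <- adequacy_test(pars_hat, n_trees = cfg$n_adequacy %||% 1000L,
                        stop_taxa = length(trees[[1L]]$tip.label),
                        empirical_props = emp / sum(emp), seed = cfg$seed)
    write_adequacy_json(ad, file.path(cfg$out_dir, "adequacy.json"))
    results$adequacy <- ad
  }

  jsonlite::write_json(.manifest(cfg, inputs),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic study and write its artifacts
#'
#' Emits the same formats the pipeline consumes: one Newick per tree,
#' `species,state` CSVs, the diet-score CSV and `truth.json`.
#'
#' @param cfg a [study_config()] (default: the sink scenario).
#' @param out_dir output directory.
#' @return the `guild_study`, invisibly.
#' @export
pipeline_synth <- function(cfg = sink_scenario_default(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(cfg)
  writeLines(vapply(study$trees, function(tr) write_newick(tr$phy),
                    character(1L)),
             file.path(out_dir, "trees.nwk"))
  st <- do.call(rbind, lapply(study$trees, function(tr)
    data.frame(species = names(tr$states), state = as.integer(tr$states))))
  utils::write.csv(st, file.path(out_dir, "states.csv"), row.names = FALSE)
  utils::write.csv(study$diet, file.path(out_dir, "diet.csv"),
                   row.names = FALSE)
  write_truth_json(study, file.path(out_dir, "truth.json"))
  invisible(study)
}

#' Minimal command-line dispatcher
#'
#' `guilddiv_cli(c("synth", "--out", dir))` or
#' `guilddiv_cli(c("run", "--config", cfg.json))`; used by the
#' `inst/cli/guilddiv.R` script.
#'
#' @param args character vector of command-line arguments.
#' @return 0 on success (invisibly); errors propagate.
#' @export
guilddiv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: guilddiv <synth|run> [options]")
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  if (cmd == "synth") {
    out <- opt("--out")
    if (is.null(out)) stop("synth needs --out <dir>")
    seed <- as.integer(opt("--seed", "1"))
    n_trees <- as.integer(opt("--trees", "5"))
    n_tips <- as.integer(opt("--tips", "300"))
    pipeline_synth(sink_scenario_default(n_trees = n_trees, n_tips = n_tips,
                                         master_seed = seed), out)
  } else if (cmd == "run") {
    cfgp <- opt("--config")
    if (is.null(cfgp)) stop("run needs --config <json>")
    pipeline_run(run_config(cfgp))
  } else stop("unknown subcommand: ", cmd)
  invisible(0L)
}
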