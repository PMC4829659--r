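# Simulate a MuSSE tree, retrying with derived seeds when the process goes
# extinct before reaching the stop rule.
sim_with_retry <- function(pars, stop_taxa, seed, root_state = 0L,
                           max_retry = 50L) {
  for (a in seq_len(max_retry)) {
    out <- tryCatch(
      simulate_musse_tree(simulation_config(pars, stop_taxa = stop_taxa,
                                            root_state = root_state,
                                            seed = seed + (a - 1L) * 1009L)),
      error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("simulation went extinct in every retry")
}
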