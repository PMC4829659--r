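# guilddiv

Trait-dependent diversification dynamics of dietary guilds.

## The problem

Does diet shape macroevolution?  Some character states may act as
**macroevolutionary sinks**: lineages in them speciate slowly and go
extinct quickly, yet the state persists because other lineages keep
evolving into it.  Detecting such a regime requires estimating
state-dependent speciation, extinction and transition rates jointly on a
phylogeny, then asking targeted questions of the posterior: do the focal
state's rates differ from every other guild's?  Do transitions
preferentially lead into it?  Is its central position in the transition
network more than chance?

guilddiv implements that entire workflow for discrete dietary guilds —
classification of species from diet-score vectors through Bayesian
multi-state speciation/extinction (MuSSE) inference to network, ordination,
signal and adequacy analyses — for phylogeneticists and macroevolution
researchers.  Everything runs end to end on synthetic data with known
ground truth, so the machinery is verifiable without any external data.

## The model

Each state *i* has speciation rate λ_i, extinction rate μ_i and transition
rates q_ij.  Along each branch the extinction probability E_i(t) and data
density D_i(t) obey the standard state-dependent birth–death equations

    dE_i/dt = μ_i − (λ_i + μ_i + Σ_j q_ij) E_i + λ_i E_i² + Σ_j q_ij E_j
    dD_i/dt = −(λ_i + μ_i + Σ_j q_ij) D_i + 2 λ_i E_i D_i + Σ_j q_ij D_j

integrated tip-to-root with an adaptive Cash–Karp Runge–Kutta scheme in
C++, joined at nodes by the pruning rule D_i ← λ_i D_i^L D_i^R.  Inference
is Bayesian: each rate family carries a half-Cauchy(0, s) prior whose scale
s is itself estimated (three hyper-scales), sampled by univariate slice
sampling; posteriors from independently fitted trees are combined.  Net
diversification r_i = λ_i − μ_i is computed per posterior sample, rate
differences are judged by 95/90/80% HPD intervals, and the guild-level
transition network is tested with an eigenvector-centrality permutation
null.  Details and design rationale are in the methods vignette
(`vignettes/guilddiv-methods.Rmd`).

## Worked example

Generate a synthetic study under the packaged "macroevolutionary sink"
regime (two specialist guilds plus an omnivore sink with λ = 0.07,
μ = 0.12, dominant transition rates into it), classify the diet table, fit
one tree, and test the transition network built from the true rates:

```r
library(guilddiv)

cfg   <- sink_scenario_default(n_trees = 1, n_tips = 300, master_seed = 101)
study <- generate_study(cfg)

classify_table(study$diet)
#> Guild assignment for 300 species (threshold > 5 )
#>        guild   n   pct
#>    frugivore  33 11.0%
#>  insectivore 204 68.0%
#>     omnivore  63 21.0%

tr <- run_mcmc(study$trees[[1]]$phy, study$trees[[1]]$states,
               mcmc_config(steps = 1500, thin = 2, burnin = 0.2, seed = 1),
               likelihood_options(rtol = 1e-4, atol = 1e-7), k = 3)
tr <- combine_traces(list(tr), burnin = 0.2)
round(apply(tr[, c("lambda_2", "mu_2")], 2, median), 3)
#> lambda_2     mu_2
#>    0.080    0.057
round(apply(net_diversification(tr), 2, median), 3)
#>   r_0   r_1   r_2
#> 0.133 0.165 0.021
# the sink's speciation rate is recovered low (truth 0.07; the specialists'
# is 0.20) and its net diversification r_2 is by far the lowest of the
# three guilds; extinction (truth 0.12) is weakly identified on one tree,
# which is why the full analysis pools posteriors across a tree set

pt <- centrality_permutation_test(
  transition_network(cfg$pars$Q, cfg$guilds), n_perm = 10000, seed = 2)
pt
#> Eigenvector centrality with permutation null (10000 replicas)
#>   frugivore      centrality 0.2467  p = 0.764
#>   insectivore    centrality 0.2352  p = 0.7885
#>   omnivore       centrality 1.0000  p = 0.005799
```

The omnivore guild is the unique maximally central node — transitions lead
into it far more than a random reassignment of the same rates would
produce — while it diversifies the slowest: the signature of a
macroevolutionary sink.

A tiny command-line wrapper ships in `inst/cli/guilddiv.R`
(`Rscript guilddiv.R synth --out dir` / `run --config cfg.json`); the R
functions are the primary interface.

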