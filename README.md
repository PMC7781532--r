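# hillnet

Context-specific logic-based ODE models of intracellular signaling networks.

Large-scale signaling networks — such as the cardiac hypertrophy network
linking receptor agonists (isoproterenol, phenylephrine, angiotensin II,
mechanical stretch) to transcriptional outputs — are usually available as
signed interaction graphs, while the experimental evidence that constrains
them is mostly qualitative ("inhibiting X under agonist A decreases Y").
`hillnet` is for modelers who want to turn such a graph plus a curated
perturbation compendium into a context-specific dynamic model and find out
which reactions, and which missing interactions, the data actually demand.

## The model

Each node activity `y_i ∈ [0, Ymax_i]` follows a logic-based differential
equation

```
dy_i/dt = (Ymax_i · F_i(y) − y_i) / τ_i
```

where `F_i` OR-combines (noisy-OR) the reactions targeting node i. Reactions
AND-combine their reactant terms, built from the normalized Hill function
`f(x) = B xⁿ / (Kⁿ + xⁿ)` with `B = (EC50ⁿ − 1)/(2 EC50ⁿ − 1)`,
`K = (B − 1)^(1/n)`, so that `f(0) = 0`, `f(1) = 1`, `f(EC50) = ½`. Two
modifications matter for model revision: inhibiting reactants contribute
`1 − W_R·f(x)` (so deleting an inhibition restores the un-inhibited
baseline), and AND gates are normalized by the mean of their inputs to the
power m−1 (so `AND(x, …, x) = x` at any arity).

On top of the engine, the package implements the four-stage revision loop:

1. **Estimate** the four shared defaults (n, W_R, W_i, W_e) from all-context
   qualitative data by multi-start derivative-free search.
2. **Validate** with per-class / per-context breakdowns (validation percent
   at a 1% in-silico direction threshold; six-category fold-change scoring
   for semi-quantitative data).
3. **Rank reactions**: single-reaction deletion scan, Morris
   elementary-effects screening over per-reaction EC50, Sobol
   variance decomposition (Jansen estimators, bootstrap CIs, pair-synergy
   scores), then EC50 calibration of the top subset.
4. **Infer crosstalks** by exhaustive single-edge addition (all N² OR edges,
   all N·R AND reactant insertions), ranked by the change in validation
   percent.

## Worked example

```r
library(hillnet)

# a small demonstration network: two receptor inputs, an AND gate, an inhibition
m <- make_toy_network(toy_spec("crosstalk_demo"))
m
#> <network_model> 8 nodes, 10 reactions (2 inputs, 8 intermediate)

# synthetic records simulated under known "true" parameters
truth <- param_set(n = 2, W_R = 0.85, W_i = 0.15, W_e = 0.85)
rec <- make_records(record_gen_spec(m, truth, contexts = "IN2",
                                    n_per_class = 4, seed = 13))

# the shipped defaults (resting inputs fully off) misread half the data …
validate_model(m, param_set(), rec)
#> <validation_report> 50.0% (8/16 records)
#> by class:
#>                       group n matches percent
#>           InputIntermediate 4       1      25
#>                 InputOutput 4       0       0
#>      IntermediateInhibition 4       4     100
#>  IntermediateOverexpression 4       3      75

# … and stage-1 estimation recovers full agreement
est <- estimate_defaults(m, rec, n_starts = 4, n_refine = 2, seed = 2,
                         refine_control = list(min_step_frac = 1/32))
est$best_objective
#> [1] 100

# withhold a true edge, screen all OR candidates: the edge is recovered first
rc <- make_recovery_case(gate = "OR")
scr <- screen_crosstalks(rc$model, param_set(), rc$records,
                         enumerate_or_candidates(rc$model))
head(scr$candidates[, c("source", "target", "delta", "corrected", "broken")], 3)
#>   source target    delta corrected broken
#> 1      A      C 2.777778         2      0
#> 2    IN1      C 1.388889         1      0
#> 3      A      A 0.000000         0      0
```

The validation percent is the share of records whose observed direction the
simulated steady states reproduce; `delta` is the percent-point change a
candidate edge brings, with the counts of records it corrects and breaks.

Networks and data live in plain CSV/TSV tables (Netflux-style `species` +
`reactions` sheets; one experiment record per row) — see `read_network()`
and `read_experiments()`. `run_pipeline()` chains all stages from a YAML or
list config and writes a JSON manifest with config snapshot, input hashes
and per-stage seeds; `inst/cli/hillnet` is a thin command-line wrapper
around it.

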