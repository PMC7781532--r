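---
title: "Logic-based ODE modeling and revision of signaling networks with hillnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-based ODE modeling and revision of signaling networks with hillnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillnet)
```

## The model

hillnet represents an intracellular signaling network as a system of
logic-based differential equations (LDEs). Each species (node) $i$ carries a
normalized activity $y_i \in [0, Y_{max,i}]$ evolving as

$$\frac{dy_i}{dt} = \frac{Y_{max,i}\, F_i(\mathbf y) - y_i}{\tau_i},$$

where $F_i$ combines the production terms of every reaction targeting node
$i$ through a noisy-OR gate, $F_i = 1 - \prod_r (1 - t_r)$. A signaling
reaction with several reactants combines them through an AND gate; a
receptor input reaction contributes its input weight directly ($W_i$ at
rest, $W_e$ when that input is stimulated by an agonist).

Reactant terms are built from the normalized Hill function

$$f_{act}(x) = \frac{B\,x^n}{K^n + x^n}, \qquad
  B = \frac{EC_{50}^n - 1}{2\,EC_{50}^n - 1}, \qquad
  K = (B - 1)^{1/n},$$

a sigmoid rescaled so that $f(0)=0$, $f(1)=1$ and $f(EC_{50})=0.5$. The
constants are undefined when $EC_{50}^n = 0.5$ (with the default $n$ this is
$EC_{50} \approx 0.609$); the package rejects such parameters explicitly and
the sensitivity-analysis bounds default to $[0.2, 0.6]$ to stay clear of the
singularity.

Two deliberate departures from the classical normalized-Hill formulation are
built in:

* **Inhibition.** An inhibiting reactant contributes $1 - W_R f_{act}(x)$
  rather than a weight-independent complement. This is the minimal form with
  two properties the classical version lacks: lowering the weight of an
  inhibition reaction *raises* downstream activity, and $W_R = 0$ removes
  the inhibition entirely, so a deleted inhibitory reaction returns its
  target to the correct un-inhibited baseline. Deleting a reaction
  (physically removing the table row) and silencing it ($W_R = 0$) are
  therefore exactly equivalent — a property the test suite checks at steady
  state.
* **AND gates.** The product of $m$ terms shrinks with $m$, so the gate
  output is divided by the mean term to the power $m-1$:
  $\prod_j t_j / \bar t^{\,m-1}$. This keeps output and inputs on the same
  order of magnitude (`AND(x, ..., x) = x` for any arity) and restores
  sensitivity of many-input gates to single-reactant perturbations.

The weight $W_R$ is folded into each reactant term (activator
$W_R f_{act}$, inhibitor $1 - W_R f_{act}$) rather than multiplying the
whole AND product. This single placement reproduces both required behaviors
at once: a zero weight silences an activating reaction and simultaneously
lifts a purely inhibitory one. Mixed-sign AND reactions are rare in curated
networks, but the choice matters there and is fixed project-wide.

## Parameters and perturbations

Eight defaults govern the system: the reaction-level $EC_{50}$, $n$, $W_R$;
the input weights $W_i$ (resting baseline of all receptor inputs) and $W_e$
(stimulated input); and the node-level $Y_{max}$, $Y_0$, $\tau$. Shipped
defaults ($W_R = 1$, $n = 1.4$, $EC_{50} = 0.5$, $W_i = 0$, $W_e = 1$,
$Y_{max} = 1$, $Y_0 = 0$, $\tau = 1$, dimensionless activities, arbitrary
time units) are the published defaults of the β-adrenergic normalized-Hill
model family this formulation descends from. Every default can be overridden
globally or per element (`set_override()`).

Wet-lab perturbations map onto the parameters: a stimulus raises one input's
weight from $W_i$ to $W_e$; knockdown sets the node's $Y_{max}$ to 0;
reaction deletion sets $W_R = 0$. Overexpression pins the node at $Y_{max}$.
The package implements the pin as an exact clamp ($dy/dt = 0$ at
$y = Y_{max}$) rather than the literal $Y_0 = Y_{max}$, $\tau = 10^9$
convention; the two are contractually equivalent over any finite horizon,
and the clamp avoids injecting an artificial stiffness scale into the
solver. The literal convention remains available via
`hillnet_config(overexpression = "literal")`.

## Simulation and numerical choices

Steady states are computed with `deSolve::lsodar`, an adaptive
stiff-capable integrator with root finding: integration stops at the root of
$\max_i |dy_i/dt| / \max(Y_{max,i}, 10^{-6}) - \text{tol}_{ss}$ with
$\text{tol}_{ss} = 10^{-6}$ by default, or at $t_{max} = 40\,\max_i \tau_i$
with an explicit non-converged flag (such records are excluded from
validation percentages and counted, never silently scored). Solver
tolerances default to `rtol = 1e-8`, `atol = 1e-10`. Activities are clamped
to $[0, 1]$ before entering the transfer functions so solver overshoot
cannot propagate out-of-range arguments. On acyclic networks the ODE steady
state coincides with topological-order evaluation of
$y_i = Y_{max,i} F_i(y)$; the tests verify this against an independent
oracle, and against damped fixed-point iteration and root finding on cyclic
toys.

## Validation against qualitative and semi-quantitative data

Each experiment record names a context (the stimulating agonist), a data
class, perturbations, a measured node and an observation. The data class
fixes the control/treatment pair: Input–Output and Input–Intermediate
records compare the stimulated steady state to the resting state;
Intermediate–Inhibition records compare stimulus + knockdown to stimulus
alone; Intermediate–Overexpression records compare the overexpression
(plus any stated stimulus) to rest.

The predicted direction uses the percent change from control with a 1%
in-silico threshold. The threshold is interpreted as *relative* change;
because many baselines are numerically zero, controls below
$10^{-4}\,Y_{max}$ fall back to the absolute change expressed in percent of
$Y_{max}$. The low threshold compensates for the reduced sensitivity of a
network simulated with shared default parameters; raising it only converts
calls into "no change", a monotone property the tests exercise. No-change
observations are scored like any other.

Semi-quantitative observations are fold-change categories: LH (1.01–2×),
MH (2–5×), HH (> 5×) for increases and LL (0.5–0.99×), ML (0.2–0.5×),
HL (< 0.2×) for decreases; simulated folds in (0.99, 1.01] map to a
seventh NC code. Simulated folds carry an additive guard
($\varepsilon_f = 10^{-3}$) on numerator and denominator so near-zero
activities cannot produce unbounded ratios. Matching is strict category
identity by default; a lenient mode (same direction within one level)
exists because the category-matching rule is a modeling choice, and the
report records which mode produced it.

## Parameter estimation

The validation percent is a step function of the parameters — finitely many
records each contribute a 0/1 match — so gradient-based local solvers have
nothing to work with. Stage-1 estimation of $(n, W_R, W_i, W_e)$ therefore
uses a scatter of random starts (default 100, drawn from nested per-start
seeds so enlarging the start set never loses earlier starts) followed by a
deterministic shrinking coordinate search on the top-ranked starts. The
incumbent parameter set is always evaluated and refined alongside the
scatter, so estimation never returns an objective below its starting
point. Default
bounds are $n \in [1, 10]$, $W_R \in [0, 1]$, $W_i \in [0, 0.5]$,
$W_e \in [0.5, 1]$; they respect the parameter invariants, exclude the
transfer-function singularity, and are configurable. Ties between equal
optima are broken toward the smallest bound-normalized distance from the
original defaults — the minimal-revision principle, and it makes the result
deterministic. Stage-3 calibration reuses the same machinery over the
$EC_{50}$ of a selected reaction subset, maximizing the combined objective
$100\,(m_{qual} + m_{semi})/(N_{qual} + N_{semi})$ with equal weight per
record.

## Sensitivity analysis

Three layers identify the reactions a context's agreement depends on:

1. **Single-reaction deletion** re-validates after silencing each
   intermediate reaction ($W_R = 0$) and categorizes reactions as
   non-sensitive, direct (one context affected) or shared (several).
2. **Morris elementary-effects screening** varies each reaction's
   $EC_{50}$ (the most influential reaction parameter once $W_R$ has been
   estimated) on an 8-level grid with step $\Delta = p/(2(p-1))$. The
   published sampling-for-uniformity strategy's selection criterion is not
   fully specified, so the package generates an oversample of random
   trajectories (default 300) and keeps the requested number (default 16)
   by greedy max–min spread maximization — a documented stand-in behind a
   strategy switch. Cost is exactly `trajectories * (k + 1)` objective
   evaluations. A factor is flagged monotonic when
   $|\mu|/\mu^* \ge 0.99$ — the dichotomy is visual in practice and needs a
   numeric rule; 0.99 tolerates only rounding-level sign disagreement.
3. **Sobol variance decomposition** on the Morris-selected subset uses the
   Jansen estimators for main and total indices, closed-pair Jansen
   differences for second-order indices, and percentile bootstrap CIs
   (default 2,000 replicates; the reference analysis used $10^5$, reachable
   by configuration). The pair synergy is
   $S_{ij} / ((T_i - S_i) + (T_j - S_j))$; when the summed higher-order
   effects fall below 0.05 the ratio of two Monte-Carlo zeros is reported
   as 0 rather than noise. Estimator correctness is checked against the
   closed-form variance decomposition of the Ishigami function and against
   linear/additive functions.

An alternative objective (mean activity of designated output nodes at the
stimulated steady state) is available alongside the validation percent,
since key-reaction rankings should be robust to that choice.

## Crosstalk inference

Missing interactions are proposed exhaustively, one edge at a time: OR
candidates are all $N^2$ ordered node pairs (self-loops included — they
model autoregulation and make the count exactly $N^2$), added as a new
single-reactant activating reaction; AND candidates attach each node as an
extra activating reactant to each of the $R_{int}$ intermediate reactions
($N \cdot R_{int}$ cases). New edges inherit the default reaction
parameters, keeping the screen parameter-free. Each candidate is scored by
the change in validation percent plus the counts of records corrected and
broken; ranking is by delta, then corrected, then lexicographic order.
Activating-only OR enumeration is the default (matching the $N^2$ census);
inhibiting candidates double the space behind a flag. Only single additions
are screened; sequential greedy revision is supported by applying the top
candidate and re-screening.

## Synthetic data: what it emulates and what it does not

Every stage is testable offline through two generators:

* `make_toy_network()` builds cascades, branched/reconvergent motifs,
  negative-feedback loops and a fixed crosstalk demonstration network
  (two receptor inputs, a two-input AND gate, an inhibiting edge).
* `make_records()` samples (context, class, perturbation, measured node)
  combinations, simulates them under a chosen "true" parameter set and
  records the model's own classified direction — using the same 1%
  threshold machinery as validation, so the generator is an exact oracle:
  with label-noise probability $q$, the realized validation percent under
  the true parameters is exactly $100\,(1 - \hat q)$.
* `make_recovery_case()` withholds one true edge from the demonstration
  network and emits exhaustive noise-free records from the full model; the
  screen provably ranks the withheld edge first, which anchors the
  crosstalk acceptance check.
* `make_benchmark_network()` / `make_benchmark_records()` generate purely
  structural stand-ins at the published compendium's dimensions (106 nodes,
  191 reactions, 17 inputs; 450 qualitative records with 75 per studied
  context; 100 semi-quantitative records) for parsing and enumeration
  checks; their observation labels are random, not simulation-derived.

Passing these tests demonstrates internal consistency — parser, engine,
scorer, optimizer and screens agree with independent oracles — not
biological fidelity. Synthetic records carry only label noise on
directions; real curated compendia additionally carry assay heterogeneity,
inter-study disagreement and reporting bias that no generator here
emulates, and random graphs lack the hub structure and redundant parallel
pathways of curated signaling networks. Conclusions about a real network
require the corresponding curated tables.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at desk scale by design:
toy networks of 4–10 nodes, record sets of tens of rows, Morris with 4–16
trajectories, Sobol at $N \le 8192$ with 2,000 bootstrap replicates, and
estimation with a handful of starts — sizes chosen so the full suite
exercises every stage in minutes on one core. The corresponding production
settings (100 starts, 300/8/16 Morris sampling, $N$ up to $10^5$) are plain
arguments. All stochastic steps consume explicit seeds; the pipeline
manifest records the config snapshot, input file hashes and derived
per-stage seeds, and re-running with the same manifest reproduces identical
outputs regardless of execution order or worker count.

## Known limitations

* Qualitative directions in monotone cascades are often insensitive to
  parameter magnitude, so the validation-percent objective can be locally
  flat; the alternative output-activity objective is provided for
  sensitivity analysis on such toys.
* A uniform $\tau$ is assumed by default (per-node overrides exist); no
  distinction is made between signaling and transcriptional time scales.
* Only one edge is added at a time during crosstalk inference; synergistic
  pairs must be found greedily.
* The semi-quantitative matching rule and the trajectory-spread criterion
  are documented choices where the field's conventions are not fixed; both
  sit behind switches.
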