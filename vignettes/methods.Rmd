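---
title: "Cue-based flux prediction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cue-based flux prediction: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcue)
```

## The model

`fluxcue` predicts which reactions of a metabolic network carry flux in a
given condition by reconciling two kinds of evidence that individually
under-determine the answer: gene expression, which suggests how much enzyme
is available, and stoichiometry, which constrains which flux patterns are
physically possible at steady state.

The flux space is the classical constraint-based polytope
$\{v : S v = 0,\ l \le v \le u\}$, where $S$ is the metabolites-by-reactions
stoichiometric matrix. Expression enters as *trinary cues*: after collapsing
replicates and discretizing (below), every reaction is cued highly expressed
($R_H$), lowly expressed ($R_L$), or moderate (no cue). The integration
problem is a mixed-integer program: maximize the number of satisfied cues,
where an $R_H$ cue is satisfied by $|v_r| \ge \varepsilon$ (a reversible
reaction may satisfy it in either direction — expression carries no sign
information) and an $R_L$ cue by $|v_r| \le \texttt{zero\_tol}$.

The key interpretive idea is that *no single optimal solution is trusted*.
Cue-integration MILPs typically have many alternative optima, and which one
a solver returns is arbitrary. All condition-level outputs are therefore
defined over the whole optimal set:

* a reaction is **active** when every optimal cue reconciliation requires it
  to carry flux — operationally, forcing $|v_r| \le \texttt{zero\_tol}$
  strictly lowers the achievable objective while forcing
  $|v_r| \ge \varepsilon$ does not;
* **inactive** in the mirrored case; **undetermined** when both forcings
  preserve the optimum;
* the reported flux range is the optimum-preserving variability
  $[\min v_r, \max v_r]$ subject to retaining the optimal objective;
* a reaction is called **higher** in condition A than B only under strict
  interval separation, $\min_A v_r > \max_B v_r$. Overlapping ranges are
  *indistinguishable* — the data simply do not constrain the comparison,
  and we prefer an honest non-call to a point-estimate artifact.

Pathway-level statements use one-sided hypergeometric over-representation of
each pathway inside the set of active reactions, with Benjamini–Hochberg
FDR control across the pathways tested in one condition.

## Assumptions

* **Steady state.** Internal metabolite pools neither accumulate nor drain.
  This is the standard constraint-based assumption; transients and kinetic
  regulation are invisible to the method.
* **Expression as likelihood, not rate.** A high cue asks for *some* flux
  ($\ge \varepsilon$), never for proportionally more flux. Accordingly the
  objective counts satisfied cues; it does not weight them by expression
  magnitude.
* **GPR semantics.** `and` = enzyme complex = $\min$ of subunit states;
  `or` = isozymes = $\max$. Genes absent from the expression table are
  moderate: absence of evidence is not a cue. Reactions without a GPR can
  never be cued, though they can still be classified active when the network
  forces flux through them (exchange reactions usually are).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `epsilon` | 1 | flux units | minimum magnitude that counts as "carrying flux". The toy networks use bounds of 10, so the default is 10% of capacity. Must exceed `zero_tol`. |
| `zero_tol` | 1e-6 | flux units | magnitude treated as "no flux", absorbing LP arithmetic noise. |
| `q_low`, `q_high` | 0.25, 0.75 | quantile fractions | quantile-mode cue thresholds per condition; symmetric quartiles are the conventional choice. |
| `t_low`, `t_high` | unset | log-expression | explicit-threshold mode, bypassing quantiles; appropriate when the expression scale has known anchor points. |
| `alpha` | 0.05 | — | FDR level for enrichment significance. |
| `solver_time_limit` | unlimited | seconds | wall-clock budget per MILP; on expiry the best incumbent is returned flagged `feasible-timeout`. |
| `mip_gap` | 1e-9 | relative | retained for interface compatibility; the bundled solver is exact, so the realized gap is 0. |

The quantile definition is pinned to linear interpolation between order
statistics (`stats::quantile` type 7): any fixed definition would do, but a
pinned one makes discretization reproducible across implementations.
Whether to discretize per condition (default) or against thresholds shared
across conditions is exposed through the two modes; per-condition quartiles
follow common practice for this family of methods.

## Numerical and algorithmic choices

**LP layer.** Every subproblem the solver sees is a box-constrained
steady-state feasibility or single-coordinate optimization over
$\{S v = 0, l' \le v \le u'\}$. These are solved by a dense bounded-variable
two-phase primal simplex written for this package. The flux polytopes that
arise here are small but *highly* degenerate (zero right-hand sides, massive
tie structure), so the implementation uses Bland's smallest-index rule for
entering and leaving variables — giving guaranteed termination — and
recomputes basic values from the factorized basis every iteration, so
numerical drift cannot accumulate across degenerate pivots.

**MILP search.** Cue indicators are explored by depth-first implicit
enumeration: satisfying a cue tightens the reaction's flux box
(e.g. $l'_r = \max(l_r, \varepsilon)$), constraints only accumulate down a
branch, so one infeasible LP closes a subtree, and the bound
(satisfied so far + cues remaining) prunes against the incumbent. Leaving a
cue unsatisfied changes nothing, so that branch inherits its parent's
feasible point without an LP call. The search is exact; the objective is an
integer, and verdict comparisons between forced optima are exact integer
comparisons, so no floating tolerance can blur a classification into a
spurious `undetermined`.

**Decomposition.** $S v = 0$ separates over connected components of the
reaction graph (reactions linked by shared metabolites), so the MILP is
solved per component and objectives add. This is exact, and on the toy
networks (disjoint pathways) it reduces each solve to a handful of
variables. The exhaustive reference solver deliberately does *not*
decompose, prune, or order its search — it enumerates complete indicator
assignments and LP-checks them — so agreement between the two is a
meaningful check on the clever path.

**Degenerate inputs.** A constant expression vector has no meaningful
quantiles: all genes become moderate, with a message. An infeasible base
problem (no steady-state flux within bounds) yields an `infeasible` status,
never an error; a forced subproblem that is infeasible counts as objective
$-\infty$ for that branch. Reactions whose flux is structurally pinned to
zero are classified inactive with `obj_forced_active = -Inf`.

**Ties in enrichment ranking.** Results are ordered by adjusted then raw
p-value, then pathway name, making output order deterministic.

## The synthetic scenario

The generator builds the smallest structure in which the full pipeline's
behavior is provable rather than plausible: `n_pathways` disjoint linear
pathways (default 4), each `pathway_length` (default 6) single-gene
reactions between a source and a sink exchange, with one two-compartment
transport step near the end of each pathway mirroring the
glucose-6-phosphate shuttle from cytosol to endoplasmic reticulum that
completes hepatic glucose production. The first pathway is the planted
glucogenic route; with the default length its metabolites spell out the
glycerol route (glycerol → glycerol 3-phosphate → dihydroxyacetone
phosphate → fructose 1,6-bisphosphate → G6P(cytosol) → G6P(ER) → glucose).

The expression model draws log-scale values i.i.d. normal per gene:
induced planted genes at `mu_high = 10`, all baseline genes at `mu_mid = 5`,
noise `sigma = 1`, `n_reps = 3` replicates per condition. Two design
choices deserve explanation:

* **The depleted condition places planted genes at a low baseline**
  (`mu_low = mu_mid - (mu_high - mu_mid)`, default 0), not at `mu_mid`.
  Biologically, the glucogenic program is induced — its enzymes are not
  constitutively expressed at typical levels, and cells that cannot mount
  the induction sit low on the experiment-wide expression scale.
  Methodologically this is also what makes the cross-condition contrast
  *testable*: flux comparison uses strict interval separation, and only a
  low cue pins the depleted condition's planted flux range near zero. If
  the depleted condition carried no cue at all on those genes, its
  optimum-preserving range would be the full $[0, u]$ and every comparison
  would be honestly indistinguishable — correct behavior, but a scenario
  that cannot exercise the contrast machinery.
* **Defaults put the planted genes at exactly the top quartile**
  (4 pathways × 6 genes → 6 of 24 genes planted). Quantile cues label a
  fixed fraction of genes high by construction; aligning the planted
  fraction with `1 - q_high` means the high cue set coincides with the
  planted set rather than bleeding into decoys. With more decoy pathways
  the quartile rule would mechanically promote the strongest decoy genes to
  spurious high cues — a property of forced-quantile discretization worth
  knowing about on real data, where the explicit-threshold mode is the
  appropriate escape.

What the generator does *not* emulate: probe- and batch-level microarray
artifacts, correlated noise, shared metabolites between pathways, branched
or cyclic topology, isozyme redundancy (except in the optional `paired` GPR
mode), and genome-scale size. Passing the recovery properties therefore
shows the pipeline's logic is sound end-to-end; it does not certify
performance on a genome-scale reconstruction, where discretization
thresholds and model version dominate the outcome.

## Problem sizes

The validation suite runs at sizes where exhaustive ground truth is
computable: toy networks of 24–40 reactions, random networks of up to ~12
reactions with at most 6 cue-bearing reactions for solver-versus-oracle
equivalence (50 instances), 100 simulated studies for planted-pathway
recovery, and 1000 null replicates for the enrichment false-positive rate.
These sizes were chosen so that every claim is re-derivable from first
principles (enumeration, exact rational arithmetic, closed-form tails) in
minutes on one core.

## Known limitations

* Per-reaction classification re-solves two MILPs per reaction in the worst
  case; at genome scale restrict classification to a subsystem via the
  `reactions` argument of `classify_activity()`.
* The SBML reader supports a Level-3 FBC subset (species, stoichiometry,
  bound parameters, gene-product associations); exotic constructs are
  skipped with a message. SBML writing is out of scope.
* Enrichment treats reactions as exchangeable units; it is not
  topology-aware, and `undetermined` reactions are excluded from the active
  set by a strict reading of "predicted active".
* The method predicts flux *activity*, not flux *values*: `epsilon` is a
  detection threshold, and reported ranges are bounds over optimal
  solutions, not estimates of physiological rates.
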