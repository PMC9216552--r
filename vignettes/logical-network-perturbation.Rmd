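---
title: "Perturbation prediction on Logical Networks: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation prediction on Logical Networks: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logicpath)
```

## The setting

Curated pathway databases encode, reaction by reaction, how molecular
entities produce one another. Flattening a pathway's reactions into a
*Logical Network* — a directed graph whose edges carry activating (`+`)
or inhibiting (`-`) polarity and whose nodes combine incoming edges under
`AND` or `OR` logic — turns the qualitative question "what happens to
output O if input R is pushed up or down?" into a graph computation.
`logicpath` implements two predictors over this representation, a
calibration step that makes their outputs comparable, and the
direction-aware scoring used to confront predictions with experimental
observations.

A *root input* (RI) is a node with in-degree 0 (consumed but never
produced within the pathway); a *terminal output* (TO) has out-degree 0.
*Key outputs* default to the terminal outputs but can be designated
freely, since experimentalists often read out internal nodes (e.g. a
phosphorylated kinase) rather than a pathway's formal end products. One
*test case* is a triple (RI, direction ∈ {up, down}, key output), so a
pathway with $R$ roots and $K$ key outputs yields $2RK$ cases.

## The path-parity predictor

The rule set mirrors what a trained curator does with a pathway diagram:

1. if every path from the RI to the key output has an even number of
   inhibitory edges (including zero), the output moves in the same
   direction as the perturbation;
2. if the connecting path parity is odd, the output moves in the opposite
   direction;
3. if there is no path, or the paths split evenly between parities, no
   change is predicted;
4. with more than two paths, the majority parity decides.

Only polarity enters these rules; `AND`/`OR` logic is deliberately
ignored, because the manual procedure reasons about routes, not about
quantitative input combination. Paths are *simple* (no node revisited),
so feedback loops cannot inflate path counts. Enumeration is a
depth-first search with deterministic lexicographic successor order,
bounded by `max_len` (default 50 edges, comfortably above the longest
RI-to-output distances seen in curated pathways, which reach the
mid-forties) and `max_paths` (default 10<sup>4</sup>); exceeding either
cap flags the prediction low-confidence instead of silently truncating.

Two design points were genuinely open and are resolved as follows.
*Ties with more than two paths* (e.g. 2 even vs 2 odd) generalize rule 3
and predict no change — the two-path cancellation rule applied to the
majority vote. *Negative feedback loops between an RI and a key output*
are reported to have driven some manual no-change calls, but the precise
structural criterion is not defined anywhere we could ground it; the
package therefore exposes path enumeration and shortest-path summaries so
a user can apply such an override, but never applies one automatically.

## The continuous optimization model

Node activities are fold changes relative to normal: $x \in [0.01, 100]$
with $x = 1$ the unperturbed level. Each non-root node has one equation
over its parents' values:

* `AND` fan-in: $x_v = \prod_e t_e(\bar x_{src(e)})$,
* `OR` fan-in: $x_v = \operatorname{mean}_e\, t_e(\bar x_{src(e)})$,

where the edge transform is $t_e(u) = u$ for activating and
$t_e(u) = 1/u$ for inhibiting edges. `OR` is the entity-set case — a set
of interchangeable isozymes contributes the average of its members, which
also means a perturbation of one member is diluted by the set size (a
known limitation discussed below).

Every node carries *two* values: $\bar x_v$, the value it feeds into
downstream equations, and $x_v$, the value its own equation produces.
Perturbed roots are fixed ($\bar x = x$ = 100 for "up", 0.01 for "down"
by default — saturating values, since the magnitude of a real
knockdown/overexpression is rarely known); unperturbed roots are fixed at
baseline 1, modelling an otherwise-normal cell. The solver minimizes the
total disagreement $\sum_v |\bar x_v - x_v|$ (the L1 distance is the
default; a squared distance, available as `objective = "L2"`, would
spread residual disagreement across nodes rather than concentrating it).
On a consistent network the optimum is 0 and the pair collapses to a
single propagated value; around contradictory structures — a negative
feedback loop most prominently — the slack absorbs the inconsistency and
the objective reports how much absorbing was needed.

### Numerical strategy

Internally everything is solved in $\log_{10}$ space: the box becomes the
symmetric $[-2, 2]$, products become sums, reciprocals become sign flips,
and baseline is 0. The solver is a deterministic nonlinear Gauss–Seidel
relaxation started from all-baseline: each sweep replaces every free
node's value by its bound-clamped equation output until the largest
per-sweep change falls below `tol` (default $10^{-9}$, at most `max_iter`
= 500 sweeps). On acyclic networks this converges to the exact
propagation fixed point (verified in the test suite against an
independent closed-form topological evaluation on pure-`AND` networks).
When feedback makes the relaxation oscillate, the last iterate seeds a
box-constrained quasi-Newton polish (`optim(method = "L-BFGS-B")`) of a
smoothed L1 objective ($\sqrt{r^2 + 10^{-10}}$ per node, to keep the
kinks differentiable). There is no randomness anywhere on the solver
path, so identical inputs give identical solutions.

Bounds are enforced by projecting each equation output into the box; a
saturated chain (e.g. an inhibitory edge fed 0.01) therefore clamps at
100 rather than leaving the model infeasible. Because the default bounds
are reciprocal ($0.01 = 1/100$), perturbing a root by $f$ versus $1/f$
on a pure-`AND` network yields exactly reciprocal solutions — an
antisymmetry the acceptance suite asserts.

One semantic choice was open: whether an inhibitory edge under `OR`
fan-in contributes its raw or reciprocal value to the average. We apply
the same per-edge transform $t_e$ before averaging in both logic classes,
for uniform inhibition semantics. Similarly, whether `OR` should average
raw values (default, `or_mode = "arithmetic_raw"`) or log-values
(`or_mode = "geometric_log"`, which makes the whole system linear and is
noticeably friendlier to analysis) is configurable; the arithmetic
average is the default because it is the natural entity-set semantics —
every member's abundance counts equally on the raw scale.

## Discretization and calibration

The continuous predictor must be reduced to {up, down, no change} to be
comparable with curator calls or literature outcomes. With cutoff $c$
(default 0.15), the default *multiplicative-symmetric* convention calls
"up" at $x \ge 1 + c$ and "down" at $x \le 1/(1+c)$ — reciprocal
boundaries, consistent with the log-scale model; an additive convention
($x \le 1 - c$) is available because "a 15% change" is genuinely
ambiguous between the two readings. `sweep_cutoffs()` evaluates a cutoff
grid against reference calls, computing a direction-aware binary
confusion per cutoff ("positive" = any predicted change, with the correct
direction required for a true positive), and returns the F1-maximizing
cutoff, breaking ties toward the smaller cutoff. The default grid is
{1%, 5%, 10%, ..., 95%, 99%} ∪ {15%}; a `"literal"` grid
{1%, 6%, ..., 96%} is provided because the phrase "between 1% and 99% in
5% increments" admits both readings.

## Evaluation

Scoring is three-class but direction-aware. A predicted change matching
the observed direction is a TP; both-no-change is a TN; a missed change
is an FN; a predicted change where none was observed is an FP; and a
predicted change *opposite* to the observed one is the special
wrong-direction false positive, FP-WD, counted inside the FP total by
every derived metric (the published per-pathway arithmetic is only
consistent under that treatment, which the acceptance suite verifies
cell by cell). Ratios with zero denominators are reported `NA`, never
silently 0. Aggregation across pathways is either *pooled* (sum counts,
then derive) or *averaged* (per-pathway metrics, unweighted mean ±
sample SD — sample, not population, which is the reading that reproduces
the published summary rows; `NA` metrics are skipped). Display rounding
uses round-half-up, matching conventional table presentation rather than
R's round-half-to-even.

Inter-rater agreement offers pairwise percent agreement, pairwise
Cohen's kappa (expected agreement from the two raters' marginals), and
Fleiss' kappa for a fixed panel (a complete cases × raters matrix;
ragged panels are rejected). `fleiss_kappa()` also accepts a precomputed
observed/expected agreement pair, which is how the published summary
statistic can be checked directly.

## The synthetic-data world

`generate_network()` builds layered, connected DAGs: layer-1 nodes are
the root inputs, every later node draws up to `set_fan_in` parents under
a single logic class, and every non-terminal node is guaranteed a child.
Defaults — 5 layers × width 4 (20 nodes, well under the 60-node budget
that keeps exhaustive path enumeration sub-second), 30% inhibitory
edges, 30% `OR` nodes, 20% layer-skipping edges, no feedback unless
requested — describe a small signalling cascade with a realistic
minority of inhibitory interactions. These values were chosen once as a
plausible desk-scale stand-in and are not tuned against any test
outcome.

Ground truth for generated cases is computed by a deliberately naive
oracle: igraph enumerates *all* simple paths and a parity majority vote
assigns the class. It shares no code with the production curator
predictor (own DFS) — that independence is the point, since the
acceptance suite demands 100% agreement between the two on every
generated case.

What the generator does *not* emulate: real pathway size distributions
(hundreds to a thousand nodes), hub structure, annotation gaps, or
literature bias in which cases have observable outcomes. A green
synthetic suite therefore establishes the *internal correctness* of the
predictors (rules faithfully applied, solver equations faithfully
solved), not the *empirical accuracy* of any curated pathway — the
latter depends on knowledgebase completeness and can only be measured
against real evidence-backed test cases, which are an optional external
workflow for this package.

## Degenerate inputs and tie-breaks

* Networks must have ≥1 edge; empty networks are refused at read and
  write time.
* Exact duplicate edges collapse with a message; same-pair edges of
  opposite polarity are kept (dual regulation).
* Mixed `AND`/`OR` fan-in is normalized by routing the `OR` group
  through an inserted auxiliary node (`<id>..or`, positive `AND` link),
  so every equation is well-defined.
* A pure cycle has no roots and no terminals — valid, with zero test
  cases by construction.
* A key output unreachable from the perturbed root stays at baseline 1
  and discretizes to no change at any cutoff.
* F1 is defined as 0 when there are no true positives (rather than NA)
  so that cutoff sweeps remain comparable.

## Known limitations

* Entity-set averaging dilutes single-member perturbations in large
  `OR` sets; per-member weights (e.g. tissue-specific expression) are
  out of scope.
* The solver handles cycles by slack absorption, not dynamics: it finds
  a minimally inconsistent static assignment, and oscillatory behaviour
  is outside the model class.
* Path enumeration is exponential in the worst case; the caps make the
  curator predictor safe on large dense networks at the cost of a
  low-confidence flag.
* Multi-root simultaneous perturbations are supported by
  `build_model()` but untested against any reference behaviour; the
  test-case design is single-root.
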