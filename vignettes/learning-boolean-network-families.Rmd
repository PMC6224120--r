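---
title: "Learning Boolean network families from perturbation time series: models, search, and certification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Boolean network families from perturbation time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnfit)
```

This vignette is the package's methods account: the models and assumptions,
the tunable parameters and their defaults, the numerical and algorithmic
choices made where the design was genuinely open, and what the synthetic
benchmarks do and do not demonstrate.

## The modelling frame

**Prior knowledge network.** A `pkn` is a signed digraph `(V, E, σ)` with a
role for each node: stimuli are experimentally set to 0/1 for a whole
trajectory, inhibitors can be clamped to 0, readouts are measured on a
continuous scale, and the rest are unobserved. Roles are mutually exclusive
except that a protein can be inhibited *and* measured
(`inhibitor_and_readout`); the constructor enforces exactly this overlap.
The PKN constrains structure only — it carries no dynamics.

**Boolean networks and compatibility.** A candidate network gives node
`v_i` a function `f_i` written as a disjunction of conjunctive clauses
(hyper-edges). Compatibility with the PKN is concretized literal-wise: `u`
may appear positively (negatively) in a clause of `f_i` only if the PKN has
an edge `u → v_i` signed `+1` (`−1`); a clause never contains both
polarities of one regulator; `clause_space()` enumerates all admissible
clauses per node in a canonical order (size, then printed form), which makes
every downstream enumeration deterministic. Two caps bound the space:
`max_clause_size` (default 2) and `max_clauses_per_node` (default 3). These
defaults are a tractability choice of this package, exposed as configuration
— small AND gates and at most a few alternative activation routes per node
cover the bulk of curated signaling logic, but both caps can be raised where
the PKN's in-degrees warrant it.

**Semantics.** A state is a 0/1 vector over all nodes. A transition updates
an arbitrary non-empty subset of non-clamped nodes simultaneously to their
`f_i` value. Synchronous and asynchronous updates are both sub-relations, so
every result that quantifies over this transition relation (reachability,
certification) is schedule-robust. Nodes with no clauses keep their current
value; unobserved sources are thereby frozen at their (searched) initial
value rather than silently forced to 0. Clampings derive from perturbations:
every stimulus is clamped at its 0/1 setting; an inhibitor is clamped at 0
exactly when it was applied.

## Data model and preprocessing

Measurements live in a long table (perturbation, time, node, value) inside a
`pert_ts` container together with the treatment settings. `normalize()`
implements per-node maximum normalization: every value of node `i` is
divided by the global maximum of node `i` over all perturbations and time
points, so each observed node peaks at exactly 1. The operation is
idempotent, and binarization after normalization is invariant to any
positive per-node rescaling of the raw data.

`binarize()` thresholds at 0.5 by default, with ties mapping to 1. The
midpoint is the natural cut on a max-normalized scale; it is exposed because
the right cut is ultimately assay-dependent.

`qc_repair()` applies four structural repairs in a fixed order, each
recorded in a machine-readable report whose replay (`qc_replay()`)
reconstructs the output — the report is exhaustive by construction:

* **step-2** missing time-0 readings are filled from control readings when
  available;
* **step-3** duplicated readings of one cell keep the first value in file
  order (an arbitrary but deterministic choice);
* **step-4** a perturbation whose *applied inhibitor* is itself measured and
  moves by more than `tolerance` (max − min on the per-node-max normalized
  scale) is dropped as experimentally inconsistent — an inhibited protein
  has no business being dynamic;
* **step-5** perturbations still containing missing values are dropped; no
  imputation is attempted, because guessing hidden time points inside the
  trace search would multiply its cost for little benefit.

The step-4 `tolerance` default is 0.1 — on clean continuous data, anything
beyond a 10% swing of an inhibited readout is suspicious. One caveat
discovered while integrating the synthetic generator: band-coded synthetic
signals (below) make even a perfectly clamped node jitter within a 0.3-wide
band, so `run_pipeline()` passes `tolerance = 0.4` for such data — only
swings beyond one full band width count as genuine dynamics. Analyses of
data with other noise structures should set the tolerance to whatever
"flat" means on their scale.

## The objective and its floor

For binary traces `y` against normalized data `t`, the objective is the RMSE
over the complete readout × time × perturbation grid. Because predictions
are binary, each cell independently contributes at least
`min(t², (1−t)²)`; summed, this is the **discrete RMSE** — the floor imposed
by discretization alone, attained exactly by the binarized data. All search
is therefore organized around the *excess* above this floor: a candidate
that achieves zero excess is globally optimal with a proof that does not
require enumerating anything else. The **RMSE ratio** discrete/model is ≤ 1
by construction and equals 1 exactly on a zero-penalty fit.

## Over-approximated reachability

Exact reachability between consecutive binarized observations is
PSPACE-complete, so the learner instead enforces **support consistency**. A
meta-state assigns each node a non-empty subset of `{0,1}`; a widening step
replaces one component `u_i` by `u_i ∪ {f_i(x) : x ∈ u}`. Starting from the
singleton meta-state of `x`, components only ever grow from `{x_i}` to
`{0,1}`, so the reachable meta-states are exactly encodings of "widened
bit-sets" — the package represents them as such. `y` is support-consistent
with `x` when some reachable meta-state `u` contains `y` and, for every
component with `y_i = x_i`, either `u_i` stayed a singleton or some state of
`u` maps to `y_i` under `f_i`. Reachability implies support consistency; the
converse fails, and that gap is precisely what the later certification stage
detects.

Two exact shortcuts make the check cheap. The per-node image is monotone in
the meta-state, so (i) every reachable meta-state lies below the greedy
maximal widening fixpoint `W*`, and (ii) `W*` is itself reachable one
component at a time. A query that flips a bit outside `W*` is therefore
`FALSE` outright, and a query that passes all three conditions at `W*` is
`TRUE` outright; only the ambiguous remainder falls back to a memo-free BFS
over the widening lattice. The fast path and the full closure are checked
against each other (and against a brute-force reachability oracle) in the
test suite.

## The learner

`learn()` searches the product of candidate networks and binary traces. Per
perturbation, a trace is one full state per measured time point: clamped
bits fixed, observed bits free (deviating from the binarized data costs the
corresponding excess), unobserved bits free at zero cost — the unobserved
components are existential search variables, including at time 0.
Consecutive states must be support-consistent. The per-candidate inner
problem is solved by uniform-cost search over (time point, state) with
accumulated excess as priority; states at each time point are pre-sorted by
excess so expansion enumerates only affordable targets, and the best
*constant* trace — always feasible, since support consistency is reflexive —
provides a free upper bound that caps the search from the start.

Across candidates, two regimes:

* **Exhaustive branch-and-bound** (candidate space within
  `max_candidates`): lexicographic enumeration with the incumbent as bound —
  global optimality by completeness. This covers the scale at which the
  optimality property is verified against an independent brute-force
  enumeration in the tests (≤ 4 nodes, ≤ 2 perturbations, k ≤ 3).
* **Greedy-seeded coordinate descent** (larger spaces): per-node options are
  ordered by a local transition-fit score on binarized pseudo-states (a
  heuristic that only orders, never excludes), the search starts from the
  all-best assignment, sweeps nodes with first-improvement moves, and then
  enumerates co-optimal neighbours around the incumbent — per node, the
  options preserving the objective, then their lexicographic product, each
  candidate re-verified in full. This mirrors the clustering of co-optimal
  models that complete solvers exhibit. An incumbent at the discretization
  floor is still *provably* globally optimal (the floor is a universal
  bound), so `proven_optimal` can be `TRUE` without exhaustion; otherwise it
  is `TRUE` only on exhaustion, and `truncated` flags any stop before all
  co-optima were listed.

Ties in the objective are resolved at an absolute tolerance of `1e-9`
(objectives are sums of squares of values on `[0,1]`; genuine distinct
optima differ by far more at desk scale). All returned models share one
objective; `penalized_points` lists the data points where the optimal trace
overrides the binarized data, and `corrected` is the dataset with exactly
those corrections applied — it is this corrected dataset that certification
takes as its specification.

## Certification (model checking)

`verify()` decides, per perturbation, whether the corrected binarized
observation sequence can be threaded through the exact state graph:
frontier `F_1` is every full state matching observation 1 (unobserved
components free — consistent with the learner's existential choices),
`F_{j+1}` is the set of states matching observation `j+1` reachable from
`F_j`, and the trajectory passes iff `F_k` is non-empty — the explicit-state
form of nested `EF` reachability. A network is `TP` when every perturbation
passes, `FP` when some transition exactly fails (the first failing index is
reported), and `undecided` only when the exploration budget was hit —
budgets are counted in explored states, not wall-clock, so verdicts are
deterministic.

Verification runs on the cone of influence of the observed nodes (their
regulatory ancestors). Nodes outside the cone can never affect an observed
value and their updates interleave freely, so the reduction preserves
verdicts while shrinking the state space; the checker refuses cones beyond
20 nodes rather than silently thrash. Passing perturbations can return a
witness path whose replay (every step a legal transition, every anchor
matching its observation) is itself asserted in the tests. `triage()` runs
the family in enumeration order under per-network and total budgets,
mirroring the practice of time-boxing certification and leaving the
remainder undecided.

## Family analytics

* **Frequencies and aggregation**: a hyper-edge's frequency is the fraction
  of family members containing it; `aggregate_family()` keeps frequencies
  *strictly* above the threshold (default 0.3), so `threshold = 0`
  reproduces the union and thresholds are monotone.
* **Similarity**: Jaccard on hyper-edge *sets* (node ← clause pairs), not on
  plain edges — families are compared by their regulatory logic, not just
  wiring. Two empty sets count as identical. `family_similarity()` averages
  Jaccard between a gold standard and each member; with gold = the family's
  own (thresholded) aggregate it measures homogeneity, with gold = another
  family's aggregate it compares contexts and is deliberately asymmetric —
  `similarity_matrix()` reports both orientations. The union network is also
  supported as gold; the thresholded aggregate is the default because it is
  the family's consensus rather than its noise.
* **Downstream validation**: `downstream_set()` is directed reachability
  over hyper-edges excluding the root; `tpr_fpr()` uses the plain set
  counts. `family_auroc()` turns one (FPR, TPR) point per network into an
  area: points are sorted by FPR, reduced to their upper envelope at
  duplicate FPRs, anchored at (0,0) and (1,1), and integrated by the
  trapezoidal rule. A point-cloud AUROC is under-specified in general; the
  envelope + trapezoid construction was chosen because it is monotone,
  invariant to duplication and ordering, and reduces to the familiar value
  on a proper curve.
* **Centrality**: betweenness on the hyper-edge graph, normalized by the
  number of *connected* ordered source–target pairs avoiding the node, so
  the middle of a simple directed path scores exactly 1. igraph supplies
  the shortest-path machinery; the normalization is done by hand because
  the conventional `(n−1)(n−2)` denominator counts unconnected pairs and
  would not give the path example its natural score.
* **Random-data specificity**: `random_validation()` redraws every readout
  value uniformly on [0,1] (treatments untouched), recomputes each sample's
  own discretization floor and the best model RMSE attainable by the fixed
  family (trace search only, networks frozen — precomputed
  support-consistency adjacency plus min-plus dynamic programming over time
  points), and returns the per-sample ratio. Structured self-generated data
  give ratio 1; random resamples should fall clearly below — the package's
  operational definition of "the family is specific to its data".

## The synthetic generator

`sim_config()` defaults describe the study conditions the package is
validated under: 10 nodes, 3 stimuli (parentless, clamped), 1 inhibitor that
is also measured, every remaining node but one a readout, 6 perturbations
from a deterministic panel (single stimuli, stimulus × inhibitor, all-on,
stimulus pairs), and 7 time points on the canonical 0/5/15/30/60/120/240
minute grid. Ground-truth networks are drawn uniformly from the PKN's own
clause space under the learner's caps, so identifiability is a property of
the data, not of a privileged hypothesis class. Trajectories are random
walks in the same any-subset transition system the learner assumes (which is
what guarantees that a noise-free simulation admits a zero-excess fit and a
TP certificate); recorded states are emitted through bands — 0 as
U(0.05, 0.35), 1 as U(0.65, 0.95) — plus Gaussian noise (`noise_sd`,
default 0.05), clipped to [0,1]. At zero noise, binarization at 0.5 recovers
the hidden states exactly; from `noise_sd ≈ 0.15` the bands overlap the
threshold and binarization errors appear. Three QC defects can be injected
(missing t0, duplicated time point, dynamically-behaving applied inhibitor),
each engineered to trigger exactly one repair rule.

What the generator does *not* emulate: replicate structure, heteroscedastic
or correlated noise, unmodelled off-network regulation, non-binary
intermediate expression levels, and measurement batch effects. Passing the
recovery suites therefore shows the machinery is correct and the method
identifiable under its own assumptions — not that any particular real screen
satisfies those assumptions.

## Problem sizes and budgets

The validation suites run at sizes chosen to keep the full test run in
minutes on one core: soundness is exhaustive over all one-clause 3-node
networks (≈ 110k reachable pairs) plus 200 seeded random networks up to 8
nodes; learner optimality is checked against full brute force on 20 seeded
instances of 3–4 nodes; parameter recovery uses noise-free screens of 8 and
10 nodes with 5–6 perturbations on the 7-point grid (12-node instances
recover equally — ratio 1, TP certificates — in a few minutes and are
exercised outside the default suite); the random-data protocol uses the full
100 samples. Default exploration budgets (2^20 states for reachability and
certification, 20k queue pops per trace search) are far above what any of
these sizes need; they exist so that pathological inputs degrade into
explicit `undecided`/`Inf` outcomes rather than unbounded work.

## Known limitations

* Explicit-state everything: the learner handles up to 16 unclamped nodes
  per perturbation and the checker up to 20 cone nodes; beyond that, the
  right tool is a symbolic or ASP/BDD engine, not this package.
* The greedy regime's `proven_optimal = FALSE` results are genuinely
  unproven: a better network outside the explored neighbourhood may exist
  whenever the floor was not attained.
* One clause space convention: only direct PKN predecessors feed a node's
  clauses; network compression or indirect-influence rewiring is out of
  scope.
* Binarization is a single global threshold; per-node or per-time adaptive
  cuts are not implemented.
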