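---
title: "Methods: minimum interaction sets supporting protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum interaction sets supporting protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minppi)
```

## The problem and its assumptions

A protein complex is modelled as a set of proteins, and the only structural
requirement imposed is *induced connectivity*: complex $C_p$ is supported by
a network when the subgraph on $C_p$'s members, using only edges with both
endpoints inside $C_p$, has a single connected component. Given known
interactions $E$ and a catalogue $\mathcal{C} = \{C_1, \dots, C_m\}$, the
package finds a minimum edge set $E'$ such that every complex is supported
by $(V, E \cup E')$.

This is a deliberately minimal model of complex formation. It does not
require cliques (physical interaction of every subunit pair), does not use
stoichiometry or interaction weights, and treats the catalogue as ground
truth. Consequently $|E'|$ is a *lower bound* on the number of interactions
missing from a database, not an estimate of the full missing set, and the
predicted edges are hypotheses ranked by structural evidence only.

Two useful reductions shape everything downstream:

* **Candidate restriction.** An edge between proteins that never share a
  complex lies inside no induced subgraph, so both solvers search only
  co-complexed pairs. This preserves optima exactly.
* **Block additivity.** A candidate edge belongs to two complexes only when
  they share *both* of its endpoints. Grouping complexes that share at
  least two proteins (equivalently, at least one candidate pair) into
  blocks, every candidate pair belongs to exactly one block and per-complex
  feasibility depends only on its block, so the optimum is the sum of block
  optima. Complexes that pairwise share at most one protein form singleton
  blocks whose optimum is the closed form $c_p(E) - 1$ (current component
  count minus one); catalogues with only sparse overlaps are therefore
  solved in closed form, and search effort concentrates on the rare
  heavily-overlapping blocks.

## The exact integer program

`build_ilp()` encodes per-complex connectivity with a doubling scheme. For
complex $C_p$ and members $i < j$, binary variables $x^{p,t}_{ij}$ assert
that $i$ and $j$ are connected using at most $2^t$ hops of chosen edges:

* $x^{p,T_p}_{ij} = 1$ for all pairs (connectivity must hold at the horizon),
* $x^{p,0}_{ij} \le e_{ij}$ (a 1-hop connection is the edge itself),
* $x^{p,t+1}_{ij} \le x^{p,t}_{ij} + \sum_{k \notin \{i,j\}} y^{p,t+1}_{ij,k}$,
* $y^{p,t+1}_{ij,k} \le \tfrac12\left(x^{p,t}_{ik} + x^{p,t}_{kj}\right)$,

with horizon $T_p = \lceil \log_2 |C_p| \rceil$: each step concatenates two
paths, so path length doubles per step, and a connected subgraph on $s$
vertices never needs paths longer than $s - 1 \le 2^{\lceil \log_2 s\rceil}$.
The base of the logarithm follows from this doubling argument; the
`extra_steps` argument of `build_ilp()` exists to validate (as the test
suite does) that adding a step never changes the optimum. The objective
minimizes $\sum e_{ij}$ over candidate pairs. Known edges are folded in by
fixing $e_{ij} = 1$ with zero objective coefficient — an exact and
numerically safe equivalent of pricing known edges below any unit-cost
total. The third constraint is emitted once per $(p, i, j, t)$ with the full
sum over relays $k$, the only reading under which the relaxation is
meaningful.

Model size grows as $\sum_p |C_p|^3 T_p$: it is the largest complex, not
the catalogue size, that decides tractability. `build_ilp()` therefore
refuses complexes above `max_subunits` (default 8) with a resource error
unless explicitly overridden; beyond that size the relay-variable count and
the solver's memory use grow steeply.

### Solving

`write_lp()` serializes the model in CPLEX-dialect LP format with
deterministic naming (`e_i_j`, `x_p_t_i_j`, `y_p_t_i_j_k`, protein indices
into the sorted universe) and byte-stable output, so external MILP solvers
can be used directly. `solve_ilp()` provides two exact back ends:

* `"bb"` — a pure-R branch and bound. The auxiliary $x, y$ variables are
  uniquely implied by the edge variables (an assignment extends to them iff
  every complex is connected under the chosen edges), so exact search over
  edge variables with union–find connectivity checking solves the binary
  program to global optimality. The search runs per block, starts from the
  greedy solution as incumbent, and uses three lower bounds: the largest
  per-complex deficit $\max_p (c_p - 1)$, the potential bound
  $\lceil \Phi / \max \text{co-membership} \rceil$, and a union bound (all
  proteins of a block end up mutually connected through intra-complex
  paths, so at least *components − 1* merges remain). Iterative deepening
  between the bound and the incumbent either proves the greedy solution
  optimal or finds a better one. A node budget (`max_nodes`, default
  5·10⁵) turns pathological searches into an explicit resource error
  rather than a silent non-optimal answer.
* `"highs"` — hands the full variable/constraint system to the HiGHS MILP
  solver through a bundled python/scipy bridge (`inst/python/`), with the
  relative MIP gap pinned to 0 so termination implies proven optimality.

The default `"auto"` runs the branch and bound first and falls back to
HiGHS when the node budget is exhausted. Both back ends prove optimality
and always agree on the objective; when several optimal edge sets exist
they may return different ones. The LP relaxation of the doubling encoding
is weak (fractional $x$ values certify "connectivity" cheaply), which is
why the block-decomposed combinatorial search usually dominates a generic
MILP solver on catalogue-shaped instances, while the MILP back end is the
robust choice for adversarial dense blocks.

## The greedy approximation and its determinism

`greedy_min_ppi()` starts from the known edges and repeatedly inserts the
candidate pair with the maximal decrease of the potential
$\Phi = \sum_p (c_p - 1)$ — equivalently, the pair that joins two
components in the largest number of complexes. Every insertion decreases
$\Phi$ by at least one, so at most $\Phi(E)$ edges are inserted and the
result is always feasible; the classical analysis of this potential-based
greedy gives an $O(\log m)$ approximation ratio. Duplicate complexes are
deduplicated for connectivity bookkeeping but counted with multiplicity in
$\Phi$ and in tie-breaking, since they legitimately weight the evidence for
a pair.

Ties are broken by (1) potential decrease, (2) per-pair co-membership
count across the catalogue, (3) bytewise-lexicographic pair order. The
third criterion makes the entire output — edge set *and* insertion order —
a function of the instance as a set system, not of its presentation:
shuffling complex order or member order provably cannot change the result.
This determinism is a design choice, not a theorem about other
implementations; an implementation breaking ties by input position can
return different (even differently-sized) solutions for reordered inputs,
and `shuffle_instance()` exists precisely to audit this property.

Insertion rank doubles as a confidence score: with $N$ added edges, the
rank-$r$ edge scores $N - r + 1$. The first insertions bridge components in
many complexes at once and are the structurally best-supported
predictions. Ranks attached to ILP or oracle solutions are positional only
(those solvers have no insertion semantics).

The reduction `reduce_to_network_construction()` expresses a non-empty
known edge set in the cost-weighted network construction formulation:
known pairs cost a symbolic $\epsilon$, all others cost 1. The tiers are
compared lexicographically (unit total first, $\epsilon$-count second)
instead of instantiating a numeric $\epsilon < 2^{-n}$, which would
underflow IEEE doubles for $n$ beyond a few hundred proteins; the symbolic
comparison is exact at any scale. Solving the weighted instance greedily —
all $\epsilon$ edges as free pre-insertions, then unit edges by potential
decrease — recovers `greedy_min_ppi()` exactly, which the test suite checks
on random instances.

## Synthetic catalogues

`generate_instance()` draws: complex count uniform on `1:complex_cap`,
complex sizes uniform on `min_subunits:subunit_cap`, members uniform
without replacement from a fixed universe of `protein_cap` proteins, no
known edges. Uniform sampling at every level is the package's choice of a
neutral null regime — the regimes are identified by their caps (small:
10/20/5; moderate: 100/100/4; large for the shuffling experiment:
1600/400/5), and the generating parameters are recorded in a `# spec:`
header when catalogues are written to disk, so a regime is auditable from
its file. Duplicate complexes arising by chance are kept, as real
catalogues also contain repeated subunit sets.

What the generator does *not* emulate: the long-tailed complex-size
distributions of real catalogues (CYC2008 contains complexes with dozens
of subunits), correlated membership (paralogues, shared cores), or any
known-edge structure. Passing tests on these regimes therefore demonstrate
algorithmic correctness and determinism, not calibrated performance on
real catalogues; on real data the subunit-cap guardrail of the ILP binds
much earlier, and only the greedy solver is expected to scale.

`shuffle_instance()` permutes complex order and member order while names
travel with their complexes. Together with name-sorted serialization in
`write_solution()`, a shuffled instance yields byte-identical solver
output; complexes left unnamed get positional names at build time, so
shuffling an unnamed catalogue relabels (but never re-solves) its
complexes.

## Evaluation choices

`confusion_metrics()` requires the pair universe as an explicit argument:
the negative class of an interaction-prediction experiment is a modelling
decision (here typically all pairs over the proteins under study, see
`pair_universe()`), and defaulting it silently would bake that decision
in. Zero-denominator criteria are reported as `NA` rather than 0.
`roc_auc()` is the Mann–Whitney statistic with midrank tie correction,
identical to the trapezoidal ROC area. Score combination follows
$S_c = SPE \cdot S_g + S_e$ over the union of edges, a missing term
contributing 0 — an edge found only by the augmentation carries no
external evidence and vice versa. In `overlap_summary()` the "top $k$"
average is taken over gold scores of the $k$ best common edges ranked by
predicted score (ties bytewise); averaging predicted scores instead is
available via `average = "predicted"`, since both conventions appear in
comparative studies.

## Numerical and degenerate-input conventions

* Protein identifiers are opaque strings compared bytewise (radix
  collation), making every ordering locale-independent.
* Singleton complexes are vacuously connected; size-2 complexes force
  their single pair; both are handled by the general code path.
* Known edges whose endpoints share no complex are accepted, recorded in
  the instance's validation report, and ignored by the solvers.
* Within-complex duplicate member listings are dropped on construction and
  recorded; duplicate complexes are kept.
* `brute_force_min()` enumerates subsets in increasing size per block and
  refuses instances with more than `pair_budget` (default 20) candidate
  pairs, since its purpose is to be an obviously-correct oracle, not a
  solver.

## Problem sizes exercised by the tests

The suite solves, among others: 50 random instances at caps (9, 5, 4)
against the oracle; 10 instances at (100, 100, 4) comparing greedy and
exact objectives; one instance at (1600, 400, 5) under 100 shuffled
presentations; 20 single-complex and 20 near-disjoint closed-form cases;
and 20 nested known-edge monotonicity pairs. These sizes keep the full
suite in the low minutes on one CPU while covering every solver path,
including both exact back ends and their agreement.

## Known limitations

* The ILP is practical only for catalogues whose largest complex is small
  (the `max_subunits = 8` default); real catalogues need the greedy
  solver.
* Confidence scores are ordinal, not probabilistic; combining them with
  external scores via $SPE$ is a heuristic with no calibration guarantee.
* The model treats catalogues as noise-free: a spurious complex inflates
  $|E'|$, and missing complexes cannot be compensated.
* When multiple optimal solutions exist, which one is returned depends on
  the back end; only the objective is canonical for exact solvers.
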