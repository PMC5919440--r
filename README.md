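# minppi

Protein complexes are sets of proteins that assemble into one molecular
machine. A complex is *supported* by a protein–protein interaction (PPI)
network when the subgraph induced by its members — using only interactions
whose two endpoints both belong to the complex — is connected. Curated
catalogues such as CYC2008 list hundreds of complexes, yet even the largest
interaction databases do not contain enough pairwise interactions to support
all of them. `minppi` answers the resulting question: **how many
interactions are missing, and which ones?**

Formally, given an undirected network `G = (V, E)` of known interactions and
a collection of complexes `C = {C_1, ..., C_m}` with `C_p ⊆ V`, the package
finds a minimum set `E'` of additional edges such that in `G' = (V, E ∪ E')`
every `C_p` induces a connected subgraph (`MinPPI`; the special case
`E = ∅` is `MinPPI0`, equivalent to the minimum topic-connected overlay /
uniform-cost network construction problem). `|E'|` is a lower bound on the
number of interactions missing from the database. The problem is NP-hard, so
the package offers:

* **An exact integer program** (`build_ilp()` / `solve_ilp()`). For each
  complex `C_p`, binary reachability variables `x_p_t_i_j` certify that
  members `i, j` are connected within `2^t` chosen edges; a doubling step
  `x_p_(t+1)_i_j ≤ x_p_t_i_j + Σ_k y_p_(t+1)_i_j_k` with relay variables
  `y ≤ (x_p_t_i_k + x_p_t_k_j)/2` composes two step-`t` paths, so
  `T_p = ⌈log2 |C_p|⌉` steps suffice. The objective minimizes `Σ e_ij`;
  known edges are fixed to 1 at zero cost. `write_lp()` emits the model in
  CPLEX-dialect LP format; `solve_ilp()` solves it exactly with either a
  bundled branch and bound (pure R, decomposing over blocks of complexes
  that share edges) or the HiGHS MILP solver via a python/scipy bridge.
* **A deterministic greedy approximation** (`greedy_min_ppi()`), within
  `O(log m)` of the optimum: starting from the known edges it repeatedly
  inserts the pair joining components in the largest number of complexes
  until every complex is connected. Insertion order yields rank-based
  confidence scores (first edge = most complexes bridged = highest score
  `N`, last edge score 1), and canonical tie-breaking makes the output
  invariant under any reordering of the input.
* **An exhaustive oracle** (`brute_force_min()`) for small instances, seeded
  synthetic catalogue generators (`generate_instance()`,
  `shuffle_instance()`), and evaluation utilities against gold-standard
  scored interaction sets (`confusion_metrics()`, `roc_auc()`,
  `combine_scores()`, `overlap_summary()`).

## Worked example

Three size-3 complexes chained by single shared proteins
(`C1 ∩ C2 = {p3}`, `C2 ∩ C3 = {p5}`), no known interactions:

```r
library(minppi)
inst <- build_instance(list(
  C1 = c("p1", "p2", "p3"),
  C2 = c("p3", "p4", "p5"),
  C3 = c("p5", "p6", "p7")))
sol <- greedy_min_ppi(inst)
print(sol)
#> MinPPI solution (greedy): 6 added edge(s)
#>     1. p1 -- p2 (confidence 6)
#>     2. p1 -- p3 (confidence 5)
#>     3. p3 -- p4 (confidence 4)
#>     4. p3 -- p5 (confidence 3)
#>     5. p5 -- p6 (confidence 2)
#>     6. p5 -- p7 (confidence 1)
```

Each complex has 3 members and needs 2 internal edges; the shared proteins
cannot save any edge because an edge helps a complex only if **both**
endpoints lie inside it. The optimum is therefore 6, which the exact solver
confirms:

```r
solve_ilp(build_ilp(inst))$objective
#> [1] 6
```

`write_solution()` serializes the ranked edge list as TSV
(`rank`, `protein_a`, `protein_b`, `confidence`, `supporting_complexes`).
Starting instead from three known interactions (`p1–p2`, `p3–p4`, `p5–p6`),
only the 3 remaining merges are needed:

```r
known <- data.frame(protein_a = c("p1", "p3", "p5"),
                    protein_b = c("p2", "p4", "p6"))
greedy_min_ppi(build_instance(inst$complexes, known))$objective
#> [1] 3
```

A command-line surface wrapping these functions (subcommands `gen`,
`solve-greedy`, `solve-ilp`, `write-lp`, `oracle`, `eval`) is installed at
`system.file("cli", "minppi.R", package = "minppi")`.

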