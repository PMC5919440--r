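# Exhaustive optimum for small instances, used as the exactness oracle in
# tests and available through solver = "oracle" on the command line.

# Blocks of the complex catalogue: connected components of the graph on
# dedup complexes in which two complexes are adjacent iff they share at
# least TWO proteins (equivalently, share a candidate pair). A candidate
# edge lies within two complexes only when they share both its endpoints,
# so every candidate pair belongs to exactly one block, per-complex
# feasibility depends only on its block's pairs, and the optimal objective
# is additive across blocks. Complexes that pairwise share at most one
# protein therefore fall into singleton blocks, whose optimum is the
# per-complex closed form (component count - 1).
complex_blocks <- function(idx) {
  parent <- seq_len(idx$nd)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (length(idx$pc_pair)) {
    for (ds in split(idx$pc_d, idx$pc_pair)) {
      if (length(ds) > 1L) {
        r <- find(ds[1L])
        for (d in ds[-1L]) {
          rd <- find(d)
          if (rd != r) parent[rd] <- r
        }
      }
    }
  }
  roots <- vapply(seq_len(idx$nd), find, integer(1L))
  split(seq_len(idx$nd), match(roots, unique(roots)))
}

# Feasibility of (known edges + subset of candidate pairs) over a set of
# dedup complexes, via per-complex union-find.
subset_feasible <- function(idx, pair_present, dset) {
  for (d in dset) {
    s <- idx$sizes[d]
    if (s < 2L) next
    rows <- which(idx$pc_d == d)
    lab <- seq_len(s)
    for (r in rows[pair_present[idx$pc_pair[rows]]]) {
      r1 <- lab[idx$pc_lu[r]]; r2 <- lab[idx$pc_lv[r]]
      if (r1 != r2) lab[lab == r2] <- r1
    }
    if (length(unique(lab)) > 1L) return(FALSE)
  }
  TRUE
}

#' Exact minimum augmentation by exhaustive search
#'
#' Finds a provably minimum set of additional edges by iterative deepening
#' over subset sizes 0, 1, 2, ... of the candidate pairs, independently
#' within each block of complexes chained by shared pairs (across which the
#' optimum is additive). Intended as a correctness oracle for small
#' instances; the search space grows combinatorially, so instances whose
#' candidate-pair count exceeds `pair_budget` are refused outright.
#'
#' @param instance A [build_instance()] object.
#' @param pair_budget Maximum number of candidate pairs accepted (default
#'   20); larger instances raise a `minppi_budget_error`.
#' @return A `min_ppi_solution` with a globally minimum objective. Edges are
#'   reported in canonical pair order; ranks are positional, not
#'   reliability-ordered.
#' @seealso [solve_ilp()] for the scalable exact solver, [greedy_min_ppi()]
#'   for the approximation.
#' @export
brute_force_min <- function(instance, pair_budget = 20L) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  t0 <- proc.time()[["elapsed"]]
  idx <- instance_index(instance)
  cand <- which(!idx$known_pair)
  if (length(cand) > pair_budget)
    stop_budget(sprintf(
      "instance has %d candidate pairs, exceeding pair_budget = %d",
      length(cand), pair_budget))

  base <- idx$known_pair
  chosen <- integer(0)
  for (dset in complex_blocks(idx)) {
    rows <- which(idx$pc_d %in% dset)
    comp_cand <- sort(intersect(cand, unique(idx$pc_pair[rows])))
    k <- 0L
    repeat {
      if (k > length(comp_cand))
        stop("internal error: no feasible subset exists")  # nocov
      found <- NULL
      if (k == 0L) {
        if (subset_feasible(idx, base, dset)) found <- integer(0)
      } else {
        sets <- utils::combn(comp_cand, k)
        for (ci in seq_len(ncol(sets))) {
          present <- base
          present[sets[, ci]] <- TRUE
          if (subset_feasible(idx, present, dset)) {
            found <- sets[, ci]
            break
          }
        }
      }
      if (!is.null(found)) {
        chosen <- c(chosen, found)
        break
      }
      k <- k + 1L
    }
  }
  chosen <- chosen[order(idx$lexrank[chosen])]
  new_solution(idx, idx$pairs_u[chosen], idx$pairs_v[chosen],
               method = "oracle",
               wall_time = proc.time()[["elapsed"]] - t0)
}
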