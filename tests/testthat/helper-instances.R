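# Shared fixtures, built in code.

# Three size-3 complexes over 7 proteins chained by single-protein overlaps
# (the canonical worked example: optimal augmentation has 6 edges).
fig1b_instance <- function() {
  build_instance(list(C1 = c("p1", "p2", "p3"),
                      C2 = c("p3", "p4", "p5"),
                      C3 = c("p5", "p6", "p7")))
}

edges_df <- function(...) {
  pairs <- list(...)
  data.frame(protein_a = vapply(pairs, `[[`, "", 1L),
             protein_b = vapply(pairs, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

rand_instance <- function(seed, protein_cap = 9, complex_cap = 5,
                          subunit_cap = 4) {
  generate_instance(synthetic_spec(protein_cap, complex_cap, subunit_cap,
                                   seed = seed))
}

# random instance plus `k` random known edges drawn from its candidate pairs
rand_instance_with_edges <- function(seed, k = 2, ...) {
  inst <- rand_instance(seed, ...)
  cp <- candidate_pairs(inst)
  if (nrow(cp) == 0L || k == 0L) return(inst)
  sel <- withr::with_seed(seed + 1000L, sample(nrow(cp), min(k, nrow(cp))))
  build_instance(inst$complexes, known_edges = cp[sel, , drop = FALSE],
                 proteins = inst$proteins)
}

# complexes chained by single shared proteins: pairwise intersections <= 1
near_disjoint_instance <- function(seed, m = 4, smin = 2, smax = 5) {
  withr::with_seed(seed, {
    sizes <- sample(smin:smax, m, replace = TRUE)
    complexes <- list()
    next_id <- 1L
    prev_last <- NULL
    for (i in seq_len(m)) {
      fresh <- sprintf("q%03d", seq(next_id, length.out = sizes[i] - 1L))
      next_id <- next_id + sizes[i] - 1L
      first <- if (is.null(prev_last) || stats::runif(1) < 0.5) {
        id <- sprintf("q%03d", next_id)
        next_id <- next_id + 1L
        id
      } else prev_last
      complexes[[i]] <- c(first, fresh)
      prev_last <- fresh[length(fresh)] %||% first
    }
    build_instance(complexes)
  })
}

solution_edges <- function(sol) {
  sol$added_edges[, c("protein_a", "protein_b"), drop = FALSE]
}

augmented_edges <- function(inst, sol) {
  rbind(inst$known_edges[, c("protein_a", "protein_b"), drop = FALSE],
        solution_edges(sol))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
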