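# Solution container shared by the greedy solver, the ILP solver and the
# brute-force oracle.

# edges_u/edges_v: integer protein indices in insertion order (greedy) or
# canonical pair order (ilp/oracle). supporting: list of character vectors of
# complex names containing both endpoints.
new_solution <- function(idx, edges_u, edges_v, method, wall_time = NA_real_) {
  N <- length(edges_u)
  supporting <- vector("list", N)
  if (N) {
    n <- idx$n
    ekey <- (as.numeric(edges_u) - 1) * n + as.numeric(edges_v)
    pkey <- (as.numeric(idx$pairs_u) - 1) * n + as.numeric(idx$pairs_v)
    pid <- match(ekey, pkey)
    for (i in seq_len(N)) {
      rows <- which(idx$pc_pair == pid[i])
      nm <- unlist(idx$names_by_dedup[idx$pc_d[rows]], use.names = FALSE)
      supporting[[i]] <- str_sort(nm)
    }
  }
  added <- data.frame(
    rank = seq_len(N),
    protein_a = idx$proteins[edges_u] %||% character(),
    protein_b = idx$proteins[edges_v] %||% character(),
    confidence = if (N) N - seq_len(N) + 1L else integer(0),
    stringsAsFactors = FALSE)
  structure(list(
    added_edges = added,
    supporting_complexes = supporting,
    objective = N,
    method = method,
    wall_time = wall_time
  ), class = "min_ppi_solution")
}

#' @export
print.min_ppi_solution <- function(x, ...) {
  cat(sprintf("MinPPI solution (%s): %d added edge(s)\n", x$method,
              x$objective))
  if (x$objective > 0L) {
    show <- utils::head(x$added_edges, 10L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %3d. %s -- %s (confidence %d)\n", show$rank[i],
                  show$protein_a[i], show$protein_b[i], show$confidence[i]))
    if (x$objective > 10L) cat(sprintf("  ... %d more\n", x$objective - 10L))
  }
  invisible(x)
}

#' Rank-based confidence scores of an augmentation solution
#'
#' The first interaction inserted by the greedy solver joins components in
#' the largest number of complexes and is therefore considered the most
#' reliable; confidence decreases with insertion rank. A solution with `N`
#' added edges scores its rank-`r` edge as `N - r + 1`, so scores are exactly
#' the integers `1..N` with the first edge holding the maximum.
#'
#' @param solution A `min_ppi_solution` (from [greedy_min_ppi()],
#'   [solve_ilp()] or [brute_force_min()]; only greedy ranks reflect
#'   reliability, see the respective help pages).
#' @return A scored edge set: data frame with columns `protein_a`,
#'   `protein_b`, `score`.
#' @export
assign_confidence <- function(solution) {
  stopifnot(inherits(solution, "min_ppi_solution"))
  out <- solution$added_edges[, c("protein_a", "protein_b"), drop = FALSE]
  out$score <- as.numeric(solution$added_edges$confidence)
  rownames(out) <- NULL
  out
}
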