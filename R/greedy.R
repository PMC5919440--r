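#' Greedy augmentation of a PPI network to support all complexes
#'
#' Starting from the known edges, repeatedly inserts the candidate pair
#' `{u, v}` that joins components in the largest number of complexes (the
#' largest decrease of the connectivity [potential()]), until every complex
#' induces a single connected component. Each inserted edge decreases the
#' potential by at least one, so the procedure always terminates with a
#' feasible solution; the number of inserted edges is within a factor
#' `O(log m)` of the optimum.
#'
#' Ties are broken deterministically: larger per-pair complex co-membership
#' count first, then bytewise-lexicographic pair order. The output (edge set
#' and insertion order) is therefore invariant under any permutation of the
#' complexes or of the members within a complex; see [shuffle_instance()].
#'
#' @param instance A [build_instance()] object.
#' @return A `min_ppi_solution`: added edges in insertion order with ranks,
#'   rank-based confidence scores (first edge highest; see
#'   [assign_confidence()]), per-edge supporting complex names, and the
#'   objective `|E'|`.
#' @examples
#' inst <- build_instance(list(C1 = c("p1", "p2", "p3"),
#'                             C2 = c("p3", "p4", "p5"),
#'                             C3 = c("p5", "p6", "p7")))
#' greedy_min_ppi(inst)$objective  # 6 edges for three chained 3-complexes
#' @export
greedy_min_ppi <- function(instance) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  t0 <- proc.time()[["elapsed"]]
  idx <- instance_index(instance)
  picked <- greedy_core(idx)
  new_solution(idx, idx$pairs_u[picked], idx$pairs_v[picked],
               method = "greedy",
               wall_time = proc.time()[["elapsed"]] - t0)
}

# Greedy engine on the structural index. `pre_pairs` marks pairs present
# before the run (defaults to the known edges); returns the picked pair ids
# in insertion order. Used by greedy_min_ppi(), the weighted-reduction
# solver, and the branch-and-bound upper bound.
greedy_core <- function(idx, pre_pairs = idx$known_pair, restrict = NULL) {
  roots <- roots_for_pairs(idx, pre_pairs)
  P <- idx$npairs
  mult_row <- idx$mult[idx$pc_d]
  usable <- !pre_pairs
  if (!is.null(restrict)) usable <- usable & restrict
  picked <- integer(0)
  repeat {
    ru <- roots[cbind(idx$pc_d, idx$pc_lu)]
    rv <- roots[cbind(idx$pc_d, idx$pc_lv)]
    act <- which(ru != rv)
    act <- act[usable[idx$pc_pair[act]]]
    if (!length(act)) break
    dec <- numeric(P)
    tmp <- rowsum(mult_row[act], idx$pc_pair[act])
    dec[as.integer(rownames(tmp))] <- tmp
    best <- max(dec)
    cand <- which(dec == best)
    if (length(cand) > 1L) {
      cm <- idx$comember[cand]
      cand <- cand[cm == max(cm)]
      if (length(cand) > 1L) cand <- cand[which.min(idx$lexrank[cand])]
    }
    rows <- act[idx$pc_pair[act] == cand]
    for (r in rows) {
      d <- idx$pc_d[r]
      r1 <- roots[d, idx$pc_lu[r]]
      r2 <- roots[d, idx$pc_lv[r]]
      if (r1 != r2) roots <- merge_roots(roots, d, r1, r2)
    }
    usable[cand] <- FALSE
    picked <- c(picked, cand)
  }
  picked
}

#' Reduce a MinPPI instance to cost-weighted network construction
#'
#' MinPPI with known edges reduces to the network construction problem (find
#' a minimum-cost edge set making every complex connected) by pricing known
#' edges at a symbolic cost tier \eqn{\epsilon} that is cheaper than any
#' count of unit edges, and all other pairs at unit cost. Costs are compared
#' lexicographically (unit-cost total first, \eqn{\epsilon}-count second)
#' rather than through a tiny floating-point constant, which would underflow
#' for realistic protein counts.
#'
#' @param instance A [build_instance()] object.
#' @return An object of class `min_ppi_weighted` with the protein universe,
#'   the complex catalogue, `eps_edges` (the known edges, at cost
#'   \eqn{\epsilon}) and the implicit unit tier over all remaining pairs.
#' @seealso [greedy_network_construction()]
#' @export
reduce_to_network_construction <- function(instance) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  structure(list(
    proteins = instance$proteins,
    complexes = instance$complexes,
    eps_edges = instance$known_edges[, c("protein_a", "protein_b"),
                                     drop = FALSE],
    instance = instance
  ), class = "min_ppi_weighted")
}

#' @export
print.min_ppi_weighted <- function(x, ...) {
  cat(sprintf(paste0("network construction instance: %d proteins, ",
                     "%d complexes, %d epsilon-cost pair(s), unit cost ",
                     "elsewhere\n"),
              length(x$proteins), length(x$complexes), nrow(x$eps_edges)))
  invisible(x)
}

#' Greedy solver for the two-tier network construction reduction
#'
#' Solves a [reduce_to_network_construction()] instance greedily: the
#' \eqn{\epsilon}-tier edges are cheaper than any number of unit edges, so
#' they are all taken as free pre-insertions; unit edges are then inserted
#' by maximal potential decrease exactly as in [greedy_min_ppi()]. The added
#' unit-edge set (and its order) coincides with what [greedy_min_ppi()]
#' returns on the source instance.
#'
#' @param winstance A `min_ppi_weighted` object.
#' @return A `min_ppi_solution` over the unit-cost edges.
#' @export
greedy_network_construction <- function(winstance) {
  stopifnot(inherits(winstance, "min_ppi_weighted"))
  idx <- instance_index(winstance$instance)
  eps_present <- pair_presence(idx, winstance$eps_edges)
  picked <- greedy_core(idx, pre_pairs = eps_present)
  new_solution(idx, idx$pairs_u[picked], idx$pairs_v[picked],
               method = "greedy")
}
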