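#' Build a MinPPI problem instance
#'
#' Assembles a protein universe, a complex catalogue and a set of known
#' interactions into the instance object consumed by all solvers. The
#' connectivity requirement the solvers enforce is that every complex
#' `C_p` induces a connected subgraph of the augmented network, using only
#' edges with both endpoints inside `C_p`.
#'
#' Complexes are kept in presentation order with their given member order
#' (so instances can be permuted for determinism experiments); duplicate
#' complexes are retained, because they contribute to the per-pair
#' co-membership counts used in tie-breaking, but connectivity bookkeeping
#' deduplicates them internally. Known edges whose endpoints never share a
#' complex cannot affect any induced subgraph; they are accepted, recorded
#' in the validation report, and ignored by the solvers.
#'
#' @param complexes A list of character vectors, one per complex; a single
#'   character vector is treated as one complex. List names become complex
#'   names; unnamed complexes receive zero-padded positional names
#'   (`C01`, `C02`, ...).
#' @param known_edges Known interactions: a two-column data frame, matrix, or
#'   list of pairs (an optional third/`score` column is allowed and ignored
#'   beyond validation). Self-loops are rejected; pairs are stored in
#'   canonical (bytewise-sorted) order.
#' @param proteins Optional character vector of the protein universe. Members
#'   and edge endpoints are always included; supply this to add isolated
#'   proteins (e.g., a fixed-size universe from a generator).
#' @return An object of class `min_ppi_instance` with elements `proteins`
#'   (sorted universe), `complexes` (named list, presentation order),
#'   `known_edges` (canonical data frame), `n`, `m`, and `validation`
#'   (duplicate-complex groups, ignored edges, dropped repeated members).
#' @seealso [is_feasible()], [candidate_pairs()], [greedy_min_ppi()],
#'   [solve_ilp()], [brute_force_min()]
#' @examples
#' inst <- build_instance(list(C1 = c("a", "b", "c"), C2 = c("c", "d", "e")))
#' inst$n
#' is_feasible(inst)
#' @export
build_instance <- function(complexes, known_edges = NULL, proteins = NULL) {
  if (is.character(complexes)) complexes <- list(complexes)
  if (!is.list(complexes) || length(complexes) == 0L)
    stop("complexes must be a non-empty list of character vectors")
  complexes <- lapply(complexes, as.character)
  sizes0 <- lengths(complexes)
  if (any(sizes0 == 0L))
    stop(sprintf("complex %d is empty", which(sizes0 == 0L)[1L]))
  dropped <- integer(0)
  for (i in seq_along(complexes)) {
    if (anyDuplicated(complexes[[i]])) {
      dropped <- c(dropped, i)
      complexes[[i]] <- complexes[[i]][!duplicated(complexes[[i]])]
    }
  }
  nm <- names(complexes)
  m <- length(complexes)
  if (is.null(nm) || all(nm == "")) {
    nm <- sprintf("C%0*d", max(2L, nchar(m)), seq_len(m))
  } else if (anyDuplicated(nm)) {
    stop("complex names must be unique")
  } else if (any(nm == "")) {
    stop("either all or no complexes may be named")
  }
  names(complexes) <- nm

  edges <- canonicalize_edges(known_edges, "known_edges")

  universe <- str_sort(unique(c(unlist(complexes, use.names = FALSE),
                                edges$protein_a, edges$protein_b,
                                as.character(proteins %||% character()))))

  # duplicate complexes: groups of identical member sets
  ckey <- vapply(complexes, function(cc) paste(str_sort(cc), collapse = "\t"), "")
  dup_groups <- unname(split(seq_len(m), ckey))
  dup_groups <- dup_groups[lengths(dup_groups) > 1L]

  # known edges with endpoints never sharing a complex are inert
  in_complex <- rep(FALSE, nrow(edges))
  if (nrow(edges)) {
    for (cc in complexes) {
      in_complex <- in_complex |
        (edges$protein_a %in% cc & edges$protein_b %in% cc)
    }
  }

  structure(list(
    proteins = universe,
    complexes = complexes,
    known_edges = edges,
    n = length(universe),
    m = m,
    validation = list(
      duplicate_complexes = dup_groups,
      ignored_edges = edges[!in_complex, c("protein_a", "protein_b"),
                            drop = FALSE],
      repeated_members = dropped
    )
  ), class = "min_ppi_instance")
}

#' @export
print.min_ppi_instance <- function(x, ...) {
  cat(sprintf("MinPPI instance: %d proteins, %d complexes, %d known edges\n",
              x$n, x$m, nrow(x$known_edges)))
  sz <- lengths(x$complexes)
  cat(sprintf("  complex sizes: min %d / median %g / max %d\n",
              min(sz), stats::median(sz), max(sz)))
  if (length(x$validation$duplicate_complexes))
    cat(sprintf("  %d duplicate complex group(s) retained\n",
                length(x$validation$duplicate_complexes)))
  if (nrow(x$validation$ignored_edges))
    cat(sprintf("  %d known edge(s) outside every complex (inert)\n",
                nrow(x$validation$ignored_edges)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Internal structural index.
#
# Everything downstream (state, greedy, solvers) works on this index:
#  - dedup:    deduplicated complexes as sorted integer member vectors
#  - dmap:     original complex -> dedup id; mult: duplicate multiplicity
#  - pairs_u/v: the candidate universe = all pairs co-occurring in a complex
#  - pc_*:     (pair, dedup complex, local positions) incidence table
#  - comember: per-pair co-membership count over ORIGINAL complexes
#  - known_pair: logical over pairs, TRUE if the pair is a known edge
#  - lexrank:  tie-break rank of pairs by (protein_a, protein_b), bytewise
instance_index <- function(inst) {
  prot <- inst$proteins
  n <- length(prot)
  mem <- lapply(inst$complexes, function(cc) sort(match(cc, prot)))
  ckey <- vapply(mem, paste, "", collapse = ",")
  first <- !duplicated(ckey)
  dedup <- mem[first]
  dmap <- match(ckey, ckey[first])
  nd <- length(dedup)
  mult <- tabulate(dmap, nd)
  names_by_dedup <- split(names(inst$complexes),
                          factor(dmap, levels = seq_len(nd)))
  sizes <- lengths(dedup)
  smax <- max(sizes)

  pd <- vector("list", nd); plu <- vector("list", nd); plv <- vector("list", nd)
  pgu <- vector("list", nd); pgv <- vector("list", nd)
  for (d in seq_len(nd)) {
    s <- sizes[d]
    if (s < 2L) next
    iu <- rep(seq_len(s - 1L), times = (s - 1L):1L)
    iv <- sequence((s - 1L):1L) + iu
    v <- dedup[[d]]
    pd[[d]] <- rep.int(d, length(iu)); plu[[d]] <- iu; plv[[d]] <- iv
    pgu[[d]] <- v[iu]; pgv[[d]] <- v[iv]
  }
  pd <- unlist(pd) %||% integer(0); plu <- unlist(plu) %||% integer(0)
  plv <- unlist(plv) %||% integer(0)
  pgu <- unlist(pgu) %||% integer(0); pgv <- unlist(pgv) %||% integer(0)

  pkey <- (as.numeric(pgu) - 1) * n + as.numeric(pgv)
  keep <- !duplicated(pkey)
  pair_of_row <- match(pkey, pkey[keep])
  pairs_u <- pgu[keep]; pairs_v <- pgv[keep]
  P <- length(pairs_u)

  comember <- integer(P)
  if (length(pd)) {
    tmp <- rowsum(mult[pd], pair_of_row)
    comember[as.integer(rownames(tmp))] <- as.integer(tmp)
  }

  known_pair <- logical(P)
  ke <- inst$known_edges
  if (nrow(ke)) {
    ka <- match(ke$protein_a, prot); kb <- match(ke$protein_b, prot)
    kk <- (as.numeric(pmin(ka, kb)) - 1) * n + as.numeric(pmax(ka, kb))
    hit <- match(kk, pkey[keep])
    known_pair[hit[!is.na(hit)]] <- TRUE
  }

  ord <- str_order(prot[pairs_u], prot[pairs_v])
  lexrank <- integer(P)
  lexrank[ord] <- seq_len(P)

  roots_init <- matrix(NA_integer_, nrow = nd, ncol = smax)
  for (d in seq_len(nd)) roots_init[d, seq_len(sizes[d])] <- seq_len(sizes[d])

  list(proteins = prot, n = n, dedup = dedup, dmap = dmap, mult = mult,
       names_by_dedup = names_by_dedup, sizes = sizes, smax = smax, nd = nd,
       pc_d = pd, pc_lu = plu, pc_lv = plv, pc_pair = pair_of_row,
       pairs_u = pairs_u, pairs_v = pairs_v, npairs = P,
       comember = comember, known_pair = known_pair, lexrank = lexrank,
       roots_init = roots_init)
}

# Merge the components labelled r1 and r2 of dedup complex d (in place-ish).
merge_roots <- function(roots, d, r1, r2) {
  row <- roots[d, ]
  row[!is.na(row) & row == r2] <- r1
  roots[d, ] <- row
  roots
}

# Root-label matrix for an arbitrary pair-presence vector.
roots_for_pairs <- function(idx, pair_present) {
  roots <- idx$roots_init
  rows <- which(pair_present[idx$pc_pair])
  for (r in rows) {
    d <- idx$pc_d[r]
    r1 <- roots[d, idx$pc_lu[r]]
    r2 <- roots[d, idx$pc_lv[r]]
    if (r1 != r2) roots <- merge_roots(roots, d, r1, r2)
  }
  roots
}

# Logical pair-presence vector for an arbitrary edge collection (edges
# outside the co-complexed pair universe are inert and dropped).
pair_presence <- function(idx, edges) {
  present <- logical(idx$npairs)
  ef <- canonicalize_edges(edges)
  if (!nrow(ef)) return(present)
  a <- match(ef$protein_a, idx$proteins); b <- match(ef$protein_b, idx$proteins)
  if (anyNA(a) || anyNA(b))
    stop("edge endpoints must belong to the instance's protein universe")
  n <- idx$n
  key <- (as.numeric(pmin(a, b)) - 1) * n + as.numeric(pmax(a, b))
  pkey <- (as.numeric(idx$pairs_u) - 1) * n + as.numeric(idx$pairs_v)
  hit <- match(key, pkey)
  present[hit[!is.na(hit)]] <- TRUE
  present
}

# Per-dedup-complex component counts from a root-label matrix.
component_counts <- function(idx, roots) {
  vapply(seq_len(idx$nd), function(d) {
    length(unique(roots[d, seq_len(idx$sizes[d])]))
  }, integer(1L))
}

# ---------------------------------------------------------------------------

#' Per-complex connected components under a given edge set
#'
#' Partitions each complex's members into the connected components of the
#' subgraph induced by that complex: only edges with both endpoints inside
#' the complex count, so an edge leaving the complex never connects anything
#' within it.
#'
#' @param instance A [build_instance()] object.
#' @param edge_set Edges to evaluate (any representation accepted by
#'   [build_instance()]); defaults to the instance's known edges.
#' @return An object of class `min_ppi_component_state`: a list with
#'   `components` (per original complex, a list of sorted character vectors),
#'   `counts` (named integer vector `c_p`), and `potential`
#'   (`sum(c_p - 1)`, zero iff the instance is feasible).
#' @examples
#' inst <- build_instance(list(C1 = c("a", "b", "c")))
#' component_state(inst, data.frame(protein_a = "a", protein_b = "b"))$counts
#' @export
component_state <- function(instance, edge_set = instance$known_edges) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  idx <- instance_index(instance)
  roots <- roots_for_pairs(idx, pair_presence(idx, edge_set))
  cnt_d <- component_counts(idx, roots)
  comps <- lapply(seq_along(instance$complexes), function(p) {
    d <- idx$dmap[p]
    lab <- roots[d, seq_len(idx$sizes[d])]
    members <- idx$proteins[idx$dedup[[d]]]
    unname(lapply(split(members, lab), str_sort))
  })
  names(comps) <- names(instance$complexes)
  counts <- cnt_d[idx$dmap]
  names(counts) <- names(instance$complexes)
  structure(list(components = comps, counts = counts,
                 potential = sum(counts - 1L)),
            class = "min_ppi_component_state")
}

#' @export
print.min_ppi_component_state <- function(x, ...) {
  cat(sprintf("component state: %d complexes, potential %d (%s)\n",
              length(x$counts), x$potential,
              if (x$potential == 0L) "feasible" else "infeasible"))
  invisible(x)
}

#' Does an edge set make every complex connected?
#'
#' @inheritParams component_state
#' @return `TRUE` iff every complex induces a single connected component
#'   (singleton complexes are vacuously connected).
#' @export
is_feasible <- function(instance, edge_set = instance$known_edges) {
  potential(instance, edge_set) == 0L
}

#' Connectivity potential of an edge set
#'
#' The potential is `sum over complexes of (components - 1)`: the total
#' number of component merges still needed. It is zero exactly when the
#' instance is feasible, and it is the progress measure the greedy solver
#' maximally decreases at each insertion.
#'
#' @inheritParams component_state
#' @return Non-negative integer.
#' @export
potential <- function(instance, edge_set = instance$known_edges) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  idx <- instance_index(instance)
  roots <- roots_for_pairs(idx, pair_presence(idx, edge_set))
  sum(idx$mult * (component_counts(idx, roots) - 1L))
}

#' Candidate edges for augmentation
#'
#' All unordered protein pairs that co-occur in at least one complex and are
#' not already known edges. An edge between proteins sharing no complex
#' changes no induced subgraph, so restricting both solvers to these pairs
#' preserves optimal objective values while shrinking the search space.
#'
#' @inheritParams component_state
#' @return Data frame with columns `protein_a`, `protein_b` (canonical pair
#'   order, sorted bytewise).
#' @export
candidate_pairs <- function(instance) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  idx <- instance_index(instance)
  sel <- which(!idx$known_pair)
  out <- data.frame(protein_a = idx$proteins[idx$pairs_u[sel]],
                    protein_b = idx$proteins[idx$pairs_v[sel]],
                    stringsAsFactors = FALSE)
  out <- out[str_order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
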