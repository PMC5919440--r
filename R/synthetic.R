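#' Parameters for synthetic complex-catalogue generation
#'
#' Describes a random-instance regime by its caps: universe size, maximum
#' number of complexes, and per-complex subunit range. The regimes used in
#' benchmarking are expressed directly in these terms, e.g.
#' `synthetic_spec(10, 20, 5)` (small), `synthetic_spec(100, 100, 4)`
#' (moderate), and `synthetic_spec(1600, 400, 5)` (the shuffling
#' experiment's shape).
#'
#' @param protein_cap Universe size: the instance carries exactly this many
#'   labelled proteins (some may end up in no complex).
#' @param complex_cap Maximum number of complexes; the actual count is drawn
#'   uniformly from `1:complex_cap`.
#' @param subunit_cap Maximum complex size.
#' @param min_subunits Minimum complex size (default 2; singletons impose no
#'   connectivity constraint).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `min_ppi_synspec`.
#' @export
synthetic_spec <- function(protein_cap, complex_cap, subunit_cap,
                           min_subunits = 2L, seed = 1L) {
  protein_cap <- as.integer(protein_cap)
  complex_cap <- as.integer(complex_cap)
  subunit_cap <- as.integer(subunit_cap)
  min_subunits <- as.integer(min_subunits)
  if (!(2L <= min_subunits && min_subunits <= subunit_cap &&
          subunit_cap <= protein_cap))
    stop("need 2 <= min_subunits <= subunit_cap <= protein_cap")
  if (complex_cap < 1L) stop("complex_cap must be >= 1")
  structure(list(protein_cap = protein_cap, complex_cap = complex_cap,
                 subunit_cap = subunit_cap, min_subunits = min_subunits,
                 seed = as.integer(seed)),
            class = "min_ppi_synspec")
}

#' @export
print.min_ppi_synspec <- function(x, ...) {
  cat(sprintf(paste0("synthetic regime: <=%d proteins, <=%d complexes, ",
                     "sizes %d..%d, seed %d\n"),
              x$protein_cap, x$complex_cap, x$min_subunits, x$subunit_cap,
              x$seed))
  invisible(x)
}

#' Generate a random problem instance
#'
#' Draws a complex catalogue under a [synthetic_spec()] regime: the number
#' of complexes is uniform on `1:complex_cap`, each complex size is uniform
#' on `min_subunits:subunit_cap`, and members are sampled uniformly without
#' replacement from a universe of `protein_cap` labelled proteins
#' (`P001`, `P002`, ...). The known edge set is empty (the empty-network
#' problem); add edges afterwards via [build_instance()] if needed.
#' Complexes are named `C001`, `C002`, ... in generation order; duplicate
#' complexes arising by chance are kept, mirroring real catalogues with
#' repeated subunit sets. Equal spec and seed give identical instances.
#'
#' @param spec A [synthetic_spec()].
#' @return A `min_ppi_instance` whose universe has exactly `protein_cap`
#'   proteins.
#' @examples
#' inst <- generate_instance(synthetic_spec(10, 20, 5, seed = 1))
#' inst$n
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "min_ppi_synspec"))
  with_seed(spec$seed, {
    prot <- sprintf("P%0*d", max(3L, nchar(spec$protein_cap)),
                    seq_len(spec$protein_cap))
    m <- sample.int(spec$complex_cap, 1L)
    sizes <- runif_int(m, spec$min_subunits, spec$subunit_cap)
    complexes <- lapply(sizes, function(s) sample(prot, s))
    names(complexes) <- sprintf("C%0*d", max(3L, nchar(m)), seq_len(m))
    inst <- build_instance(complexes, known_edges = NULL, proteins = prot)
    inst$spec <- spec
    inst
  })
}

#' Permute the presentation order of an instance
#'
#' Reorders the complexes and permutes the member listing inside each
#' complex. The instance is semantically identical (the same sets of
#' proteins, the same names travelling with their complexes); only the
#' presentation order differs. Solvers with canonical tie-breaking, such as
#' [greedy_min_ppi()], return identical solutions (same edges, same
#' insertion order) on the original and on any shuffle.
#'
#' @param instance A `min_ppi_instance`.
#' @param seed Integer seed for the permutation.
#' @return A `min_ppi_instance` over the same universe.
#' @export
shuffle_instance <- function(instance, seed = 1L) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  with_seed(seed, {
    perm <- sample.int(instance$m)
    complexes <- instance$complexes[perm]
    complexes <- lapply(complexes, function(cc) cc[sample.int(length(cc))])
    build_instance(complexes, known_edges = instance$known_edges,
                   proteins = instance$proteins)
  })
}
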