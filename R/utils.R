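# Internal helpers shared across modules.
#
# Protein identifiers are opaque strings compared bytewise (radix order), so
# every ordering here is locale-independent and runs are diffable.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Order/sort wrappers pinned to radix (C locale) collation.
str_order <- function(...) order(..., method = "radix")
str_sort <- function(x) sort(x, method = "radix")

# Bytewise pairwise comparison a > b for equal-length character vectors.
str_gt <- function(a, b) {
  u <- str_sort(unique(c(a, b)))
  match(a, u) > match(b, u)
}

# Coerce various edge representations to a data.frame with character columns
# protein_a, protein_b and an optional numeric score column.
as_edge_frame <- function(edges, what = "edges") {
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE)
  if (is.null(edges)) return(empty)
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.list(edges) && !is.data.frame(edges)) {
    if (length(edges) == 0L) return(empty)
    bad <- which(lengths(edges) != 2L)
    if (length(bad))
      stop(sprintf("%s: element %d is not a pair", what, bad[1L]))
    edges <- data.frame(
      protein_a = vapply(edges, function(e) as.character(e[[1L]]), ""),
      protein_b = vapply(edges, function(e) as.character(e[[2L]]), ""),
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stop(sprintf("%s must be a two-column data frame, matrix or list of pairs",
                 what))
  if (nrow(edges) == 0L) return(empty)
  out <- data.frame(protein_a = as.character(edges[[1L]]),
                    protein_b = as.character(edges[[2L]]),
                    stringsAsFactors = FALSE)
  if ("score" %in% names(edges)) out$score <- as.numeric(edges[["score"]])
  else if (ncol(edges) >= 3L && is.numeric(edges[[3L]]))
    out$score <- as.numeric(edges[[3L]])
  out
}

# Canonical form: endpoints swapped so protein_a < protein_b (bytewise),
# rows sorted, duplicates collapsed (keeping the maximum score if present).
canonicalize_edges <- function(edges, what = "edges") {
  ef <- as_edge_frame(edges, what)
  if (nrow(ef) == 0L) {
    ef$key <- character()
    return(ef)
  }
  loop <- ef$protein_a == ef$protein_b
  if (any(loop))
    stop(sprintf("%s: self-loop edge not allowed: (%s, %s)", what,
                 ef$protein_a[which(loop)[1L]], ef$protein_b[which(loop)[1L]]))
  swap <- str_gt(ef$protein_a, ef$protein_b)
  if (any(swap)) {
    tmp <- ef$protein_a[swap]
    ef$protein_a[swap] <- ef$protein_b[swap]
    ef$protein_b[swap] <- tmp
  }
  ef$key <- paste(ef$protein_a, ef$protein_b, sep = "\t")
  if (anyDuplicated(ef$key)) {
    if (!is.null(ef$score)) {
      # keep the best-scoring record of each duplicated pair
      ef <- ef[str_order(ef$key, -xtfrm(ef$score)), , drop = FALSE]
    }
    ef <- ef[!duplicated(ef$key), , drop = FALSE]
  }
  ef <- ef[str_order(ef$protein_a, ef$protein_b), , drop = FALSE]
  rownames(ef) <- NULL
  ef
}

# Evaluate code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Uniform integer draw on [lo, hi] (sample() mis-handles length-1 vectors).
runif_int <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

stop_resource <- function(msg, call = sys.call(-1L)) {
  stop(structure(class = c("minppi_resource_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_budget <- function(msg, call = sys.call(-1L)) {
  stop(structure(class = c("minppi_budget_error", "error", "condition"),
                 list(message = msg, call = call)))
}
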