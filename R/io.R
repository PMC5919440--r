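# Readers and writers for the plain-text complex and edge formats, and
# solution serialization. All output orderings are canonical so runs are
# diffable.

#' Read a complex catalogue
#'
#' Two dialects are supported. `"lines"` (the catalogue style of CYC2008
#' after trivial reshaping): one complex per line, members separated by tabs
#' or whitespace, with an optional leading complex-name column selected by
#' `names_in_first_column`. `"pairs"`: rows of `protein`, `complex-name`
#' that are grouped into complexes. Blank lines and `#` comments are
#' skipped. Single-member complexes are accepted with a warning (they
#' impose no connectivity constraint).
#'
#' @param source File path or connection.
#' @param dialect `"lines"` or `"pairs"`.
#' @param names_in_first_column For the lines dialect: the first field of
#'   each row is the complex name.
#' @return A named list of character vectors, ready for [build_instance()].
#' @export
read_complexes <- function(source, dialect = c("lines", "pairs"),
                           names_in_first_column = FALSE) {
  dialect <- match.arg(dialect)
  raw <- readLines(source, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no complexes found")
  fields <- strsplit(trimws(raw[keep]), "[\t ]+")
  if (dialect == "lines") {
    if (names_in_first_column) {
      bad <- which(lengths(fields) < 2L)
      if (length(bad))
        stop(sprintf("line %d: complex name without members", keep[bad[1L]]))
      complexes <- lapply(fields, `[`, -1L)
      names(complexes) <- vapply(fields, `[[`, "", 1L)
      if (anyDuplicated(names(complexes)))
        stop("duplicate complex names in catalogue")
    } else {
      complexes <- fields
    }
    if (any(lengths(complexes) == 1L))
      warning(sprintf("%d single-member complex(es): no constraint imposed",
                      sum(lengths(complexes) == 1L)))
  } else {
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
      stop(sprintf("line %d: expected 'protein<TAB>complex' row",
                   keep[bad[1L]]))
    prot <- vapply(fields, `[[`, "", 1L)
    cplx <- vapply(fields, `[[`, "", 2L)
    complexes <- lapply(split(prot, factor(cplx, levels = unique(cplx))),
                        unique)
  }
  complexes
}

#' Write a complex catalogue
#'
#' Lines dialect, one complex per line with a leading name column; an
#' optional `# spec: ...` provenance header records the generating regime
#' and is skipped by [read_complexes()].
#'
#' @param complexes Named list of character vectors (or a
#'   `min_ppi_instance`, whose catalogue is written).
#' @param sink File path or connection.
#' @param header Optional character vector of comment lines (written with a
#'   leading `# `).
#' @return Invisibly, the lines written.
#' @export
write_complexes <- function(complexes, sink, header = NULL) {
  if (inherits(complexes, "min_ppi_instance")) {
    inst <- complexes
    complexes <- inst$complexes
    if (!is.null(inst$spec) && is.null(header)) {
      s <- inst$spec
      header <- sprintf(paste0("spec: protein_cap=%d complex_cap=%d ",
                               "subunit_cap=%d min_subunits=%d seed=%d ",
                               "(uniform sizes, uniform membership)"),
                        s$protein_cap, s$complex_cap, s$subunit_cap,
                        s$min_subunits, s$seed)
    }
  }
  lines <- c(if (!is.null(header)) paste("#", header),
             vapply(seq_along(complexes), function(i) {
               paste(c(names(complexes)[i] %||% sprintf("C%d", i),
                       complexes[[i]]), collapse = "\t")
             }, ""))
  write_text(lines, sink)
  invisible(lines)
}

#' Read an edge list
#'
#' TSV with columns `protein_a`, `protein_b` and an optional numeric
#' `score`. A header row is auto-detected (by the `protein_a`/`protein_b`
#' names, or by a non-numeric third field). Pairs are canonicalized,
#' duplicate rows collapsed keeping the maximum score, self-loops rejected.
#'
#' @param source File path or connection.
#' @return A scored edge set data frame (`protein_a`, `protein_b`, and
#'   `score` when present).
#' @export
read_edges <- function(source) {
  raw <- readLines(source, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep))
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  # fall back to whitespace splitting for space-separated files
  if (any(lengths(fields) < 2L)) fields <- strsplit(trimws(raw[keep]), "[\t ]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("line %d: expected at least two columns", keep[bad[1L]]))
  first <- fields[[1L]]
  has_header <- identical(tolower(first[1:2]), c("protein_a", "protein_b")) ||
    (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L]))) &&
       tolower(first[3L]) == "score")
  if (has_header) {
    fields <- fields[-1L]
    keep <- keep[-1L]
  }
  if (!length(fields))
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  has_score <- any(lengths(fields) >= 3L)
  if (has_score) {
    sc_chr <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, "")
    sc <- suppressWarnings(as.numeric(sc_chr))
    bad <- which(!is.na(sc_chr) & is.na(sc))
    if (length(bad))
      stop(sprintf("line %d: non-numeric score '%s'", keep[bad[1L]],
                   sc_chr[bad[1L]]))
    ef <- data.frame(protein_a = a, protein_b = b, score = sc,
                     stringsAsFactors = FALSE)
  } else {
    ef <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  }
  out <- canonicalize_edges(ef, basename(if (is.character(source)) source else "edges"))
  out$key <- NULL
  rownames(out) <- NULL
  out
}

#' Write an edge list
#'
#' @param edges Edge set (canonicalized on write).
#' @param sink File path or connection.
#' @param header Write the `protein_a`/`protein_b`(/`score`) header row.
#' @return Invisibly, the lines written.
#' @export
write_edges <- function(edges, sink, header = TRUE) {
  ef <- canonicalize_edges(edges)
  has_score <- !is.null(ef$score)
  lines <- c(
    if (header) paste(c("protein_a", "protein_b", if (has_score) "score"),
                      collapse = "\t"),
    if (nrow(ef)) paste(ef$protein_a, ef$protein_b,
                        if (has_score) format(ef$score, trim = TRUE,
                                              scientific = FALSE),
                        sep = "\t"))
  write_text(lines, sink)
  invisible(lines)
}

#' Serialize an augmentation solution
#'
#' TSV with columns `rank`, `protein_a`, `protein_b`, `confidence`,
#' `supporting_complexes` (semicolon-joined, bytewise-sorted complex
#' names), one row per added edge in rank order, followed by summary footer
#' comments (`# objective:`, `# method:`, and the solve's `# wall_time_s:`
#' when recorded). Re-writing the same solution object gives identical
#' bytes. [format_solution()] returns the table and the objective/method
#' footer only (no wall time), so equal solutions from different runs
#' format identically — that is the form the permutation-invariance checks
#' compare.
#'
#' @param solution A `min_ppi_solution`.
#' @param sink File path or connection.
#' @param footer Include the summary footer (default TRUE).
#' @return Invisibly, the lines written.
#' @export
write_solution <- function(solution, sink, footer = TRUE) {
  lines <- format_solution(solution, footer = footer)
  if (footer && !is.na(solution$wall_time %||% NA_real_))
    lines <- c(lines, sprintf("# wall_time_s: %.3f", solution$wall_time))
  write_text(lines, sink)
  invisible(lines)
}

#' @rdname write_solution
#' @return `format_solution()`: the character vector of TSV lines (without
#'   wall time, so equal solutions format identically).
#' @export
format_solution <- function(solution, footer = TRUE) {
  stopifnot(inherits(solution, "min_ppi_solution"))
  ae <- solution$added_edges
  sup <- vapply(solution$supporting_complexes,
                function(s) paste(str_sort(s), collapse = ";"), "")
  c(paste(c("rank", "protein_a", "protein_b", "confidence",
            "supporting_complexes"), collapse = "\t"),
    if (nrow(ae)) paste(ae$rank, ae$protein_a, ae$protein_b, ae$confidence,
                        sup, sep = "\t"),
    if (footer) c(sprintf("# objective: %d", solution$objective),
                  sprintf("# method: %s", solution$method)))
}

#' Read back a serialized solution
#'
#' @param source File path or connection written by [write_solution()].
#' @return Data frame with the solution table (ranks, pairs, confidences,
#'   supporting complex names).
#' @export
read_solution <- function(source) {
  raw <- readLines(source, warn = FALSE)
  keep <- raw[!grepl("^\\s*(#|$)", raw)]
  fields <- strsplit(keep, "\t", fixed = TRUE)
  stopifnot(length(fields) >= 1L)
  fields <- fields[-1L]  # header
  data.frame(
    rank = as.integer(vapply(fields, `[[`, "", 1L)),
    protein_a = vapply(fields, `[[`, "", 2L),
    protein_b = vapply(fields, `[[`, "", 3L),
    confidence = as.integer(vapply(fields, `[[`, "", 4L)),
    supporting_complexes = vapply(fields, function(f)
      if (length(f) >= 5L) f[[5L]] else "", ""),
    stringsAsFactors = FALSE)
}

write_text <- function(lines, sink) {
  if (is.character(sink)) {
    con <- file(sink, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    writeLines(lines, sink, sep = "\n", useBytes = TRUE)
  }
}
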