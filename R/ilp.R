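#' Doubling horizon for a complex
#'
#' Number of doubling steps needed to certify connectivity of a complex of
#' the given size: reachability at step `t + 1` is composed from two step-`t`
#' reachabilities, so path length doubles per step and `ceiling(log2(size))`
#' steps suffice for any connected subgraph (a path between two members
#' never needs more than `size - 1` hops).
#'
#' @param size Complex size (number of distinct members), a positive integer
#'   (vectorized).
#' @return Non-negative integer(s); 0 for singletons, which emit no pair
#'   constraints.
#' @export
ilp_horizon <- function(size) {
  size <- as.integer(size)
  stopifnot(all(size >= 1L))
  as.integer(ceiling(log2(size)))
}

#' Build the exact integer program for a MinPPI instance
#'
#' Constructs the binary program whose optimum is the minimum number of
#' additional edges. Variables: `e_i_j` (one per candidate pair, the edge
#' indicators being minimized), `x_p_t_i_j` (members `i`, `j` of complex `p`
#' are connected within `2^t` hops of the chosen edges) and relay variables
#' `y_p_t_i_j_k` (`i` and `j` connected through `k` at step `t`). For each
#' complex `p` with horizon `T_p =` [ilp_horizon()]`(|C_p|)` and each member
#' pair `i < j`:
#' \itemize{
#'   \item `x_p_Tp_i_j = 1` (every pair must end up connected),
#'   \item `x_p_0_i_j <= e_i_j` (step 0 is the edge itself),
#'   \item `x_p_(t+1)_i_j <= x_p_t_i_j + sum_k y_p_(t+1)_i_j_k`,
#'   \item `y_p_(t+1)_i_j_k <= (x_p_t_i_k + x_p_t_k_j) / 2`.
#' }
#' The objective minimizes the sum of `e_i_j` over candidate pairs. Known
#' edges are handled by fixing their `e_i_j` to 1 with zero objective
#' weight, so the program solves the general problem (known edges present),
#' not only the empty-network special case. Edge variables exist only for
#' pairs co-occurring in some complex, which preserves the optimum (see
#' [candidate_pairs()]).
#'
#' Model size grows as `sum_p |C_p|^3 * T_p`, driven by the largest complex
#' rather than by how many complexes there are; complexes beyond
#' `max_subunits` members are refused with a resource error unless
#' `allow_large = TRUE`, since memory use becomes prohibitive.
#'
#' @param instance A [build_instance()] object.
#' @param max_subunits Refuse complexes larger than this (default 8) unless
#'   overridden.
#' @param allow_large Set `TRUE` to bypass the subunit guardrail.
#' @param extra_steps Add this many steps to every horizon (the optimum is
#'   unchanged; exposed for validating that the `ceiling(log2)` horizon
#'   suffices).
#' @return An object of class `min_ppi_ilp`: variable table (`vars` with
#'   name, objective coefficient, bounds), constraint system in triplet form
#'   (`con_row`, `con_col`, `con_coef`, `rhs`, `sense`, `con_names`),
#'   per-complex `horizons`, and the decode metadata used by [solve_ilp()].
#' @seealso [write_lp()], [solve_ilp()]
#' @export
build_ilp <- function(instance, max_subunits = 8L, allow_large = FALSE,
                      extra_steps = 0L) {
  stopifnot(inherits(instance, "min_ppi_instance"))
  sz <- lengths(instance$complexes)
  if (max(sz) > max_subunits && !allow_large)
    stop_resource(sprintf(
      paste0("largest complex has %d subunits, above max_subunits = %d; ",
             "the model would be prohibitively large ",
             "(pass allow_large = TRUE to force)"),
      max(sz), max_subunits))
  idx <- instance_index(instance)
  P <- idx$npairs

  # edge variables first, in bytewise pair order
  ord <- order(idx$lexrank)            # var id -> pair id
  var_names <- sprintf("e_%d_%d", idx$pairs_u[ord], idx$pairs_v[ord])
  obj <- as.numeric(!idx$known_pair[ord])
  lb <- as.numeric(idx$known_pair[ord])
  ub <- rep(1, P)
  evar <- integer(P); evar[ord] <- seq_len(P)   # pair id -> var id

  env <- new.env(parent = emptyenv())
  env$vn <- as.list(var_names); env$obj <- as.list(obj)
  env$lb <- as.list(lb); env$ub <- as.list(ub)
  env$nv <- P
  env$rows <- vector("list", 0L); env$cols <- vector("list", 0L)
  env$coefs <- vector("list", 0L)
  env$rhs <- vector("list", 0L); env$sense <- vector("list", 0L)
  env$cn <- vector("list", 0L); env$nc <- 0L

  new_var <- function(name) {
    env$nv <- env$nv + 1L
    env$vn[[env$nv]] <- name
    env$obj[[env$nv]] <- 0
    env$lb[[env$nv]] <- 0
    env$ub[[env$nv]] <- 1
    env$nv
  }
  add_con <- function(name, cols, coefs, sense, rhs) {
    env$nc <- env$nc + 1L
    env$rows[[env$nc]] <- rep.int(env$nc, length(cols))
    env$cols[[env$nc]] <- cols
    env$coefs[[env$nc]] <- coefs
    env$rhs[[env$nc]] <- rhs
    env$sense[[env$nc]] <- sense
    env$cn[[env$nc]] <- name
  }

  horizons <- integer(instance$m)
  for (p in seq_len(instance$m)) {
    d <- idx$dmap[p]
    v <- idx$dedup[[d]]
    s <- idx$sizes[d]
    horizons[p] <- if (s >= 2L) ilp_horizon(s) + as.integer(extra_steps) else 0L
    if (s < 2L) next
    Tp <- horizons[p]
    rows_d <- which(idx$pc_d == d)
    lu <- idx$pc_lu[rows_d]; lv <- idx$pc_lv[rows_d]
    pid <- idx$pc_pair[rows_d]
    Q <- length(rows_d)
    qof <- matrix(0L, s, s)                 # local pair lookup
    qof[cbind(lu, lv)] <- seq_len(Q)
    qof[cbind(lv, lu)] <- seq_len(Q)

    xid <- matrix(0L, Q, Tp + 1L)
    for (t in 0:Tp) for (q in seq_len(Q))
      xid[q, t + 1L] <- new_var(sprintf("x_%d_%d_%d_%d", p, t,
                                        v[lu[q]], v[lv[q]]))
    yid <- if (Tp > 0L && s > 2L) array(0L, c(Q, s, Tp)) else NULL
    if (!is.null(yid)) {
      for (t in seq_len(Tp)) for (q in seq_len(Q))
        for (k in seq_len(s)[-c(lu[q], lv[q])])
          yid[q, k, t] <- new_var(sprintf("y_%d_%d_%d_%d_%d", p, t,
                                          v[lu[q]], v[lv[q]], v[k]))
    }

    for (q in seq_len(Q)) {
      gi <- v[lu[q]]; gj <- v[lv[q]]
      add_con(sprintf("top_%d_%d_%d", p, gi, gj),
              xid[q, Tp + 1L], 1, "=", 1)
      add_con(sprintf("base_%d_%d_%d", p, gi, gj),
              c(xid[q, 1L], evar[pid[q]]), c(1, -1), "<=", 0)
      for (t in 0:(Tp - 1L)) {
        ks <- seq_len(s)[-c(lu[q], lv[q])]
        ycols <- if (length(ks)) yid[q, ks, t + 1L] else integer(0)
        add_con(sprintf("step_%d_%d_%d_%d", p, t + 1L, gi, gj),
                c(xid[q, t + 2L], xid[q, t + 1L], ycols),
                c(1, -1, rep(-1, length(ycols))), "<=", 0)
        for (k in ks) {
          add_con(sprintf("relay_%d_%d_%d_%d_%d", p, t + 1L, gi, gj, v[k]),
                  c(yid[q, k, t + 1L], xid[qof[lu[q], k], t + 1L],
                    xid[qof[k, lv[q]], t + 1L]),
                  c(1, -0.5, -0.5), "<=", 0)
        }
      }
    }
  }

  vars <- data.frame(name = unlist(env$vn),
                     obj = unlist(env$obj),
                     lb = unlist(env$lb),
                     ub = unlist(env$ub),
                     stringsAsFactors = FALSE)
  structure(list(
    vars = vars,
    con_row = unlist(env$rows) %||% integer(0),
    con_col = unlist(env$cols) %||% integer(0),
    con_coef = unlist(env$coefs) %||% numeric(0),
    rhs = unlist(env$rhs) %||% numeric(0),
    sense = unlist(env$sense) %||% character(0),
    con_names = unlist(env$cn) %||% character(0),
    n_con = env$nc,
    horizons = stats::setNames(horizons, names(instance$complexes)),
    evar = evar,
    pair_of_evar = ord,
    instance = instance,
    idx = idx
  ), class = "min_ppi_ilp")
}

#' @export
print.min_ppi_ilp <- function(x, ...) {
  cat(sprintf("MinPPI integer program: %d binary variables, %d constraints\n",
              nrow(x$vars), x$n_con))
  cat(sprintf("  %d edge variables (%d fixed known), horizons up to %d\n",
              length(x$evar), sum(x$vars$lb[seq_along(x$evar)] == 1),
              max(x$horizons)))
  invisible(x)
}

# wrap a vector of tokens into indented lines of bounded width
wrap_tokens <- function(tokens, width = 72L, indent = " ") {
  lines <- character(0)
  cur <- indent
  for (tok in tokens) {
    if (nchar(cur) > nchar(indent) && nchar(cur) + 1L + nchar(tok) > width) {
      lines <- c(lines, cur)
      cur <- indent
    }
    cur <- if (nchar(cur) > nchar(indent)) paste(cur, tok) else paste0(cur, tok)
  }
  c(lines, cur)
}

format_coef <- function(coef) {
  ifelse(coef == 1, "", ifelse(coef == -1, "", format(abs(coef))))
}

#' Serialize an integer program in CPLEX-dialect LP format
#'
#' Writes the model of [build_ilp()] as an LP-format text file accepted by
#' CPLEX and other MILP solvers: a `Minimize` section, the constraint rows,
#' a `Bounds` section fixing the known-edge variables, and a `Binary`
#' section listing every variable. Variable naming and emission order are
#' deterministic, so serializing the same model twice yields identical
#' bytes.
#'
#' @param model A `min_ppi_ilp` object.
#' @param sink A file path or writable connection.
#' @return Invisibly, the character vector of lines written.
#' @export
write_lp <- function(model, sink) {
  stopifnot(inherits(model, "min_ppi_ilp"))
  vn <- model$vars$name
  lines <- c("\\ MinPPI binary program (doubling connectivity encoding)",
             "Minimize")
  ov <- which(model$vars$obj != 0)
  obj_tokens <- if (length(ov)) {
    c(vn[ov[1L]], as.vector(rbind("+", vn[ov[-1L]])))
  } else "0"
  ot <- wrap_tokens(c("obj:", obj_tokens))
  lines <- c(lines, ot, "Subject To")

  split_rows <- split(seq_along(model$con_row), model$con_row)
  for (ci in seq_len(model$n_con)) {
    ix <- split_rows[[ci]]
    cols <- model$con_col[ix]
    coefs <- model$con_coef[ix]
    tokens <- character(0)
    for (k in seq_along(cols)) {
      sgn <- if (coefs[k] < 0) "-" else "+"
      mag <- abs(coefs[k])
      term <- if (mag == 1) vn[cols[k]] else paste(format(mag), vn[cols[k]])
      tokens <- c(tokens,
                  if (k == 1L && sgn == "+") term else c(sgn, term))
    }
    tokens <- c(tokens, model$sense[ci], format(model$rhs[ci]))
    lines <- c(lines, wrap_tokens(c(paste0(model$con_names[ci], ":"), tokens)))
  }

  fixed <- which(model$vars$lb == model$vars$ub)
  if (length(fixed)) {
    lines <- c(lines, "Bounds",
               sprintf(" %s = %s", vn[fixed], format(model$vars$lb[fixed])))
  }
  lines <- c(lines, "Binary", wrap_tokens(vn), "End")

  if (is.character(sink)) {
    con <- file(sink, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    writeLines(lines, sink, sep = "\n", useBytes = TRUE)
  }
  invisible(lines)
}

# ---------------------------------------------------------------------------
# Solver backends

.minppi_env <- new.env(parent = emptyenv())

# Locate a python interpreter with scipy >= 1.9 (HiGHS MILP interface).
find_python <- function(python = NULL) {
  if (!is.null(python)) return(python)
  cached <- .minppi_env$python
  if (!is.null(cached)) return(if (nzchar(cached)) cached else NULL)
  path <- Sys.which("python")
  ok <- nzchar(path) &&
    system2(path, c("-c", shQuote("from scipy.optimize import milp")),
            stdout = FALSE, stderr = FALSE) == 0L
  .minppi_env$python <- if (ok) unname(path) else ""
  if (ok) unname(path) else NULL
}

solve_backend_highs <- function(model, python, time_limit) {
  script <- system.file("python", "solve_milp.py", package = "minppi",
                        mustWork = TRUE)
  spec <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(spec, out)))
  payload <- list(
    nvar = nrow(model$vars),
    ncon = model$n_con,
    obj = model$vars$obj,
    lb = model$vars$lb,
    ub = model$vars$ub,
    row = model$con_row - 1L,
    col = model$con_col - 1L,
    coef = model$con_coef,
    rhs = model$rhs,
    sense = model$sense,
    time_limit = time_limit %||% -1
  )
  jsonlite::write_json(payload, spec, auto_unbox = TRUE, digits = NA)
  status <- system2(python, c(shQuote(script), shQuote(spec), shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(out))
    stop(sprintf("MILP back end failed: %s",
                 paste(status, collapse = "\n")))
  res <- jsonlite::read_json(out, simplifyVector = TRUE)
  if (res$status == 1L)
    stop_resource("MILP back end hit its time/iteration limit")
  if (res$status != 0L)
    stop(sprintf(paste0("internal error: MILP back end reported status %d ",
                        "(%s); the model is feasible by construction"),
                 res$status, res$message %||% "unknown"))
  round(res$x)
}

# ---------------------------------------------------------------------------
# Pure-R exact branch and bound on the edge variables.
#
# The auxiliary reachability variables of the model are uniquely implied by
# the edge variables (the constraints admit an assignment iff every complex
# is connected under the chosen edges, by correctness of the doubling
# encoding), so exact search over edge variables with per-complex
# connectivity checking solves the binary program to global optimality.
# Work decomposes across blocks of complexes chained by shared pairs
# (complex_blocks()), over which the optimum is additive.

comp_lower_bound <- function(idx, roots, present, dset, comp_pairs,
                             comp_prot) {
  cnt <- vapply(dset, function(d) {
    length(unique(roots[d, seq_len(idx$sizes[d])]))
  }, integer(1L))
  b1 <- max(cnt - 1L)
  phi_w <- sum(idx$mult[dset] * (cnt - 1L))
  maxco <- max(idx$comember[comp_pairs])
  b2 <- as.integer(ceiling(phi_w / maxco))
  # union bound: all proteins of the component end up mutually connected
  # through intra-complex paths, so at least (#union components - 1) merges
  # remain
  lab <- seq_along(comp_prot)
  pos <- match(seq_len(idx$n), comp_prot)
  rows <- which(idx$pc_d %in% dset)
  for (r in rows[present[idx$pc_pair[rows]]]) {
    d <- idx$pc_d[r]
    a <- pos[idx$dedup[[d]][idx$pc_lu[r]]]
    b <- pos[idx$dedup[[d]][idx$pc_lv[r]]]
    ra <- lab[a]; rb <- lab[b]
    if (ra != rb) lab[lab == rb] <- ra
  }
  b3 <- length(unique(lab)) - 1L
  max(b1, b2, b3)
}

solve_backend_bb <- function(model, max_nodes) {
  idx <- model$idx
  greedy_picked <- greedy_core(idx)
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  chosen_all <- integer(0)

  dfs <- function(roots, present, depth_left, dset, comp_pairs, comp_prot) {
    env$nodes <- env$nodes + 1L
    if (env$nodes > max_nodes)
      stop_resource(sprintf(
        "branch-and-bound exceeded max_nodes = %d; use the MILP back end",
        max_nodes))
    cnt <- vapply(dset, function(d) {
      length(unique(roots[d, seq_len(idx$sizes[d])]))
    }, integer(1L))
    if (all(cnt == 1L)) return(integer(0))
    if (depth_left == 0L) return(NULL)
    lb <- comp_lower_bound(idx, roots, present, dset, comp_pairs, comp_prot)
    if (lb > depth_left) return(NULL)
    # branch on a disconnected complex with the fewest merging pairs: any
    # feasible completion must merge two of its current components
    best_d <- NULL; best_pairs <- NULL
    for (d in dset[cnt > 1L]) {
      rows <- which(idx$pc_d == d)
      mrg <- rows[roots[cbind(idx$pc_d[rows], idx$pc_lu[rows])] !=
                    roots[cbind(idx$pc_d[rows], idx$pc_lv[rows])]]
      prs <- unique(idx$pc_pair[mrg])
      prs <- prs[!present[prs] & !idx$known_pair[prs]]
      if (is.null(best_pairs) || length(prs) < length(best_pairs)) {
        best_d <- d; best_pairs <- prs
      }
    }
    for (pr in best_pairs[order(idx$lexrank[best_pairs])]) {
      roots2 <- roots
      rows <- which(idx$pc_pair == pr)
      for (r in rows) {
        d <- idx$pc_d[r]
        r1 <- roots2[d, idx$pc_lu[r]]
        r2 <- roots2[d, idx$pc_lv[r]]
        if (r1 != r2) roots2 <- merge_roots(roots2, d, r1, r2)
      }
      present2 <- present
      present2[pr] <- TRUE
      sub <- dfs(roots2, present2, depth_left - 1L, dset, comp_pairs,
                 comp_prot)
      if (!is.null(sub)) return(c(pr, sub))
    }
    NULL
  }

  for (dset in complex_blocks(idx)) {
    rows <- which(idx$pc_d %in% dset)
    comp_pairs <- unique(idx$pc_pair[rows])
    cand <- comp_pairs[!idx$known_pair[comp_pairs]]
    inc <- greedy_picked[greedy_picked %in% cand]
    comp_prot <- sort(unique(unlist(idx$dedup[dset])))
    present0 <- idx$known_pair
    roots0 <- roots_for_pairs(idx, present0)
    ub <- length(inc)
    if (ub == 0L) next
    lb0 <- comp_lower_bound(idx, roots0, present0, dset, comp_pairs,
                            comp_prot)
    found <- NULL
    if (lb0 < ub) {
      for (depth in lb0:(ub - 1L)) {
        found <- dfs(roots0, present0, depth, dset, comp_pairs, comp_prot)
        if (!is.null(found)) break
      }
    }
    chosen_all <- c(chosen_all, if (is.null(found)) inc else found)
  }
  x <- numeric(nrow(model$vars))
  x[model$evar[c(chosen_all, which(idx$known_pair))]] <- 1
  x
}

#' Solve the MinPPI integer program exactly
#'
#' Computes a globally optimal solution of a [build_ilp()] model and decodes
#' the selected edge variables into an augmentation solution. Two exact
#' back ends are available: `"highs"` hands the full variable/constraint
#' system to the HiGHS MILP solver (through a bundled python/scipy bridge;
#' requires a `python` interpreter with scipy on the `PATH`), and `"bb"` is
#' a pure-R branch and bound that exploits the model's block structure (the
#' reachability variables are uniquely implied by the edge variables, so
#' exact search over edge variables with per-complex connectivity checking
#' solves the same program). The default `"auto"` runs the branch and bound
#' first and falls back to HiGHS if the node budget is exhausted. Both
#' back ends prove optimality; they may return different optimal edge sets
#' when several exist, but always the same objective.
#'
#' @param model A `min_ppi_ilp` object.
#' @param backend `"auto"`, `"highs"`, or `"bb"`.
#' @param max_nodes Node budget for the branch and bound; exceeding it
#'   raises a `minppi_resource_error` (mirroring the memory exhaustion an
#'   exact solver runs into on large complexes) rather than returning a
#'   non-optimal solution.
#' @param time_limit Optional time limit in seconds for the HiGHS back end;
#'   hitting it raises a `minppi_resource_error`.
#' @param python Optional path to a python interpreter (defaults to the
#'   first `python` on the `PATH` that can import scipy).
#' @return A `min_ppi_solution` with the minimum objective. Edges are
#'   reported in canonical pair order; ranks are positional and carry no
#'   reliability meaning (reliability ranks are a greedy concept).
#' @examples
#' inst <- build_instance(list(C1 = c("a", "b", "c", "d")))
#' sol <- solve_ilp(build_ilp(inst), backend = "bb")
#' sol$objective  # 3: a spanning tree of the single complex
#' @export
solve_ilp <- function(model, backend = c("auto", "highs", "bb"),
                      max_nodes = 5e5, time_limit = NULL, python = NULL) {
  stopifnot(inherits(model, "min_ppi_ilp"))
  backend <- match.arg(backend)
  t0 <- proc.time()[["elapsed"]]
  idx <- model$idx
  if (nrow(model$vars) == 0L || all(model$vars$obj == 0)) {
    # no free edge variables: feasible as given, or only fixed known edges
    feas_x <- numeric(nrow(model$vars))
    feas_x[model$evar[idx$known_pair]] <- 1
    x <- feas_x
    backend <- "none"
  } else if (backend == "auto") {
    # portfolio: the block-decomposed branch and bound first (fast when
    # greedy is optimal or near-optimal per block), HiGHS on the full
    # system when the search budget runs out
    x <- tryCatch(solve_backend_bb(model, max_nodes),
                  minppi_resource_error = function(e) NULL)
    if (is.null(x)) {
      py <- find_python(python)
      if (is.null(py))
        stop_resource(paste0("branch and bound exceeded its node budget and ",
                             "no python interpreter with scipy is on PATH ",
                             "for the highs back end"))
      backend <- "highs"
      x <- solve_backend_highs(model, py, time_limit)
    } else backend <- "bb"
  } else if (backend == "highs") {
    py <- find_python(python)
    if (is.null(py))
      stop("the highs back end needs a python interpreter with scipy on PATH")
    x <- solve_backend_highs(model, py, time_limit)
  } else {
    x <- solve_backend_bb(model, max_nodes)
  }

  # pair id -> value
  val <- numeric(idx$npairs)
  val[model$pair_of_evar] <- x[seq_along(model$pair_of_evar)]
  added <- which(val > 0.5 & !idx$known_pair)
  present <- idx$known_pair
  present[added] <- TRUE
  roots <- roots_for_pairs(idx, present)
  if (any(component_counts(idx, roots) != 1L))
    stop("internal error: decoded ILP solution is infeasible")  # nocov
  added <- added[order(idx$lexrank[added])]
  sol <- new_solution(idx, idx$pairs_u[added], idx$pairs_v[added],
                      method = "ilp",
                      wall_time = proc.time()[["elapsed"]] - t0)
  sol$backend <- backend
  sol
}
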