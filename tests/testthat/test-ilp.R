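# minimal LP-format reader used to check the serialized model against the
# in-memory constraint system (independent of the writer's internals)
parse_lp <- function(lines) {
  txt <- paste(lines[!startsWith(lines, "\\")], collapse = " ")
  sec <- function(from, to) {
    m <- regmatches(txt, regexpr(sprintf("%s(.*?)%s", from, to), txt))
    sub(to, "", sub(from, "", m))
  }
  con_txt <- sec("Subject To", "Bounds|Binary")
  toks <- strsplit(trimws(con_txt), "\\s+")[[1L]]
  cons <- list()
  cur <- NULL
  for (tok in toks) {
    if (grepl(":$", tok)) {
      if (!is.null(cur)) cons[[length(cons) + 1L]] <- cur
      cur <- list(name = sub(":$", "", tok), vars = character(),
                  coefs = numeric(), sign = 1, pend = NA_real_,
                  sense = NA_character_, rhs = NA_real_)
    } else if (tok %in% c("+", "-")) {
      cur$sign <- if (tok == "-") -1 else 1
    } else if (tok %in% c("<=", "=", ">=")) {
      cur$sense <- tok
    } else if (grepl("^[0-9.]+$", tok)) {
      if (!is.na(cur$sense)) cur$rhs <- as.numeric(tok)
      else cur$pend <- as.numeric(tok)
    } else {
      co <- if (!is.na(cur$pend)) cur$pend else 1
      cur$vars <- c(cur$vars, tok)
      cur$coefs <- c(cur$coefs, cur$sign * co)
      cur$sign <- 1; cur$pend <- NA_real_
    }
  }
  if (!is.null(cur)) cons[[length(cons) + 1L]] <- cur
  bounds_txt <- if (grepl("Bounds", txt)) sec("Bounds", "Binary") else ""
  binary_txt <- sec("Binary", "End")
  list(constraints = cons,
       fixed = regmatches(bounds_txt,
                          gregexpr("[exy][_0-9]+(?= = 1)", bounds_txt,
                                   perl = TRUE))[[1L]],
       binary = strsplit(trimws(binary_txt), "\\s+")[[1L]])
}

test_that("doubling horizon is ceil(log2(size))", {
  expect_equal(ilp_horizon(c(1, 2, 3, 4, 5, 8, 9)), c(0L, 1L, 2L, 2L, 3L, 3L, 4L))
})

test_that("the smallest model forces the single pair edge", {
  inst <- build_instance(list(c("a", "b")))
  m <- build_ilp(inst)
  expect_equal(m$horizons[["C01"]], 1L)
  # one edge variable, one x pair at t = 0 and t = 1
  expect_equal(nrow(m$vars), 3L)
  expect_setequal(m$vars$name, c("e_1_2", "x_1_0_1_2", "x_1_1_1_2"))
  expect_equal(solve_ilp(m, backend = "bb")$objective, 1L)
  expect_equal(solve_ilp(m, backend = "highs")$objective, 1L)
})

test_that("variable and constraint counts follow the size closed forms", {
  for (s in c(3L, 4L, 5L)) {
    inst <- build_instance(list(letters[seq_len(s)]))
    m <- build_ilp(inst)
    Tp <- ilp_horizon(s)
    Q <- choose(s, 2L)
    expect_equal(nrow(m$vars), Q + Q * (Tp + 1L) + Q * (s - 2L) * Tp,
                 info = paste("size", s))
    expect_equal(m$n_con, Q + Q + Q * Tp + Q * (s - 2L) * Tp,
                 info = paste("size", s))
  }
})

test_that("LP serialization is byte-stable and faithful to the model", {
  inst <- build_instance(list(C1 = c("a", "b", "c"), C2 = c("b", "c", "d")),
                         edges_df(c("a", "b")))
  m <- build_ilp(inst)
  f1 <- tempfile(fileext = ".lp"); f2 <- tempfile(fileext = ".lp")
  write_lp(m, f1); write_lp(m, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  lines <- readLines(f1)
  expect_true(any(lines == "Minimize"))
  expect_true(any(lines == "Subject To"))
  expect_true(any(lines == "Binary"))
  expect_true(any(lines == "End"))

  parsed <- parse_lp(lines)
  expect_setequal(parsed$binary, m$vars$name)
  # the known edge is fixed to 1 in the Bounds section
  expect_true("e_1_2" %in% parsed$fixed)
  expect_equal(length(parsed$constraints), m$n_con)
  # rebuild each constraint row from the text and compare to the triplets
  for (ci in seq_along(parsed$constraints)) {
    pc <- parsed$constraints[[ci]]
    ix <- which(m$con_row == ci)
    want <- m$con_coef[ix]
    names(want) <- m$vars$name[m$con_col[ix]]
    got <- pc$coefs
    names(got) <- pc$vars
    expect_equal(got[order(names(got))], want[order(names(want))],
                 info = pc$name)
    expect_equal(pc$rhs, m$rhs[ci])
    expect_equal(pc$sense, m$sense[ci])
  }
})

test_that("exact solver reproduces hand-checked optima with both back ends", {
  one4 <- build_instance(list(c("a", "b", "c", "d")))
  fig <- fig1b_instance()
  feas <- build_instance(list(c("a", "b", "c")),
                         edges_df(c("a", "b"), c("b", "c")))
  for (be in c("bb", "highs")) {
    expect_equal(solve_ilp(build_ilp(one4), backend = be)$objective, 3L)
    expect_equal(solve_ilp(build_ilp(fig), backend = be)$objective, 6L)
    expect_equal(solve_ilp(build_ilp(feas), backend = be)$objective, 0L)
  }
  sol <- solve_ilp(build_ilp(fig))
  expect_true(is_feasible(fig, solution_edges(sol)))
})

test_that("both back ends match the exhaustive oracle on random instances", {
  for (seed in 1:12) {
    inst <- rand_instance_with_edges(seed, k = seed %% 3)
    opt <- brute_force_min(inst, pair_budget = 40)$objective
    m <- build_ilp(inst)
    expect_equal(solve_ilp(m, backend = "bb")$objective, opt,
                 info = paste("bb seed", seed))
    expect_equal(solve_ilp(m, backend = "highs")$objective, opt,
                 info = paste("highs seed", seed))
  }
})

test_that("one extra doubling step never changes the optimum", {
  for (seed in 1:6) {
    inst <- rand_instance(seed, 8, 4, 4)
    base <- solve_ilp(build_ilp(inst), backend = "highs")$objective
    more <- solve_ilp(build_ilp(inst, extra_steps = 1L),
                      backend = "highs")$objective
    expect_equal(more, base, info = paste("seed", seed))
  }
})

test_that("reachability variables respect the 2^t distance semantics", {
  inst <- fig1b_instance()
  m <- build_ilp(inst)
  py <- minppi:::find_python()
  expect_false(is.null(py))
  x <- minppi:::solve_backend_highs(m, py, NULL)
  names(x) <- m$vars$name
  chosen <- names(x)[x > 0.5 & startsWith(names(x), "e_")]
  adj <- lapply(strsplit(chosen, "_"), function(f) as.integer(f[2:3]))
  dist2 <- function(a, b, members) {
    # BFS over chosen edges restricted to one complex
    frontier <- a; seen <- a; d <- 0L
    while (!(b %in% seen)) {
      d <- d + 1L
      nxt <- integer(0)
      for (e in adj) {
        if (!all(e %in% members)) next
        if (e[1L] %in% frontier && !(e[2L] %in% seen)) nxt <- c(nxt, e[2L])
        if (e[2L] %in% frontier && !(e[1L] %in% seen)) nxt <- c(nxt, e[1L])
      }
      if (!length(nxt)) return(Inf)
      seen <- c(seen, nxt); frontier <- nxt
    }
    d
  }
  prot_index <- function(ids) match(ids, inst$proteins)
  xs <- grep("^x_", names(x), value = TRUE)
  for (v in xs[x[xs] > 0.5]) {
    f <- as.integer(strsplit(v, "_")[[1L]][-1L])  # p, t, i, j
    members <- prot_index(inst$complexes[[f[1L]]])
    expect_lte(dist2(f[3L], f[4L], members), 2^f[2L])
  }
})

test_that("oversized complexes are refused unless overridden", {
  big <- build_instance(list(letters[1:9]))
  expect_error(build_ilp(big), class = "minppi_resource_error")
  m <- build_ilp(big, allow_large = TRUE)
  expect_equal(solve_ilp(m, backend = "bb")$objective, 8L)
})

test_that("a tiny node budget raises a resource error, not a wrong answer", {
  # counting argument: the three complexes need 3 + 2 + 2 internal spanning
  # edges of which only (a,b) and (c,d) can be shared, so the optimum is 5,
  # strictly above every quick lower bound (union bound 4); the branch and
  # bound must therefore search, and a zero node budget must refuse
  inst <- build_instance(list(c("a", "b", "c", "d"), c("a", "b", "e"),
                              c("c", "d", "e")))
  expect_equal(brute_force_min(inst)$objective, 5L)
  expect_equal(solve_ilp(build_ilp(inst), backend = "bb")$objective, 5L)
  expect_equal(solve_ilp(build_ilp(inst), backend = "highs")$objective, 5L)
  expect_error(
    solve_ilp(build_ilp(inst), backend = "bb", max_nodes = 0L),
    class = "minppi_resource_error")
})
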