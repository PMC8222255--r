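chain3 <- function() build_olc_graph(c("ATG", "TGC", "GCA"), min_overlap = 2)

test_that("vertex-position encoding reproduces hand-evaluated energies", {
  g <- chain3()
  for (A in c(1, 2.5)) {
    q <- qubo_vertex_position(g, A = A)
    expect_equal(q$n_vars, 9L)
    ident <- encode_path(c("frag_1", "frag_2", "frag_3"), q, g)
    expect_equal(qubo_energy(q, ident), 0)
    # all-zero: each of 3 rows and 3 columns contributes A
    expect_equal(qubo_energy(q, rep(0, 9)), 6 * A)
    # order (a, c, b): non-edges a->c and c->b penalized once each
    swapped <- encode_path(c("frag_1", "frag_3", "frag_2"), q, g)
    expect_equal(qubo_energy(q, swapped), 2 * A)
  }
})

test_that("edge-indicator encoding reproduces hand-evaluated energies", {
  g <- chain3()
  for (A in c(1, 3)) {
    q <- qubo_edge_indicator(g, A = A)
    expect_equal(q$n_vars, 2L)
    expect_equal(qubo_energy(q, c(1, 1)), 2 * A)  # endpoint terms only
    expect_equal(qubo_energy(q, c(0, 0)), 6 * A)  # all six vertex terms
  }
  # out-degree 2: selecting both outgoing edges of a costs A*(1-2)^2 = A
  # from a's outgoing term; b and c have no outgoing edges (A each) and a
  # no incoming edge (A); their incoming terms are satisfied. Total 4A.
  branch <- toy_graph(3, rbind(c(1, 2), c(1, 3)))
  qb <- qubo_edge_indicator(branch, A = 1)
  expect_equal(qubo_energy(qb, c(1, 1)), 4)
  # cyclic input rejected
  cyc <- build_olc_graph(c("ATGC", "GCAT"), min_overlap = 2)
  expect_error(qubo_edge_indicator(cyc), "acyclic")
})

test_that("qubo_energy matches an independent double-loop evaluation", {
  withr::local_seed(5)
  for (trial in 1:10) {
    n <- sample(2:6, 1)
    M <- matrix(rnorm(n * n), n)
    Q <- (M + t(M)) / 2
    off <- rnorm(1)
    q <- olcanneal:::new_qubo(Q, off, A = 1, var_map = NULL, encoding = "test")
    x <- sample(c(0, 1), n, replace = TRUE)
    expect_equal(qubo_energy(q, x), energy_double_loop(Q, off, x))
  }
  g <- chain3()
  q <- qubo_vertex_position(g)
  expect_error(qubo_energy(q, rep(0, 4)), "dimension")
  expect_error(qubo_energy(q, rep(2, 9)), "binary")
})

test_that("QUBO and Ising energies agree on every configuration", {
  withr::local_seed(17)
  for (trial in 1:8) {
    n <- sample(2:10, 1)
    M <- matrix(rnorm(n * n), n)
    Q <- (M + t(M)) / 2
    q <- olcanneal:::new_qubo(Q, rnorm(1), A = 1, var_map = NULL,
                              encoding = "test")
    p <- qubo_to_ising(q)
    X <- all_states(n)
    eq <- apply(X, 1, function(x) qubo_energy(q, x))
    ei <- apply(X, 1, function(x) ising_energy(p, 2 * x - 1))
    expect_equal(ei, eq, tolerance = 1e-12)
    # round trip is the identity up to offset bookkeeping
    q2 <- ising_to_qubo(p)
    eq2 <- apply(X, 1, function(x) qubo_energy(q2, x))
    expect_equal(eq2, eq, tolerance = 1e-12)
  }
})

test_that("the spin-to-binary substitution maps +1 to 1 and -1 to 0", {
  # single-variable QUBO E = 3x: h = 3/2, offset 3/2
  q <- olcanneal:::new_qubo(matrix(3, 1, 1), 0, 1, NULL, "test")
  p <- qubo_to_ising(q)
  expect_equal(p$h, 1.5)
  expect_equal(p$offset, 1.5)
  expect_equal(ising_energy(p, 1), 3)    # sigma = +1  <->  x = 1
  expect_equal(ising_energy(p, -1), 0)   # sigma = -1  <->  x = 0
})

test_that("hardware rescaling bounds coefficients and keeps the argmin", {
  p <- ising_problem(h = c(2, -4))
  ps <- rescale_for_hardware(p)
  expect_equal(ps$h, c(0.5, -1))
  inrange <- ising_problem(h = c(0.3, -0.9))
  expect_identical(rescale_for_hardware(inrange), inrange)
  withr::local_seed(23)
  for (trial in 1:5) {
    n <- sample(2:8, 1)
    M <- matrix(rnorm(n * n, sd = 3), n)
    J <- (M + t(M)) / 2; diag(J) <- 0
    p <- ising_problem(rnorm(n, sd = 3), J)
    ps <- rescale_for_hardware(p)
    expect_lte(max(abs(ps$h), abs(ps$J)), 1)
    S <- 2 * all_states(n) - 1
    e1 <- apply(S, 1, function(s) ising_energy(p, s))
    e2 <- apply(S, 1, function(s) ising_energy(ps, s))
    expect_equal(which(e1 <= min(e1) + 1e-9), which(e2 <= min(e2) + 1e-9))
  }
})

test_that("penalty coefficient scales energies linearly, argmin unchanged", {
  g <- chain3()
  q1 <- qubo_vertex_position(g, A = 1)
  q5 <- qubo_vertex_position(g, A = 5)
  X <- all_states(9)
  e1 <- apply(X, 1, function(x) qubo_energy(q1, x))
  e5 <- apply(X, 1, function(x) qubo_energy(q5, x))
  expect_equal(e5, 5 * e1, tolerance = 1e-12)
})

test_that("QUBO and Ising file exports are well-formed", {
  g <- chain3()
  q <- qubo_edge_indicator(g)
  f <- withr::local_tempfile(fileext = ".qubo")
  write_qubo(q, f)
  lines <- readLines(f)
  expect_true(any(grepl("^p qubo 0 2 ", lines)))
  coo <- withr::local_tempfile(fileext = ".csv")
  write_qubo_coo(q, coo)
  df <- utils::read.csv(coo)
  # rebuild the energy of x = (1,1) from the triplets: all terms active
  expect_equal(sum(df$value) + q$offset, qubo_energy(q, c(1, 1)))
  js <- withr::local_tempfile(fileext = ".json")
  write_ising_json(qubo_to_ising(q), js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$n, 2)
  expect_length(obj$h, 2)
})
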