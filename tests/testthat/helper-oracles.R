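# Independent combinatorial oracles used to cross-check the QUBO route.
# These deliberately avoid the package's hamiltonian_paths() / decoders.

# olc_graph on n abstract vertices from a 2-column edge index matrix.
toy_graph <- function(n, edges) {
  labels <- paste0("v", seq_len(n))
  seqs <- rep("A", n)   # sequences unused by the graph-level machinery
  df <- if (length(edges) == 0) {
    data.frame(from = character(0), to = character(0), overlap = integer(0))
  } else {
    data.frame(from = labels[edges[, 1]], to = labels[edges[, 2]],
               overlap = 1L, stringsAsFactors = FALSE)
  }
  olcanneal:::new_olc_graph(labels, seqs, df)
}

# Adjacency matrix (0/1, no diagonal) -> edge index matrix.
adj_to_edges <- function(A) which(A == 1, arr.ind = TRUE)

# All labelled digraphs on n vertices as adjacency matrices (n small!).
all_digraphs <- function(n) {
  slots <- which(diag(n) == 0, arr.ind = TRUE)
  ne <- nrow(slots)
  lapply(0:(2^ne - 1), function(code) {
    A <- matrix(0L, n, n)
    bits <- as.integer(intToBits(code))[seq_len(ne)]
    A[slots[bits == 1L, , drop = FALSE]] <- 1L
    A
  })
}

# Permutation-enumeration Hamiltonian path existence check (no DFS reuse).
has_ham_path_perm <- function(A) {
  n <- nrow(A)
  if (n == 1) return(TRUE)
  perms <- perm_enum(seq_len(n))
  for (p in perms) {
    ok <- TRUE
    for (i in seq_len(n - 1)) if (A[p[i], p[i + 1]] == 0) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

perm_enum <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_enum(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Kahn acyclicity on an adjacency matrix.
is_dag_adj <- function(A) {
  n <- nrow(A)
  alive <- rep(TRUE, n)
  repeat {
    indeg <- colSums(A[alive, alive, drop = FALSE])
    src <- which(alive)[indeg == 0]
    if (length(src) == 0) break
    alive[src] <- FALSE
    if (!any(alive)) return(TRUE)
  }
  !any(alive)
}

# Minimum path cover of a DAG: N - maximum bipartite matching between
# out-copies and in-copies of the vertices.
min_path_cover <- function(A) {
  n <- nrow(A)
  edges <- adj_to_edges(A)
  if (nrow(edges) == 0) return(n)
  g <- igraph::make_bipartite_graph(
    types = rep(c(FALSE, TRUE), each = n),
    edges = as.vector(t(cbind(edges[, 1], n + edges[, 2]))))
  m <- igraph::max_bipartite_match(g)$matching_size
  n - m
}

# Seeded random DAG on n vertices: random permutation + upper-triangular
# coin flips, guaranteed at least one edge.
random_dag <- function(n, p = 0.4) {
  repeat {
    perm <- sample.int(n)
    A <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p) A[perm[i], perm[j]] <- 1L
    }
    if (sum(A) >= 1) return(A)
  }
}

random_digraph <- function(n, p = 0.4) {
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

# Double-loop QUBO energy evaluation, independent of qubo_energy().
energy_double_loop <- function(Q, offset, x) {
  e <- offset
  n <- length(x)
  for (i in seq_len(n)) for (j in seq_len(n)) e <- e + x[i] * Q[i, j] * x[j]
  e
}

# All 0/1 states of n bits as a matrix (rows = states).
all_states <- function(n) {
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, n:1, drop = FALSE]
}
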