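#' QUBO problems
#'
#' A `qubo_problem` stores the quadratic form `E(x) = x'Qx + offset` over
#' binary variables, with linear terms on the diagonal of the symmetric
#' matrix `Q` (so an off-diagonal pair coefficient `c` for `x_p x_q` is
#' stored as `Q[p,q] = Q[q,p] = c/2`). `var_map` maps each variable index to
#' its graph meaning: a (vertex, position) pair for the `vertex_position`
#' encoding or an edge for the `edge_indicator` encoding.
#'
#' @name qubo_problem
NULL

new_qubo <- function(Q, offset, A, var_map, encoding) {
  stopifnot(isSymmetric(unname(Q)))
  structure(list(Q = Q, offset = offset, A = A, var_map = var_map,
                 encoding = encoding, n_vars = nrow(Q)),
            class = "qubo_problem")
}

#' @export
print.qubo_problem <- function(x, ...) {
  cat(sprintf("<qubo_problem> %s encoding, %d variables, A = %g, offset = %g\n",
              x$encoding, x$n_vars, x$A, x$offset))
  invisible(x)
}

#' Vertex-position QUBO encoding of the Hamiltonian path problem
#'
#' Encodes a Hamiltonian path through the N-vertex graph with N^2 binary
#' variables `x[v, j]` ("the path visits vertex v at step j"). The energy is
#' a pure penalty with three terms, each weighted by `A > 0`: every vertex
#' must occupy exactly one step, every step must hold exactly one vertex, and
#' consecutive steps must not use a vertex pair that is not an edge. A valid
#' Hamiltonian path has energy exactly 0; any other assignment is positive.
#' Variables are indexed vertex-major: `index = (v-1)*N + j`.
#'
#' @param g an `olc_graph`.
#' @param A positive penalty coefficient (default 1; any positive value has
#'   the same minimizers).
#' @return A [qubo_problem].
#' @export
qubo_vertex_position <- function(g, A = 1) {
  stopifnot(inherits(g, "olc_graph"), A > 0)
  N <- g$N
  nv <- N * N
  Q <- matrix(0, nv, nv)
  offset <- 0
  idx <- function(v, j) (v - 1L) * N + j
  # row (vertex) and column (step) uniqueness: (1 - sum x)^2
  for (v in seq_len(N)) {
    vars <- idx(v, seq_len(N))
    offset <- offset + A
    Q[cbind(vars, vars)] <- Q[cbind(vars, vars)] - A
    for (a in seq_len(N - 1)) for (b in seq((a + 1), N)) {
      Q[vars[a], vars[b]] <- Q[vars[a], vars[b]] + A
      Q[vars[b], vars[a]] <- Q[vars[b], vars[a]] + A
    }
  }
  for (j in seq_len(N)) {
    vars <- idx(seq_len(N), j)
    offset <- offset + A
    Q[cbind(vars, vars)] <- Q[cbind(vars, vars)] - A
    for (a in seq_len(N - 1)) for (b in seq((a + 1), N)) {
      Q[vars[a], vars[b]] <- Q[vars[a], vars[b]] + A
      Q[vars[b], vars[a]] <- Q[vars[b], vars[a]] + A
    }
  }
  # adjacency penalty: ordered non-edge (u,v), u != v, at consecutive steps
  ek <- edge_key(g$edges$from, g$edges$to)
  for (u in seq_len(N)) for (v in seq_len(N)) {
    if (u == v) next
    if (edge_key(g$vertices[u], g$vertices[v]) %in% ek) next
    for (j in seq_len(N - 1)) {
      p <- idx(u, j); q <- idx(v, j + 1L)
      Q[p, q] <- Q[p, q] + A / 2
      Q[q, p] <- Q[q, p] + A / 2
    }
  }
  var_map <- data.frame(index = seq_len(nv),
                        vertex = rep(g$vertices, each = N),
                        position = rep(seq_len(N), times = N),
                        stringsAsFactors = FALSE)
  new_qubo(Q, offset, A, var_map, "vertex_position")
}

#' Edge-indicator QUBO encoding for acyclic graphs
#'
#' Encodes the path with one binary variable per edge ("this edge is on the
#' path"), M variables in total. For every vertex the penalty
#' `A*(1 - sum of selected outgoing)^2 + A*(1 - sum of selected incoming)^2`
#' asks for exactly one incoming and one outgoing path edge where possible.
#' A Hamiltonian path has energy exactly `2A` (the source has no incoming
#' edge and the sink no outgoing edge); more generally the ground energy of a
#' DAG is `2A` times its minimum path-cover size. Cyclic input is rejected:
#' the encoding is only sound on acyclic graphs, where selected edges with
#' unit degrees cannot close a cycle.
#'
#' @param g an acyclic `olc_graph` with at least one edge.
#' @param A positive penalty coefficient.
#' @return A [qubo_problem].
#' @export
qubo_edge_indicator <- function(g, A = 1) {
  stopifnot(inherits(g, "olc_graph"), A > 0)
  if (g$M < 1) stop("graph has no edges", call. = FALSE)
  if (!is_acyclic(g)$acyclic) {
    stop("edge-indicator encoding requires an acyclic graph", call. = FALSE)
  }
  M <- g$M
  Q <- matrix(0, M, M)
  offset <- 0
  add_group <- function(vars) {
    # contributes (1 - sum_{vars} x)^2, weighted by A
    offset <<- offset + A
    if (length(vars) == 0L) return()
    Q[cbind(vars, vars)] <<- Q[cbind(vars, vars)] - A
    if (length(vars) > 1L) {
      for (a in seq_len(length(vars) - 1)) for (b in seq(a + 1, length(vars))) {
        Q[vars[a], vars[b]] <<- Q[vars[a], vars[b]] + A
        Q[vars[b], vars[a]] <<- Q[vars[b], vars[a]] + A
      }
    }
  }
  for (v in g$vertices) {
    add_group(which(g$edges$from == v))
    add_group(which(g$edges$to == v))
  }
  var_map <- data.frame(index = seq_len(M), from = g$edges$from,
                        to = g$edges$to, stringsAsFactors = FALSE)
  new_qubo(Q, offset, A, var_map, "edge_indicator")
}

#' Evaluate a QUBO energy
#'
#' @param q a [qubo_problem].
#' @param x binary vector (0/1) of length `q$n_vars`.
#' @return `x' Q x + offset` as a scalar.
#' @export
qubo_energy <- function(q, x) {
  stopifnot(inherits(q, "qubo_problem"))
  if (length(x) != q$n_vars) stop("dimension mismatch", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("x must be binary", call. = FALSE)
  drop(crossprod(x, q$Q %*% x)) + q$offset
}

# Energies of many states at once; X is a (states x n_vars) 0/1 matrix.
qubo_energies <- function(q, X) {
  rowSums((X %*% q$Q) * X) + q$offset
}

#' Ising problems
#'
#' An `ising_problem` stores local fields `h`, a symmetric zero-diagonal
#' coupling matrix `J` and a constant `offset`; the energy of a spin
#' configuration `s` in \{-1,+1\}^n is
#' `sum_i h_i s_i + sum_{i<j} J_ij s_i s_j + offset`.
#'
#' @name ising_problem
NULL

new_ising <- function(h, J, offset, var_map = NULL) {
  stopifnot(isSymmetric(unname(J)), all(diag(J) == 0), length(h) == nrow(J))
  structure(list(h = as.numeric(h), J = J, offset = offset,
                 var_map = var_map, n_vars = length(h)),
            class = "ising_problem")
}

#' @rdname ising_problem
#' @param h numeric vector of local fields.
#' @param J symmetric coupling matrix with zero diagonal (each unordered pair
#'   counted once by its entry `J[i,j]`).
#' @param offset constant energy shift.
#' @param var_map optional variable-semantics table carried along.
#' @return An `ising_problem`.
#' @export
ising_problem <- function(h, J = matrix(0, length(h), length(h)), offset = 0,
                          var_map = NULL) {
  new_ising(h, J, offset, var_map)
}

#' @export
print.ising_problem <- function(x, ...) {
  cat(sprintf("<ising_problem> %d spins, offset = %g, max|h| = %g, max|J| = %g\n",
              x$n_vars, x$offset, max(abs(x$h), 0), max(abs(x$J), 0)))
  invisible(x)
}

#' Evaluate an Ising energy
#'
#' @param p an [ising_problem].
#' @param s spin vector over \{-1, +1\}.
#' @return Scalar energy.
#' @export
ising_energy <- function(p, s) {
  stopifnot(inherits(p, "ising_problem"))
  if (length(s) != p$n_vars) stop("dimension mismatch", call. = FALSE)
  if (!all(s %in% c(-1, 1))) stop("s must be +/-1 spins", call. = FALSE)
  sum(p$h * s) + 0.5 * drop(crossprod(s, p$J %*% s)) + p$offset
}

ising_energies <- function(p, S) {
  as.numeric(S %*% p$h) + 0.5 * rowSums((S %*% p$J) * S) + p$offset
}

#' Convert a QUBO problem to Ising form
#'
#' Applies the binary-to-spin substitution `x_i = (s_i + 1)/2`; for every
#' configuration the QUBO energy of `x` equals the Ising energy of `s`, with
#' constants absorbed into the offset.
#'
#' @param q a [qubo_problem].
#' @return An [ising_problem] carrying the same `var_map`.
#' @export
qubo_to_ising <- function(q) {
  stopifnot(inherits(q, "qubo_problem"))
  Q <- q$Q
  n <- nrow(Q)
  off_diag <- Q - diag(diag(Q), n, n)
  # E = sum_i Q_ii x_i + sum_{i<j} 2 Q_ij x_i x_j + c under x = (s+1)/2:
  # pair coefficient Q_ij/2, field Q_ii/2 + sum_{j!=i} Q_ij/2, and offset
  # c + sum_i Q_ii/2 + sum_{i<j} Q_ij/2.
  h <- diag(Q) / 2 + rowSums(off_diag) / 2
  J <- off_diag / 2
  offset <- q$offset + sum(diag(Q)) / 2 + sum(off_diag[upper.tri(off_diag)]) / 2
  new_ising(h, J, offset, var_map = q$var_map)
}

#' Convert an Ising problem to QUBO form
#'
#' Inverse substitution `s_i = 2 x_i - 1`; energies agree configuration by
#' configuration and the round trip is the identity up to offset bookkeeping.
#'
#' @param p an [ising_problem].
#' @param encoding tag to place on the resulting QUBO (default `"ising"`).
#' @return A [qubo_problem].
#' @export
ising_to_qubo <- function(p, encoding = "ising") {
  stopifnot(inherits(p, "ising_problem"))
  n <- p$n_vars
  Q <- 2 * p$J                           # pair coeff 4*J_ij -> Q_ij = 2 J_ij
  diag(Q) <- 2 * p$h - 2 * rowSums(p$J)
  offset <- p$offset - sum(p$h) + sum(p$J[upper.tri(p$J)])
  new_qubo(Q, offset, A = NA_real_, var_map = p$var_map, encoding = encoding)
}

#' Rescale an Ising problem into the hardware coefficient range
#'
#' Divides the whole energy uniformly by `max(|h|, |J|)` when that maximum
#' exceeds 1, so that every field and coupling lies in [-1, 1]. The argmin
#' set is unchanged.
#'
#' @param p an [ising_problem].
#' @return A rescaled [ising_problem] (unchanged if already in range).
#' @export
rescale_for_hardware <- function(p) {
  stopifnot(inherits(p, "ising_problem"))
  s <- max(abs(p$h), abs(p$J), 0)
  if (s <= 1) return(p)
  new_ising(p$h / s, p$J / s, p$offset / s, var_map = p$var_map)
}

spins_to_bits <- function(s) (s + 1) / 2
bits_to_spins <- function(x) 2 * x - 1

#' Write a QUBO in qbsolv-style text format
#'
#' Emits a `p qubo 0 <maxNodes> <nDiagonals> <nElements>` header followed by
#' one line per nonzero diagonal (`i i value`) and per nonzero coupler
#' (`i j 2*Q[i,j]`, upper triangle, 0-based indices), matching the
#' conventional qbsolv file semantics where the coupler line carries the full
#' pair coefficient.
#'
#' @param q a [qubo_problem].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qubo <- function(q, path) {
  stopifnot(inherits(q, "qubo_problem"))
  n <- q$n_vars
  d <- diag(q$Q)
  ut <- which(upper.tri(q$Q) & q$Q != 0, arr.ind = TRUE)
  lines <- c(sprintf("c offset %.10g", q$offset),
             sprintf("p qubo 0 %d %d %d", n, sum(d != 0), nrow(ut)),
             sprintf("%d %d %.10g", which(d != 0) - 1L, which(d != 0) - 1L,
                     d[d != 0]),
             if (nrow(ut) > 0)
               sprintf("%d %d %.10g", ut[, 1] - 1L, ut[, 2] - 1L,
                       2 * q$Q[ut]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a QUBO as COO triplets (CSV)
#'
#' Columns `i`, `j`, `value` with 0-based indices; the diagonal carries
#' linear terms and each off-diagonal pair appears once with its full
#' coefficient `2*Q[i,j]`.
#'
#' @param q a [qubo_problem].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qubo_coo <- function(q, path) {
  d <- diag(q$Q)
  ut <- which(upper.tri(q$Q) & q$Q != 0, arr.ind = TRUE)
  df <- rbind(
    data.frame(i = which(d != 0) - 1L, j = which(d != 0) - 1L,
               value = d[d != 0]),
    data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L, value = 2 * q$Q[ut]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an Ising problem as JSON
#'
#' Serializes `h`, the upper-triangle couplings, the offset and the variable
#' map.
#'
#' @param p an [ising_problem].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ising_json <- function(p, path) {
  ut <- which(upper.tri(p$J) & p$J != 0, arr.ind = TRUE)
  obj <- list(n = p$n_vars, h = p$h,
              J = data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                             value = p$J[ut]),
              offset = p$offset, var_map = p$var_map)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
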