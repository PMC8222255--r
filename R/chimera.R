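#' Chimera hardware topology
#'
#' Builds the standard Chimera graph `C_m`: an `m x m` grid of 8-qubit
#' complete-bipartite (K4,4) unit cells. Within a cell the four "vertical"
#' qubits couple to the four "horizontal" qubits; vertical-shore qubits also
#' couple to the like-positioned qubit in the cell below, horizontal-shore
#' qubits to the cell at the right. Qubit ids are 0-based:
#' `id = 8*(row*m + col) + k` with `k` in `0:3` the vertical shore and `4:7`
#' the horizontal shore. Every qubit has degree at most 6; `C_m` has `8 m^2`
#' qubits and `16 m^2 + 8 m (m-1)` couplers (2048 and 6016 for `m = 16`).
#'
#' @param m grid dimension (>= 1).
#' @return An object of class `chimera_graph` with `m`, `n_qubits`,
#'   `couplers` (2-column matrix of 0-based qubit ids) and `n_couplers`.
#' @export
chimera_graph <- function(m) {
  stopifnot_scalar_int(m, "m", min = 1L)
  qid <- function(row, col, k) 8L * (row * m + col) + k
  ii <- integer(0); jj <- integer(0)
  for (row in 0:(m - 1L)) for (col in 0:(m - 1L)) {
    for (a in 0:3) for (b in 4:7) {           # in-cell K4,4
      ii <- c(ii, qid(row, col, a)); jj <- c(jj, qid(row, col, b))
    }
    if (row < m - 1L) for (k in 0:3) {        # vertical inter-cell
      ii <- c(ii, qid(row, col, k)); jj <- c(jj, qid(row + 1L, col, k))
    }
    if (col < m - 1L) for (k in 4:7) {        # horizontal inter-cell
      ii <- c(ii, qid(row, col, k)); jj <- c(jj, qid(row, col + 1L, k))
    }
  }
  couplers <- cbind(pmin(ii, jj), pmax(ii, jj))
  structure(list(m = as.integer(m), n_qubits = as.integer(8 * m^2),
                 couplers = couplers, n_couplers = nrow(couplers)),
            class = "chimera_graph")
}

#' @export
print.chimera_graph <- function(x, ...) {
  cat(sprintf("<chimera_graph> C%d: %d qubits, %d couplers\n", x$m,
              x$n_qubits, x$n_couplers))
  invisible(x)
}

coupler_keys <- function(cg) paste(cg$couplers[, 1], cg$couplers[, 2])

has_coupler <- function(cg, a, b) {
  paste(pmin(a, b), pmax(a, b)) %in% coupler_keys(cg)
}

#' Deterministic clique minor embedding on a Chimera graph
#'
#' Embeds the complete graph on `n_logical` variables into `C_m` with the
#' triangular scheme: variable `v` (with group `g = v %/% 4`, offset
#' `o = v %% 4`) occupies the horizontal-shore qubit `o` of cells
#' `(g, 0..g)` and the vertical-shore qubit `o` of cells `(g..m'-1, g)`,
#' where `m' = ceiling(n/4)` is the sub-grid actually used. Each chain is
#' connected (the two segments meet inside cell `(g, g)`) and has length
#' `m' + 1`; any two chains meet in some cell through an in-cell coupler.
#' The capacity of `C_m` under this scheme is `4 m` logical variables.
#'
#' @param n_logical number of logical variables (clique size).
#' @param target a [chimera_graph()].
#' @param chain_strength positive ferromagnetic tie strength recorded on the
#'   embedding (used by [embed_ising()]).
#' @return An object of class `chimera_embedding`: list with `chains` (list
#'   of 0-based qubit-id vectors, one per logical variable),
#'   `chain_strength` and `m`.
#' @export
embed_clique <- function(n_logical, target, chain_strength = 1) {
  stopifnot(inherits(target, "chimera_graph"), chain_strength > 0)
  stopifnot_scalar_int(n_logical, "n_logical", min = 1L)
  m <- target$m
  if (n_logical > 4L * m) {
    stop(sprintf("clique capacity of C%d is %d logical variables (requested %d)",
                 m, 4L * m, n_logical), call. = FALSE)
  }
  qid <- function(row, col, k) 8L * (row * m + col) + k
  if (n_logical == 1L) {
    chains <- list(qid(0L, 0L, 0L))
  } else {
    mp <- as.integer(ceiling(n_logical / 4))
    chains <- lapply(seq_len(n_logical) - 1L, function(v) {
      g <- v %/% 4L; o <- v %% 4L
      horiz <- vapply(0:g, function(col) qid(g, col, 4L + o), integer(1))
      vert <- vapply(g:(mp - 1L), function(row) qid(row, g, o), integer(1))
      c(horiz, vert)
    })
  }
  structure(list(chains = chains, chain_strength = chain_strength, m = m),
            class = "chimera_embedding")
}

#' @export
print.chimera_embedding <- function(x, ...) {
  cat(sprintf("<chimera_embedding> %d chains (lengths %s), chain strength %g\n",
              length(x$chains),
              paste(range(lengths(x$chains)), collapse = "-"),
              x$chain_strength))
  invisible(x)
}

#' Apply a minor embedding to an Ising problem
#'
#' Produces the physical Ising problem over the union of chain qubits:
#' each logical field is spread evenly over its chain, each logical coupling
#' is spread evenly over the available physical couplers between the two
#' chains, and every intra-chain coupler receives the ferromagnetic tie
#' `-chain_strength`. By default the chain strength is
#' `2 * max(|J|)` of the logical problem so that chains dominate the logical
#' couplings.
#'
#' @param p the logical [ising_problem].
#' @param emb a [embed_clique()] embedding with at least `p$n_vars` chains.
#' @param target the [chimera_graph()] the embedding lives on.
#' @param chain_strength override of the embedding's chain strength;
#'   `NULL` uses `max(emb$chain_strength, 2 * max(abs(p$J)))`.
#' @return List with `problem` (the physical [ising_problem]), `qubits`
#'   (0-based physical ids in variable order) and `chain_strength`.
#' @export
embed_ising <- function(p, emb, target, chain_strength = NULL) {
  stopifnot(inherits(p, "ising_problem"), inherits(emb, "chimera_embedding"))
  if (length(emb$chains) < p$n_vars) {
    stop("embedding has fewer chains than logical variables", call. = FALSE)
  }
  chains <- emb$chains[seq_len(p$n_vars)]
  cs <- if (!is.null(chain_strength)) chain_strength else
    max(emb$chain_strength, 2 * max(abs(p$J), 0))
  qubits <- sort(unique(unlist(chains)))
  np <- length(qubits)
  qindex <- stats::setNames(seq_len(np), qubits)
  h_phys <- numeric(np)
  J_phys <- matrix(0, np, np)
  ck <- coupler_keys(target)
  pair_in_target <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% ck
  for (i in seq_along(chains)) {
    ci <- chains[[i]]
    h_phys[qindex[as.character(ci)]] <-
      h_phys[qindex[as.character(ci)]] + p$h[i] / length(ci)
    # ferromagnetic intra-chain ties on every target coupler inside the chain
    if (length(ci) > 1L) {
      prs <- utils::combn(ci, 2L)
      ok <- pair_in_target(prs[1, ], prs[2, ])
      for (e in which(ok)) {
        a <- qindex[as.character(prs[1, e])]
        b <- qindex[as.character(prs[2, e])]
        J_phys[a, b] <- J_phys[a, b] - cs
        J_phys[b, a] <- J_phys[a, b]
      }
    }
  }
  nz <- which(upper.tri(p$J) & p$J != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]
    grid <- expand.grid(a = chains[[i]], b = chains[[j]])
    ok <- pair_in_target(grid$a, grid$b)
    if (!any(ok)) {
      stop(sprintf("no physical coupler between chains %d and %d", i, j),
           call. = FALSE)
    }
    w <- p$J[i, j] / sum(ok)
    for (e in which(ok)) {
      a <- qindex[as.character(grid$a[e])]
      b <- qindex[as.character(grid$b[e])]
      J_phys[a, b] <- J_phys[a, b] + w
      J_phys[b, a] <- J_phys[a, b]
    }
  }
  vm <- data.frame(index = seq_len(np), qubit = qubits)
  list(problem = new_ising(h_phys, J_phys, 0, var_map = vm),
       qubits = qubits, chain_strength = cs)
}

#' Map physical samples back to logical variables
#'
#' A chain whose physical spins all agree contributes that value as the
#' logical spin; samples containing any broken chain (disagreeing spins) are
#' discarded and counted, not repaired.
#'
#' @param samples 0/1 matrix of physical states, columns in the order of
#'   `qubits`.
#' @param emb the [embed_clique()] embedding.
#' @param qubits 0-based physical ids naming the sample columns (as returned
#'   by [embed_ising()]).
#' @param n_logical number of logical variables to decode.
#' @return List with `samples` (0/1 matrix, one row per intact physical
#'   sample) and `n_broken` (discarded samples).
#' @export
unembed_samples <- function(samples, emb, qubits, n_logical) {
  samples <- as.matrix(samples)
  qindex <- stats::setNames(seq_along(qubits), qubits)
  chains <- emb$chains[seq_len(n_logical)]
  out <- matrix(NA_real_, nrow(samples), n_logical)
  intact <- rep(TRUE, nrow(samples))
  for (i in seq_along(chains)) {
    cols <- qindex[as.character(chains[[i]])]
    vals <- samples[, cols, drop = FALSE]
    agree <- apply(vals, 1, function(v) all(v == v[1]))
    intact <- intact & agree
    out[, i] <- vals[, 1]
  }
  list(samples = out[intact, , drop = FALSE], n_broken = sum(!intact))
}
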