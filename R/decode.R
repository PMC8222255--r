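#' Path solutions
#'
#' A `path_solution` is the decoded output of a solver sample: a vertex
#' order, a validity status (`"hamiltonian"`, `"disjoint_paths"` or
#' `"malformed"`), the sample's energy, and — for Hamiltonian paths — the
#' reconstructed sequence.
#'
#' @name path_solution
NULL

new_path_solution <- function(order, valid, energy, sequence = NULL, ...) {
  structure(list(order = order, valid = valid, energy = energy,
                 sequence = sequence, ...),
            class = "path_solution")
}

#' @export
print.path_solution <- function(x, ...) {
  cat(sprintf("<path_solution> %s, energy %.6g", x$valid, x$energy))
  if (!is.null(x$sequence)) cat(sprintf(", %d bp contig", nchar(x$sequence)))
  cat("\n")
  if (!is.null(x$order)) {
    cat("order:", paste(x$order, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Decode a vertex-position sample into a path
#'
#' Interprets the binary vector as the N x N visit matrix of the
#' vertex-position encoding. If any vertex-row or step-column does not sum to
#' exactly 1, or any consecutive step pair uses a non-edge, the sample is
#' `"malformed"`; otherwise the visit order is a Hamiltonian path.
#'
#' @param x binary vector of length `N^2`.
#' @param q the [qubo_problem] (encoding `vertex_position`).
#' @param g the source `olc_graph`.
#' @return A [path_solution].
#' @export
decode_vertex_position <- function(x, q, g) {
  stopifnot(inherits(q, "qubo_problem"), q$encoding == "vertex_position")
  N <- g$N
  if (length(x) != N * N) stop("dimension mismatch", call. = FALSE)
  energy <- qubo_energy(q, x)
  X <- matrix(x, nrow = N, byrow = TRUE)   # rows: vertices, cols: steps
  if (any(rowSums(X) != 1) || any(colSums(X) != 1)) {
    return(new_path_solution(NULL, "malformed", energy))
  }
  ord <- g$vertices[apply(X, 2, which.max)]
  ek <- edge_key(g$edges$from, g$edges$to)
  steps_ok <- if (N > 1) {
    all(edge_key(ord[-N], ord[-1]) %in% ek)
  } else TRUE
  if (!steps_ok) return(new_path_solution(ord, "malformed", energy))
  new_path_solution(ord, "hamiltonian", energy)
}

#' Decode an edge-indicator sample into a path
#'
#' The selected edges must give every vertex in- and out-degree at most 1
#' (otherwise `"malformed"`). On an acyclic graph such a selection is a set
#' of vertex-disjoint paths: a single path covering all vertices is
#' `"hamiltonian"`, anything else is `"disjoint_paths"` with the path-cover
#' size reported.
#'
#' @param x binary vector of length `M` in the QUBO's edge order.
#' @param q the [qubo_problem] (encoding `edge_indicator`).
#' @param g the source `olc_graph`.
#' @return A [path_solution]; for disjoint paths, field `n_paths` holds the
#'   path-cover size.
#' @export
decode_edge_indicator <- function(x, q, g) {
  stopifnot(inherits(q, "qubo_problem"), q$encoding == "edge_indicator")
  if (length(x) != q$n_vars) stop("dimension mismatch", call. = FALSE)
  energy <- qubo_energy(q, x)
  sel <- q$var_map[x == 1, , drop = FALSE]
  outdeg <- table(factor(sel$from, levels = g$vertices))
  indeg <- table(factor(sel$to, levels = g$vertices))
  if (any(outdeg > 1) || any(indeg > 1)) {
    return(new_path_solution(NULL, "malformed", energy))
  }
  nxt <- stats::setNames(sel$to, sel$from)
  starts <- g$vertices[indeg[g$vertices] == 0]
  n_paths <- length(starts)
  if (n_paths == 1L) {
    ord <- starts
    while (!is.na(nxt[ord[length(ord)]])) {
      ord <- c(ord, unname(nxt[ord[length(ord)]]))
    }
    if (length(ord) == g$N) {
      return(new_path_solution(ord, "hamiltonian", energy))
    }
  }
  new_path_solution(NULL, "disjoint_paths", energy, n_paths = n_paths)
}

#' Encode a Hamiltonian path as a binary sample
#'
#' Inverse of the decoders: produces the bit vector whose decoding recovers
#' the given vertex order, for either encoding.
#'
#' @param order vertex labels in path order.
#' @param q the target [qubo_problem].
#' @param g the source `olc_graph`.
#' @return Binary vector of length `q$n_vars`.
#' @export
encode_path <- function(order, q, g) {
  stopifnot(inherits(q, "qubo_problem"))
  if (q$encoding == "vertex_position") {
    N <- g$N
    stopifnot(length(order) == N)
    x <- numeric(N * N)
    v <- match(order, g$vertices)
    x[(v - 1L) * N + seq_len(N)] <- 1
    x
  } else {
    x <- numeric(q$n_vars)
    if (length(order) > 1) {
      keys <- edge_key(order[-length(order)], order[-1])
      idx <- match(keys, edge_key(q$var_map$from, q$var_map$to))
      if (anyNA(idx)) stop("order uses a non-edge", call. = FALSE)
      x[idx] <- 1
    }
    x
  }
}

#' Reconstruct the assembled sequence from a Hamiltonian path
#'
#' Left-to-right merge: the first vertex's string, then each next vertex's
#' string with its overlap-length prefix dropped (overlaps taken from the
#' graph's edges).
#'
#' @param path a [path_solution] with `valid == "hamiltonian"`, or a plain
#'   character vector of vertex labels.
#' @param g the `olc_graph`.
#' @return The merged nucleotide string.
#' @export
reconstruct_sequence <- function(path, g) {
  ord <- if (inherits(path, "path_solution")) {
    if (!identical(path$valid, "hamiltonian")) {
      stop("can only reconstruct from a Hamiltonian path", call. = FALSE)
    }
    path$order
  } else path
  stopifnot(all(ord %in% g$vertices))
  out <- g$seqs[[ord[1]]]
  if (length(ord) > 1) {
    ek <- edge_key(g$edges$from, g$edges$to)
    for (i in seq_len(length(ord) - 1L)) {
      row <- match(edge_key(ord[i], ord[i + 1L]), ek)
      if (is.na(row)) stop("path uses a non-edge", call. = FALSE)
      L <- g$edges$overlap[row]
      nx <- g$seqs[[ord[i + 1L]]]
      out <- paste0(out, substr(nx, L + 1L, nchar(nx)))
    }
  }
  out
}

# Exact solver used by assemble(): exhaustive binary enumeration when the
# QUBO is small enough, otherwise (vertex-position encoding only, where the
# zero-energy states are exactly the Hamiltonian paths) direct path search.
solve_exact <- function(q, g, cap = 24L) {
  if (q$n_vars <= cap) return(brute_force_solve(q, cap = cap))
  if (q$encoding != "vertex_position") {
    stop("exact solver cap exceeded for edge-indicator problem", call. = FALSE)
  }
  paths <- hamiltonian_paths(g, max_paths = 1)
  if (length(paths) == 0L) {
    stop(paste("no Hamiltonian path found and problem too large for",
               "exhaustive enumeration"), call. = FALSE)
  }
  x <- encode_path(paths[[1]], q, g)
  res <- anneal_result(matrix(x, 1), qubo_energy(q, x), "exact_path",
                       ground_energy = 0)
  res$n_ground_states <- NA_integer_
  res
}

#' End-to-end assembly pipeline
#'
#' Builds the overlap graph, chooses the QUBO encoding (edge-indicator when
#' the graph is acyclic, vertex-position otherwise), minimizes it with the
#' requested solver, decodes the best sample and reconstructs the sequence.
#' With the exact solver the number of distinct ground-state Hamiltonian
#' paths is reported, flagging ambiguous assemblies.
#'
#' @param fragments list of [sequence_record()]s or a character vector; with
#'   `k` set these are fragmented into k-mers first (duplicate k-mers across
#'   fragments collapse into one vertex).
#' @param k optional k-mer length; implies `min_overlap = k - 1`.
#' @param min_overlap minimum exact overlap for an edge (required when `k` is
#'   not given).
#' @param solver `"exact"`, `"simcim"` or `"sa"`.
#' @param A penalty coefficient for the QUBO.
#' @param params solver parameters: a [simcim_params()] for `"simcim"`, a
#'   list of [simulated_annealing_solve()] arguments for `"sa"`.
#' @param rng_seed seed forwarded to stochastic solvers when `params` does
#'   not carry one.
#' @return A [path_solution] with diagnostic fields: `graph`, `encoding`,
#'   `solver`, `result` (the [anneal_result()]), and for the exact solver
#'   `n_ground_paths`.
#' @export
assemble <- function(fragments, k = NULL, min_overlap = NULL,
                     solver = c("exact", "simcim", "sa"), A = 1,
                     params = NULL, rng_seed = 1L) {
  solver <- match.arg(solver)
  if (is.character(fragments)) {
    fragments <- lapply(seq_along(fragments), function(i) {
      sequence_record(sprintf("frag_%d", i), fragments[i])
    })
  }
  if (!is.null(k)) {
    kmers <- unlist(lapply(fragments, kmerize, k = k))
    fragments <- lapply(seq_along(kmers), function(i) {
      sequence_record(sprintf("kmer_%d", i), kmers[i])
    })
    min_overlap <- k - 1L
  }
  if (is.null(min_overlap)) {
    stop("supply either k or min_overlap", call. = FALSE)
  }
  g <- build_olc_graph(fragments, min_overlap = min_overlap,
                       collapse_duplicates = TRUE)
  if (g$M == 0L) {
    return(new_path_solution(NULL, "malformed", NA_real_, graph = g,
                             encoding = NA_character_, solver = solver,
                             diagnostics = "no overlaps between fragments"))
  }
  acy <- is_acyclic(g)
  encoding <- if (acy$acyclic) "edge_indicator" else "vertex_position"
  q <- if (acy$acyclic) qubo_edge_indicator(g, A) else
    qubo_vertex_position(g, A)
  res <- switch(solver,
    exact = solve_exact(q, g),
    simcim = {
      sp <- if (is.null(params)) simcim_params(rng_seed = rng_seed) else params
      simcim_solve(qubo_to_ising(q), sp)
    },
    sa = {
      args <- c(list(q = q), if (is.null(params))
        list(rng_seed = rng_seed) else params)
      do.call(simulated_annealing_solve, args)
    })
  sol <- if (encoding == "vertex_position") {
    decode_vertex_position(res$best, q, g)
  } else {
    decode_edge_indicator(res$best, q, g)
  }
  sol$graph <- g
  sol$encoding <- encoding
  sol$solver <- solver
  sol$result <- res
  if (identical(sol$valid, "hamiltonian")) {
    sol$sequence <- reconstruct_sequence(sol, g)
  }
  if (solver == "exact" && !is.null(res$n_ground_states) &&
      !is.na(res$n_ground_states)) {
    dec <- if (encoding == "vertex_position") decode_vertex_position else
      decode_edge_indicator
    ground_paths <- unique(Filter(Negate(is.null), lapply(
      seq_len(nrow(res$samples)), function(i) {
        s <- dec(res$samples[i, ], q, g)
        if (identical(s$valid, "hamiltonian"))
          paste(s$order, collapse = ">") else NULL
      })))
    sol$n_ground_paths <- length(ground_paths)
  }
  sol
}

#' Collapse the circular wrap of a contig
#'
#' A contig assembled around a circular genome repeats its origin: the end of
#' the string matches its beginning. This trims the largest strict
#' suffix-prefix self-overlap of at least `min_overlap`.
#'
#' @param contig nucleotide string.
#' @param min_overlap smallest self-overlap to collapse.
#' @return List with `sequence` (trimmed string) and `trimmed` (bases
#'   removed).
#' @export
collapse_circular <- function(contig, min_overlap = 1L) {
  L <- overlap_length(contig, contig, min_overlap)
  if (is.na(L)) return(list(sequence = contig, trimmed = 0L))
  list(sequence = substr(contig, 1L, nchar(contig) - L), trimmed = L)
}

#' Assemble reads classically via partition and path concatenation
#'
#' The classical route used for read-scale graphs: build the exact-overlap
#' OLC graph, optionally split it into blocks joined by single cut edges,
#' find a Hamiltonian path in each block by depth-first search constrained to
#' enter and leave at the cut-edge endpoints, concatenate the per-block paths
#' across the cut edges, merge overlaps, and (for circular references)
#' collapse the wrap-around duplication.
#'
#' @param reads list of [sequence_record()]s.
#' @param min_overlap minimum exact overlap for an edge.
#' @param n_parts optional number of single-edge-cut blocks; `NULL` searches
#'   the whole graph at once.
#' @param circular collapse the circular wrap of the final contig.
#' @return List with `contig`, `path` (vertex order), `graph`, `status`, and
#'   `partition` (when requested).
#' @export
assemble_reads_classical <- function(reads, min_overlap, n_parts = NULL,
                                     circular = FALSE) {
  g <- build_olc_graph(reads, min_overlap = min_overlap,
                       collapse_duplicates = TRUE)
  partition <- NULL
  path <- NULL
  if (!is.null(n_parts)) {
    partition <- partition_single_edge_cuts(g, n_parts)
    if (isTRUE(partition$ok)) {
      path <- concat_partition_paths(g, partition)
    }
  }
  if (is.null(path)) {
    paths <- hamiltonian_paths(g, max_paths = 1)
    path <- if (length(paths)) paths[[1]] else NULL
  }
  if (is.null(path)) {
    return(list(contig = NULL, path = NULL, graph = g,
                status = "no_hamiltonian_path", partition = partition))
  }
  contig <- reconstruct_sequence(path, g)
  trimmed <- 0L
  if (circular) {
    cc <- collapse_circular(contig, min_overlap = min_overlap)
    contig <- cc$sequence
    trimmed <- cc$trimmed
  }
  list(contig = contig, path = path, graph = g, status = "ok",
       partition = partition, wrap_trimmed = trimmed)
}

# Hamiltonian path over a partitioned graph: per-block paths constrained by
# the cut-edge endpoints, concatenated along the block ordering. The block
# chain found by the partitioner is undirected, so both traversal
# orientations are tried.
concat_partition_paths <- function(g, partition) {
  fwd <- concat_partition_paths_ordered(g, partition$parts,
                                        partition$cut_edges)
  if (!is.null(fwd)) return(fwd)
  concat_partition_paths_ordered(
    g, rev(partition$parts),
    partition$cut_edges[rev(seq_len(nrow(partition$cut_edges))), ,
                        drop = FALSE])
}

concat_partition_paths_ordered <- function(g, parts, cuts) {
  # reorder cut edges so cut i joins block i to block i+1 (either direction
  # was allowed during the search; require forward direction here)
  full <- character(0)
  for (i in seq_along(parts)) {
    sub <- induced_olc_subgraph(g, parts[[i]])
    need_start <- if (i > 1L) cuts$to[i - 1L] else NULL
    need_end <- if (i < length(parts)) cuts$from[i] else NULL
    if ((!is.null(need_start) && !(need_start %in% parts[[i]])) ||
        (!is.null(need_end) && !(need_end %in% parts[[i]]))) {
      return(NULL)   # cut edges run against the block ordering
    }
    cand <- hamiltonian_paths(sub)
    ok <- Filter(function(pth) {
      (is.null(need_start) || pth[1] == need_start) &&
        (is.null(need_end) || pth[length(pth)] == need_end)
    }, cand)
    if (length(ok) == 0L) return(NULL)
    full <- c(full, ok[[1]])
  }
  full
}
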