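#' Exact suffix-prefix overlap length
#'
#' Finds the largest `L >= min_overlap` such that the last `L` characters of
#' `a` equal the first `L` characters of `b`. Matching is exact (zero
#' mismatches) and full containment is excluded: `L` is always strictly
#' smaller than both string lengths.
#'
#' @param a,b nucleotide strings.
#' @param min_overlap smallest overlap worth an edge (>= 1).
#' @return Integer overlap length, or `NA_integer_` when no overlap of at
#'   least `min_overlap` exists.
#' @export
overlap_length <- function(a, b, min_overlap = 1L) {
  stopifnot_scalar_int(min_overlap, "min_overlap", min = 1L)
  if (!nzchar(a) || !nzchar(b)) stop("empty strings have no overlap", call. = FALSE)
  na <- nchar(a); nb <- nchar(b)
  upper <- min(na, nb) - 1L
  if (upper < min_overlap) return(NA_integer_)
  for (L in seq(upper, min_overlap)) {
    if (substr(a, na - L + 1L, na) == substr(b, 1L, L)) return(L)
  }
  NA_integer_
}

new_olc_graph <- function(labels, seqs, edges) {
  edges <- edges[order(match(edges$from, labels), match(edges$to, labels)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(vertices = labels, seqs = stats::setNames(seqs, labels),
                 edges = edges, N = length(labels), M = nrow(edges)),
            class = "olc_graph")
}

#' Build a directed overlap (OLC) graph
#'
#' One vertex per fragment (per distinct fragment string when
#' `collapse_duplicates = TRUE`), and a directed edge `u -> v` whenever the
#' suffix of `u` matches the prefix of `v` over at least `min_overlap`
#' characters. For k-mer input with `min_overlap = k - 1` this is the
#' (k-1)-overlap rule of k-mer graphs. Containment (one fragment inside
#' another) never produces an edge. The edge set does not depend on the input
#' order of the fragments.
#'
#' @param fragments list of [sequence_record()]s (or character vector).
#' @param min_overlap minimum exact suffix-prefix overlap for an edge.
#' @param collapse_duplicates collapse identical fragment strings into one
#'   vertex (default `TRUE`).
#' @return An object of class `olc_graph` with fields `vertices` (labels),
#'   `seqs` (named strings), `edges` (data.frame `from`, `to`, `overlap`),
#'   `N`, `M`.
#' @export
build_olc_graph <- function(fragments, min_overlap = 1L,
                            collapse_duplicates = TRUE) {
  if (is.character(fragments)) {
    fragments <- lapply(seq_along(fragments), function(i) {
      sequence_record(sprintf("frag_%d", i), fragments[i])
    })
  }
  if (length(fragments) < 2L) stop("need at least 2 fragments", call. = FALSE)
  ids <- vapply(fragments, `[[`, "", "id")
  seqs <- vapply(fragments, `[[`, "", "seq")
  if (collapse_duplicates) {
    keep <- !duplicated(seqs)
    ids <- ids[keep]; seqs <- seqs[keep]
    if (length(seqs) == 1L) {
      warning("all fragments identical; single-vertex graph is degenerate",
              call. = FALSE)
    }
  } else if (anyDuplicated(ids)) {
    stop("fragment ids must be unique when not collapsing", call. = FALSE)
  }
  n <- length(seqs)
  from <- character(0); to <- character(0); ov <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- overlap_length(seqs[i], seqs[j], min_overlap)
      if (!is.na(L)) {
        from <- c(from, ids[i]); to <- c(to, ids[j]); ov <- c(ov, L)
      }
    }
  }
  new_olc_graph(ids, unname(seqs),
                data.frame(from = from, to = to, overlap = ov,
                           stringsAsFactors = FALSE))
}

#' @export
print.olc_graph <- function(x, ...) {
  cat(sprintf("<olc_graph> N = %d vertices, M = %d edges\n", x$N, x$M))
  invisible(x)
}

#' Convert an OLC graph to an igraph object
#'
#' @param g an `olc_graph`.
#' @return A directed `igraph` graph with the same vertices and edges.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "olc_graph"))
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = data.frame(name = g$vertices))
}

#' Test a graph for acyclicity (with topological order)
#'
#' @param g an `olc_graph`.
#' @return List with `acyclic` (logical) and `order` (vertex labels in a
#'   topological order when acyclic, otherwise `NULL`).
#' @export
is_acyclic <- function(g) {
  ig <- as_igraph(g)
  if (igraph::is_dag(ig)) {
    ord <- igraph::topo_sort(ig, mode = "out")
    list(acyclic = TRUE, order = igraph::V(ig)$name[as.integer(ord)])
  } else {
    list(acyclic = FALSE, order = NULL)
  }
}

# Edge lookup helper: named TRUE set "u\tv".
edge_key <- function(from, to) paste(from, to, sep = "\t")

#' Partition a graph into blocks joined by single edges
#'
#' Searches for a split of the vertices into `n_parts` weakly connected
#' blocks such that consecutive blocks (in the induced ordering) are joined by
#' exactly one directed edge and non-consecutive blocks by none. Because any
#' single cut edge between two blocks must be a bridge of the underlying
#' undirected graph, the search enumerates combinations of bridges; this is
#' exact and intended for the small graphs this toolkit targets. Failure is a
#' reported status, not an error. Ties between valid splits are broken in
#' favour of the most balanced block sizes.
#'
#' @param g an `olc_graph`.
#' @param n_parts number of blocks (>= 2).
#' @return List with `ok` (logical), `parts` (list of vertex-label vectors,
#'   ordered along the cut edges), `cut_edges` (data.frame of the edges
#'   between consecutive blocks) when `ok`, else a `reason` string.
#' @export
partition_single_edge_cuts <- function(g, n_parts = 2L) {
  stopifnot_scalar_int(n_parts, "n_parts", min = 2L)
  ig <- as_igraph(g)
  und <- igraph::as_undirected(ig, mode = "collapse")
  if (igraph::count_components(und) != 1L) {
    return(list(ok = FALSE, reason = "graph is not weakly connected"))
  }
  br <- igraph::bridges(und)
  if (length(br) < n_parts - 1L) {
    return(list(ok = FALSE, reason = "not enough single-edge cuts (bridges)"))
  }
  # A bridge of the collapsed undirected graph is a single-edge cut only if
  # exactly one directed edge runs between its endpoints.
  ends <- igraph::ends(und, br)
  ek <- edge_key(g$edges$from, g$edges$to)
  single <- vapply(seq_len(nrow(ends)), function(i) {
    a <- ends[i, 1]; b <- ends[i, 2]
    sum(ek %in% c(edge_key(a, b), edge_key(b, a))) == 1L
  }, logical(1))
  cand <- ends[single, , drop = FALSE]
  if (nrow(cand) < n_parts - 1L) {
    return(list(ok = FALSE, reason = "not enough single-edge cuts (bridges)"))
  }
  best <- NULL
  combos <- utils::combn(nrow(cand), n_parts - 1L, simplify = FALSE)
  for (cb in combos) {
    cut <- cand[cb, , drop = FALSE]
    und2 <- igraph::delete_edges(
      und, igraph::get_edge_ids(und, t(cut)))
    comp <- igraph::components(und2)
    if (comp$no != n_parts) next
    memb <- stats::setNames(comp$membership, igraph::V(und2)$name)
    # Block adjacency along the cut edges must form a simple chain.
    bl <- cbind(memb[cut[, 1]], memb[cut[, 2]])
    adj <- matrix(0L, n_parts, n_parts)
    for (i in seq_len(nrow(bl))) {
      adj[bl[i, 1], bl[i, 2]] <- adj[bl[i, 1], bl[i, 2]] + 1L
      adj[bl[i, 2], bl[i, 1]] <- adj[bl[i, 2], bl[i, 1]] + 1L
    }
    deg <- rowSums(adj > 0)
    if (any(adj > 1) || sum(deg == 1L) != 2L || any(deg > 2L)) next
    sizes <- comp$csize
    score <- max(sizes)
    if (is.null(best) || score < best$score) {
      ordering <- chain_block_order(adj)
      parts <- lapply(ordering, function(b) names(memb)[memb == b])
      cut_dir <- direct_cut_edges(g, memb, ordering)
      best <- list(score = score, parts = parts, cut_edges = cut_dir)
    }
  }
  if (is.null(best)) {
    return(list(ok = FALSE, reason = "no single-edge split found"))
  }
  list(ok = TRUE, parts = best$parts, cut_edges = best$cut_edges)
}

# Order blocks along the chain defined by the block adjacency matrix,
# starting from an endpoint.
chain_block_order <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj > 0)
  start <- which(deg == 1L)[1]
  order <- start
  while (length(order) < n) {
    nxt <- setdiff(which(adj[order[length(order)], ] > 0), order)
    order <- c(order, nxt[1])
  }
  order
}

# Directed cut edges between consecutive blocks, in block order.
direct_cut_edges <- function(g, memb, ordering) {
  out <- g$edges[0, , drop = FALSE]
  for (i in seq_len(length(ordering) - 1L)) {
    a <- ordering[i]; b <- ordering[i + 1L]
    sel <- (memb[g$edges$from] == a & memb[g$edges$to] == b) |
      (memb[g$edges$from] == b & memb[g$edges$to] == a)
    out <- rbind(out, g$edges[sel, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Extract the induced subgraph on a vertex subset
#'
#' @param g an `olc_graph`.
#' @param vertices vertex labels to keep.
#' @return An `olc_graph` on those vertices.
#' @export
induced_olc_subgraph <- function(g, vertices) {
  stopifnot(all(vertices %in% g$vertices))
  keep <- g$edges$from %in% vertices & g$edges$to %in% vertices
  new_olc_graph(g$vertices[g$vertices %in% vertices],
                unname(g$seqs[g$vertices %in% vertices]),
                g$edges[keep, , drop = FALSE])
}

#' Enumerate Hamiltonian paths by depth-first search
#'
#' Independent combinatorial reference used for validation and as the exact
#' fallback solver: backtracking over vertex orders, optionally stopping at
#' the first path found. Successors are tried in decreasing overlap order,
#' which on near-interval overlap graphs finds a path quickly.
#'
#' @param g an `olc_graph`.
#' @param max_paths stop after this many paths (default `Inf`: enumerate all).
#' @return List of Hamiltonian paths, each a character vector of vertex
#'   labels; empty list when none exists.
#' @export
hamiltonian_paths <- function(g, max_paths = Inf) {
  n <- g$N
  if (n == 1L) return(list(g$vertices))
  succ <- lapply(g$vertices, function(v) {
    rows <- g$edges$from == v
    ord <- order(-g$edges$overlap[rows])
    g$edges$to[rows][ord]
  })
  names(succ) <- g$vertices
  found <- list()
  visit <- function(path, inpath) {
    if (length(found) >= max_paths) return()
    if (length(path) == n) {
      found[[length(found) + 1L]] <<- path
      return()
    }
    for (w in succ[[path[length(path)]]]) {
      if (!inpath[w]) {
        inpath[w] <- TRUE
        visit(c(path, w), inpath)
        inpath[w] <- FALSE
        if (length(found) >= max_paths) return()
      }
    }
  }
  for (v in g$vertices) {
    inpath <- stats::setNames(rep(FALSE, n), g$vertices)
    inpath[v] <- TRUE
    visit(v, inpath)
    if (length(found) >= max_paths) break
  }
  found
}

#' Export an OLC graph as a TSV edge list
#'
#' Columns `from`, `to`, `overlap`; vertex sequences are carried in a
#' companion header line (`# vertex<TAB>sequence`) so the graph round-trips.
#'
#' @param g an `olc_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_olc_tsv <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (v in g$vertices) {
    writeLines(sprintf("# vertex\t%s\t%s", v, g$seqs[[v]]), con)
  }
  utils::write.table(g$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an OLC graph from a TSV edge list written by [write_olc_tsv()]
#'
#' @param path input file.
#' @return An `olc_graph`.
#' @export
read_olc_tsv <- function(path) {
  lines <- readLines(path)
  vh <- grepl("^# vertex\t", lines)
  vparts <- strsplit(sub("^# vertex\t", "", lines[vh]), "\t", fixed = TRUE)
  labels <- vapply(vparts, `[[`, "", 1L)
  seqs <- vapply(vparts, `[[`, "", 2L)
  body <- lines[!vh]
  edges <- if (length(body) > 1L) {
    utils::read.table(text = body, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), overlap = integer(0))
  }
  new_olc_graph(labels, seqs, edges)
}

#' Export the adjacency matrix of an OLC graph as CSV
#'
#' @param g an `olc_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(g, path) {
  A <- matrix(0L, g$N, g$N, dimnames = list(g$vertices, g$vertices))
  if (g$M > 0) A[cbind(g$edges$from, g$edges$to)] <- 1L
  utils::write.csv(A, path)
  invisible(path)
}

#' Export an OLC graph in GraphViz DOT format
#'
#' @param g an `olc_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path) {
  lines <- c("digraph olc {",
             sprintf("  \"%s\" [label=\"%s\\n%s\"];", g$vertices,
                     g$vertices, g$seqs[g$vertices]),
             if (g$M > 0)
               sprintf("  \"%s\" -> \"%s\" [label=%d];", g$edges$from,
                       g$edges$to, g$edges$overlap),
             "}")
  writeLines(lines, path)
  invisible(path)
}
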