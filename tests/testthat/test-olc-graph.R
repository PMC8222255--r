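test_that("overlap_length finds the largest exact suffix-prefix match", {
  expect_equal(overlap_length("ATG", "TGC", 2), 2L)
  expect_true(is.na(overlap_length("ATG", "GGG", 2)))
  # enumerating L = 3, 2 by hand: suffix "AAT" == prefix "AAT" wins
  expect_equal(overlap_length("AAAT", "AATC", 2), 3L)
  # containment excluded: overlap is strictly below both lengths
  expect_true(is.na(overlap_length("ATG", "ATG", 3)))
  expect_equal(overlap_length("AAAA", "AAAA", 1), 3L)
  expect_error(overlap_length("", "A"), "empty")
  expect_error(overlap_length("A", "A", 0), ">= 1")
})

test_that("build_olc_graph applies the overlap rule pairwise", {
  g <- build_olc_graph(c("ATG", "TGC", "GCA"), min_overlap = 2)
  expect_equal(g$N, 3L)
  expect_equal(g$edges$from, c("frag_1", "frag_2"))
  expect_equal(g$edges$to, c("frag_2", "frag_3"))
  expect_equal(g$edges$overlap, c(2L, 2L))

  # ATG -> TGA overlaps on TG, but TGA -> ATG has no length-2 match:
  # a single directed edge, not a 2-cycle
  g2 <- build_olc_graph(c("ATG", "TGA"), min_overlap = 2)
  expect_equal(g2$M, 1L)
  # a genuine 2-cycle: ATGC <-> GCAT (overlaps GC and AT)
  g2c <- build_olc_graph(c("ATGC", "GCAT"), min_overlap = 2)
  expect_equal(g2c$M, 2L)

  g3 <- build_olc_graph(c("AAA", "TTT"), min_overlap = 2)
  expect_equal(g3$M, 0L)

  expect_error(build_olc_graph(list()), "at least 2")
  expect_warning(build_olc_graph(c("AAA", "AAA"), min_overlap = 2),
                 "degenerate")
})

test_that("edge set is invariant under fragment input order", {
  frags <- c("ATGC", "TGCA", "GCAT", "CATG")
  g1 <- build_olc_graph(frags, min_overlap = 2)
  g2 <- build_olc_graph(rev(frags), min_overlap = 2)
  canon <- function(g) {
    e <- g$edges
    key <- paste(g$seqs[e$from], g$seqs[e$to], e$overlap)
    sort(key)
  }
  expect_identical(canon(g1), canon(g2))
})

test_that("k-mer graphs of duplicate-free sequences contain the chain", {
  for (seed in 1:10) {
    rec <- random_sequence(8, rng_seed = seed)
    kmers <- kmerize(rec, 3)
    if (anyDuplicated(kmers) > 0) next
    g <- build_olc_graph(kmers, min_overlap = 2)
    labs <- g$vertices[match(kmers, g$seqs[g$vertices])]
    ek <- paste(g$edges$from, g$edges$to)
    for (i in seq_len(length(kmers) - 1)) {
      expect_true(paste(labs[i], labs[i + 1]) %in% ek)
    }
  }
})

test_that("acyclicity check returns a valid topological order", {
  chain <- build_olc_graph(c("ATG", "TGC", "GCA"), min_overlap = 2)
  ac <- is_acyclic(chain)
  expect_true(ac$acyclic)
  expect_equal(ac$order, c("frag_1", "frag_2", "frag_3"))
  cyc <- build_olc_graph(c("ATGC", "GCAT"), min_overlap = 2)
  expect_false(is_acyclic(cyc)$acyclic)
  disc <- build_olc_graph(c("AAA", "TTT"), min_overlap = 2)
  expect_true(is_acyclic(disc)$acyclic)
})

test_that("single-edge-cut partitioning splits chains and rejects cliques", {
  chain6 <- toy_graph(6, cbind(1:5, 2:6))
  p <- partition_single_edge_cuts(chain6, 2)
  expect_true(p$ok)
  expect_equal(sort(lengths(p$parts)), c(3L, 3L))
  expect_equal(nrow(p$cut_edges), 1L)

  k3 <- toy_graph(3, rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  pk <- partition_single_edge_cuts(k3, 2)
  expect_false(pk$ok)

  chain2 <- toy_graph(2, cbind(1, 2))
  p2 <- partition_single_edge_cuts(chain2, 2)
  expect_true(p2$ok)
  expect_equal(lengths(p2$parts), c(1L, 1L))

  p3 <- partition_single_edge_cuts(chain6, 3)
  expect_true(p3$ok)
  expect_equal(sort(lengths(p3$parts)), c(2L, 2L, 2L))
})

test_that("per-part paths concatenate back into the full chain", {
  g <- build_olc_graph(kmerize("ATGCATT", 3), min_overlap = 2)
  # this 5-mer chain is a simple path graph; check the concatenation route
  p <- partition_single_edge_cuts(g, 2)
  if (p$ok) {
    path <- olcanneal:::concat_partition_paths(g, p)
    expect_false(is.null(path))
    expect_equal(reconstruct_sequence(path, g), "ATGCATT")
  }
  chain6 <- toy_graph(6, cbind(1:5, 2:6))
  p6 <- partition_single_edge_cuts(chain6, 3)
  path6 <- olcanneal:::concat_partition_paths(chain6, p6)
  expect_equal(path6, paste0("v", 1:6))
})

test_that("graph serialization round-trips and exports are well-formed", {
  g <- build_olc_graph(c("ATGC", "TGCA", "GCAT"), min_overlap = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_olc_tsv(g, tsv)
  g2 <- read_olc_tsv(tsv)
  expect_equal(g2$vertices, g$vertices)
  expect_equal(g2$edges, g$edges)
  expect_equal(unname(g2$seqs), unname(g$seqs))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_csv(g, csv)
  A <- as.matrix(utils::read.csv(csv, row.names = 1))
  expect_equal(sum(A), g$M)

  dot <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, dot)
  lines <- readLines(dot)
  expect_equal(lines[1], "digraph olc {")
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), g$M)
})

test_that("hamiltonian path enumeration agrees with permutation counting", {
  withr::local_seed(99)
  for (trial in 1:20) {
    n <- sample(2:5, 1)
    A <- random_digraph(n, p = 0.5)
    g <- toy_graph(n, adj_to_edges(A))
    found <- hamiltonian_paths(g)
    # independent count over all vertex permutations
    cnt <- 0
    for (p in perm_enum(seq_len(n))) {
      ok <- all(A[cbind(p[-n], p[-1])] == 1)
      if (ok) cnt <- cnt + 1
    }
    expect_equal(length(found), cnt)
  }
})
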