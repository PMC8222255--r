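#' Sequence records
#'
#' A `sequence_record` is the minimal substrate of the assembler: a labelled
#' nucleotide string over the alphabet A/C/G/T (case-normalized to upper).
#'
#' @param id character label.
#' @param seq nucleotide string.
#' @return An object of class `sequence_record` with fields `id` and `seq`.
#' @export
sequence_record <- function(id, seq) {
  structure(list(id = as.character(id), seq = normalize_seq(seq)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d bp)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Draw a uniform random nucleotide sequence
#'
#' Each position is an independent uniform draw over {A,C,G,T}; the result is
#' deterministic for a fixed seed and leaves the caller's RNG stream untouched.
#'
#' @param length positive integer sequence length.
#' @param rng_seed integer seed.
#' @param id label for the record (default derived from seed and length).
#' @return A [sequence_record()].
#' @export
random_sequence <- function(length, rng_seed, id = NULL) {
  stopifnot_scalar_int(length, "length", min = 1L)
  if (is.null(id)) id <- sprintf("rand_L%d_s%d", length, as.integer(rng_seed))
  seq <- with_seed(rng_seed, {
    paste(sample(DNA_ALPHABET, length, replace = TRUE), collapse = "")
  })
  sequence_record(id, seq)
}

#' Split a sequence into its overlapping k-mers
#'
#' Returns the `nchar(seq) - k + 1` substrings of length `k` in left-to-right
#' order. Duplicate k-mers are reported as they occur; filtering is the
#' caller's concern.
#'
#' @param seq a [sequence_record()] or a plain nucleotide string.
#' @param k k-mer length (positive integer).
#' @return Character vector of k-mers.
#' @export
kmerize <- function(seq, k) {
  s <- if (inherits(seq, "sequence_record")) seq$seq else normalize_seq(seq)
  stopifnot_scalar_int(k, "k", min = 1L)
  n <- nchar(s)
  if (n < k) {
    stop(sprintf("sequence of length %d is shorter than k = %d", n, k),
         call. = FALSE)
  }
  starts <- seq_len(n - k + 1L)
  substring(s, starts, starts + k - 1L)
}

#' Simulate error-free fixed-length reads from a reference
#'
#' Reads are exact substrings of the reference drawn at uniformly random start
#' positions on the forward strand. On a circular reference the read may wrap
#' around the origin; on a linear reference every read fits inside the
#' sequence.
#'
#' @param reference a [sequence_record()] (or string) to sample from.
#' @param n_reads number of reads.
#' @param read_length length of every read, in bp.
#' @param circular logical; treat the reference as circular.
#' @param rng_seed integer seed.
#' @return List of [sequence_record()]s named `read_1 ... read_n`.
#' @export
simulate_reads <- function(reference, n_reads, read_length, circular = FALSE,
                           rng_seed = 1L) {
  ref <- if (inherits(reference, "sequence_record")) reference else
    sequence_record("reference", reference)
  stopifnot_scalar_int(n_reads, "n_reads", min = 1L)
  stopifnot_scalar_int(read_length, "read_length", min = 1L)
  L <- nchar(ref$seq)
  if (read_length > L) {
    stop("read_length exceeds the reference length", call. = FALSE)
  }
  starts <- with_seed(rng_seed, {
    if (circular) sample.int(L, n_reads, replace = TRUE)
    else sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  })
  template <- if (circular) paste0(ref$seq, ref$seq) else ref$seq
  lapply(seq_len(n_reads), function(i) {
    sequence_record(sprintf("read_%d", i),
                    substr(template, starts[i], starts[i] + read_length - 1L))
  })
}

# A retained synthetic problem must be non-trivial: duplicate-free k-mers
# (so the fragmentation chain is a Hamiltonian path of the k-mer graph) and
# at least one edge beyond the bare chain (M > N - 1), otherwise there is
# nothing to optimize.
candidate_problem <- function(record, k, min_overlap = k - 1L) {
  kmers <- kmerize(record, k)
  if (anyDuplicated(kmers) > 0L) {
    return(list(keep = FALSE, reason = "duplicate_kmers"))
  }
  frags <- lapply(seq_along(kmers), function(i) {
    sequence_record(sprintf("kmer_%d", i), kmers[i])
  })
  g <- build_olc_graph(frags, min_overlap = min_overlap,
                       collapse_duplicates = TRUE)
  if (g$M == g$N - 1L) {
    return(list(keep = FALSE, reason = "trivial_chain"))
  }
  key <- paste(sort(kmers), collapse = "|")
  list(keep = TRUE, reason = "retained", record = record, kmers = kmers,
       graph = g, key = key)
}

#' Generate the synthetic problem set
#'
#' For every requested sequence length, random sequences are drawn and
#' fragmented into k-mers until `per_length` problems survive three filters:
#' the k-mer multiset must be duplicate-free (guaranteeing a Hamiltonian path
#' exists in the k-mer overlap graph), the overlap graph must not be a bare
#' chain with no auxiliary edges (those need no optimization), and no two
#' retained problems may share the same sorted k-mer list. Generation is
#' bounded by a per-length retry cap; exhaustion is reported, not fatal.
#'
#' @param lengths integer vector of source-sequence lengths.
#' @param per_length problems to retain per length.
#' @param k k-mer length.
#' @param rng_seed integer seed controlling all draws.
#' @param retry_cap maximum candidate draws per length.
#' @return An object of class `synthetic_problem_set`: list with `problems`
#'   (each holding the source record, k-mers, overlap graph and length),
#'   `seed`, `lengths`, `per_length`, `k` and `rejections` (a table of
#'   rejection reasons).
#' @export
generate_problem_set <- function(lengths = 5:10, per_length = 10, k = 3,
                                 rng_seed = 1L, retry_cap = 1000L) {
  stopifnot_scalar_int(per_length, "per_length", min = 0L)
  stopifnot_scalar_int(k, "k", min = 1L)
  if (any(lengths < k)) stop("all lengths must be >= k", call. = FALSE)
  problems <- list()
  seen_keys <- character(0)
  rejections <- c(duplicate_kmers = 0L, trivial_chain = 0L,
                  duplicate_problem = 0L)
  incomplete <- integer(0)
  with_seed(rng_seed, {
    for (L in lengths) {
      kept <- 0L
      tries <- 0L
      while (kept < per_length && tries < retry_cap) {
        tries <- tries + 1L
        seq <- paste(sample(DNA_ALPHABET, L, replace = TRUE), collapse = "")
        rec <- sequence_record(sprintf("L%d_p%d", L, tries), seq)
        cand <- candidate_problem(rec, k)
        if (!cand$keep) {
          rejections[cand$reason] <- rejections[cand$reason] + 1L
          next
        }
        if (cand$key %in% seen_keys) {
          rejections["duplicate_problem"] <- rejections["duplicate_problem"] + 1L
          next
        }
        seen_keys <- c(seen_keys, cand$key)
        kept <- kept + 1L
        problems[[length(problems) + 1L]] <- list(
          id = sprintf("L%d_%02d", L, kept), length = L,
          source = cand$record, kmers = cand$kmers, graph = cand$graph)
      }
      if (kept < per_length) incomplete <- c(incomplete, L)
    }
  })
  if (length(incomplete)) {
    warning(sprintf("retry cap reached before %d problems for length(s): %s",
                    per_length, paste(incomplete, collapse = ", ")),
            call. = FALSE)
  }
  structure(list(problems = problems, seed = as.integer(rng_seed),
                 lengths = as.integer(lengths),
                 per_length = as.integer(per_length), k = as.integer(k),
                 rejections = rejections),
            class = "synthetic_problem_set")
}

#' @export
print.synthetic_problem_set <- function(x, ...) {
  cat(sprintf("<synthetic_problem_set> %d problems (lengths %s, k = %d, seed = %d)\n",
              length(x$problems),
              paste(range(x$lengths), collapse = "-"), x$k, x$seed))
  cat("rejections:", paste(names(x$rejections), x$rejections, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Write sequence records as 60-column wrapped FASTA
#'
#' @param records list of [sequence_record()]s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into sequence records
#'
#' @param path FASTA file path.
#' @return List of [sequence_record()]s.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    sequence_record(names(seqs)[i], as.character(seqs[[i]]))
  })
}

#' Write a problem set to disk (FASTA sources + JSON manifest)
#'
#' Sources are written as one multi-record FASTA; the manifest records seeds,
#' counts and rejection statistics so the set can be regenerated exactly.
#'
#' @param ps a `synthetic_problem_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_problem_set <- function(ps, dir) {
  stopifnot(inherits(ps, "synthetic_problem_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(lapply(ps$problems, `[[`, "source"),
              file.path(dir, "sources.fasta"))
  manifest <- list(seed = ps$seed, lengths = ps$lengths,
                   per_length = ps$per_length, k = ps$k,
                   n_problems = length(ps$problems),
                   problem_ids = vapply(ps$problems, `[[`, "", "id"),
                   rejections = as.list(ps$rejections))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
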