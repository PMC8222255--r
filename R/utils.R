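#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  }
  if (!is.null(min) && x < min) {
    stop(sprintf("`%s` must be >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

DNA_ALPHABET <- c("A", "C", "G", "T")

normalize_seq <- function(seq) {
  s <- toupper(as.character(seq))
  if (length(s) != 1L || is.na(s) || nchar(s) == 0L) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(chars %in% DNA_ALPHABET)) {
    stop("sequence contains characters outside {A,C,G,T}", call. = FALSE)
  }
  s
}
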