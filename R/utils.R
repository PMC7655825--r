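# Small sequence helpers shared across modules. Sequences are plain upper-case
# character vectors over A/C/G/T (N allowed only where stated).

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTTT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Longest homopolymer run
#'
#' @param x character vector of sequences.
#' @return integer vector: length of the longest single-base run in each
#'   sequence (>= 1 for non-empty sequences).
#' @export
max_homopolymer <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    as.integer(max(r$lengths))
  }, integer(1), USE.NAMES = FALSE)
}

#' GC content as a percentage
#'
#' @param x character vector of sequences.
#' @return numeric vector, 100 * (#G + #C) / nchar.
#' @export
gc_percent <- function(x) {
  gc <- vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    sum(ch %in% c("G", "C"))
  }, numeric(1))
  100 * gc / nchar(x)
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b character scalars or vectors of equal-length sequences
#'   (recycled pairwise).
#' @return integer vector of substitution counts.
#' @export
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Minimum pairwise Levenshtein distance over a set
#'
#' @param seqs character vector (>= 2 sequences).
#' @return integer scalar: the smallest edit distance over all pairs.
#' @export
min_pairwise_levenshtein <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  d <- adist(seqs)
  as.integer(min(d[upper.tri(d)]))
}

# All sequences of length `len` at Hamming distance exactly 1 from `seq`.
hamming1_neighbors <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(bases, ch[i])) {
      v <- ch
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Stable RNG scope: run `expr` with a local seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
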