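#' @useDynLib replowpass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347) %% 2147483587)
}

#' Generate random DNA with a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc/2` and P(A) = P(T) =
#' `(1 - gc)/2`.
#'
#' @param n Sequence length in bases.
#' @param gc Target GC fraction in `[0, 1]`.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' GC fraction of sequences
#'
#' @param x Character vector of DNA sequences or a
#'   [Biostrings::DNAStringSet-class].
#' @return Numeric vector of GC fractions (`NaN` for empty sequences).
#' @export
gc_content <- function(x) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  as.numeric(Biostrings::letterFrequency(x, "GC", as.prob = TRUE))
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Introduce random substitutions at the given per-site rate.
mutate_sequence <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < divergence)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    for (i in hit) bases[i] <- sample(setdiff(alt, bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

# All rotations of a circular sequence.
rotations <- function(s) {
  n <- nchar(s)
  d <- paste0(s, s)
  vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
}

#' Canonical form of a circular DNA sequence
#'
#' The lexicographically smallest rotation, optionally over both strands.
#' Used to give satellite consensus monomers reproducible coordinates.
#'
#' @param s A DNA sequence (character scalar).
#' @param both_strands Consider rotations of the reverse complement as well.
#' @return The canonical rotation as a character string.
#' @export
canonical_rotation <- function(s, both_strands = FALSE) {
  cand <- rotations(s)
  if (both_strands) cand <- c(cand, rotations(revcomp(s)))
  sort(cand)[1L]
}

# TRUE if two circular sequences are rotations of one another (optionally on
# either strand).
rotation_equivalent <- function(a, b, both_strands = TRUE) {
  if (nchar(a) != nchar(b)) return(FALSE)
  canonical_rotation(a, both_strands) == canonical_rotation(b, both_strands)
}

# All k-mer windows of a set of sequences as a character vector.
kmer_windows <- function(seqs, k) {
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(character(0))
  unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }), use.names = FALSE)
}
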