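#' Find pairwise overlaps between long reads
#'
#' Computes, for every unordered pair of reads whose best local alignment on
#' either strand reaches both thresholds, one overlap edge. Identity is the
#' fraction of matching columns among all alignment columns; coverage is the
#' aligned span on the shorter read divided by the shorter read's length.
#' The default thresholds (90% identity over 55% of the shorter read) define
#' the read-similarity graph used for repeat-family clustering.
#'
#' Two methods are available: `"seed"` accelerates the search by only
#' aligning pairs that share an exact `seed_k`-mer (on the appropriate
#' strand combination), while `"exhaustive"` aligns every pair and serves
#' as the brute-force reference the seeded method is validated against.
#' Both use the same Smith-Waterman kernel (match +1, mismatch -1, gap -2),
#' whose scores are independently cross-checked against
#' [Biostrings::pairwiseAlignment()] in the package tests; note that among
#' co-optimal local alignments the reported extent is implementation-defined.
#'
#' @param reads Read `data.frame` (columns `id`, `seq`).
#' @param min_identity Minimum alignment identity (matching columns /
#'   alignment columns).
#' @param min_shorter_coverage Minimum fraction of the shorter read covered
#'   by the alignment.
#' @param method `"seed"` or `"exhaustive"`.
#' @param seed_k Seed k-mer length for the accelerated method.
#' @return A `data.frame` of edges: `read_a`, `read_b` (with `read_a` <
#'   `read_b` lexicographically), `identity`, `shorter_coverage`, `score`,
#'   `strand` (`"+"` if the reads overlap on the same strand).
#' @export
find_overlaps <- function(reads, min_identity = 0.90, min_shorter_coverage = 0.55,
                          method = c("seed", "exhaustive"), seed_k = 14L) {
  method <- match.arg(method)
  stopifnot(nrow(reads) >= 2, !anyDuplicated(reads$id))
  empty <- data.frame(read_a = character(0), read_b = character(0),
                      identity = numeric(0), shorter_coverage = numeric(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  cand <- if (method == "seed") {
    overlap_candidates(reads$seq, seed_k)
  } else {
    n <- nrow(reads)
    ij <- utils::combn(n, 2L)
    data.table::data.table(i = ij[1L, ], j = ij[2L, ],
                           rel = rep(c("+", "-"), each = ncol(ij)))
  }
  if (!nrow(cand)) return(empty)

  a <- reads$seq[cand$i]
  b <- ifelse(cand$rel == "+", reads$seq[cand$j], revcomp(reads$seq[cand$j]))
  st <- .cpp_sw_batch(a, b)
  len_a <- nchar(reads$seq[cand$i])
  len_b <- nchar(reads$seq[cand$j])
  shorter <- pmin(len_a, len_b)
  span_a <- st[, "a_end"] - st[, "a_start"] + 1L
  span_b <- st[, "b_end"] - st[, "b_start"] + 1L
  span_shorter <- ifelse(len_a <= len_b, span_a, span_b)
  identity <- ifelse(st[, "columns"] > 0, st[, "matches"] / st[, "columns"], 0)
  coverage <- span_shorter / shorter
  ok <- identity >= min_identity & coverage >= min_shorter_coverage &
    st[, "score"] > 0
  if (!any(ok)) return(empty)
  hits <- data.table::data.table(
    i = cand$i[ok], j = cand$j[ok], identity = identity[ok],
    coverage = coverage[ok], score = st[ok, "score"], strand = cand$rel[ok])
  # one edge per unordered pair: keep the best-scoring strand combination
  data.table::setorder(hits, i, j, -score, strand)
  hits <- hits[!duplicated(hits[, c("i", "j")]), ]
  ida <- reads$id[hits$i]; idb <- reads$id[hits$j]
  swap <- ida > idb
  out <- data.frame(read_a = ifelse(swap, idb, ida),
                    read_b = ifelse(swap, ida, idb),
                    identity = hits$identity,
                    shorter_coverage = hits$coverage,
                    score = as.integer(hits$score), strand = hits$strand,
                    stringsAsFactors = FALSE)
  out[order(out$read_a, out$read_b), , drop = FALSE]
}

# Candidate read pairs sharing an exact k-mer, with the implied strand
# relation ("+" = same strand, "-" = opposite).
overlap_candidates <- function(seqs, k) {
  n <- length(seqs)
  tab <- function(ss, orient) {
    kl <- lapply(ss, function(s) {
      m <- nchar(s) - k + 1L
      if (m < 1L) return(character(0))
      unique(substring(s, seq_len(m), seq_len(m) + k - 1L))
    })
    data.table::data.table(kmer = unlist(kl, use.names = FALSE),
                           read = rep(seq_len(n), lengths(kl)),
                           orient = orient)
  }
  dt <- data.table::rbindlist(list(tab(seqs, 0L), tab(revcomp(seqs), 1L)))
  pairs <- merge(dt, dt, by = "kmer", allow.cartesian = TRUE)
  pairs <- pairs[pairs$read.x < pairs$read.y, ]
  if (!nrow(pairs)) {
    return(data.table::data.table(i = integer(0), j = integer(0),
                                  rel = character(0)))
  }
  pairs[, rel := ifelse(orient.x == orient.y, "+", "-")]
  unique(pairs[, .(i = read.x, j = read.y, rel)])
}

# Alignment statistics via Biostrings (independent engine used to
# cross-check the package kernel): same scoring scheme, match +1 /
# mismatch -1 / gap -2.
sw_stats_biostrings <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAStringSet(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  score <- Biostrings::score(aln)
  matches <- Biostrings::nmatch(aln)
  columns <- Biostrings::nchar(aln)
  pr <- methods::slot(Biostrings::pattern(aln), "range")
  sr <- methods::slot(Biostrings::subject(aln), "range")
  out <- cbind(score = as.integer(round(score)), matches = matches,
               columns = columns,
               a_start = IRanges::start(pr), a_end = IRanges::end(pr),
               b_start = IRanges::start(sr), b_end = IRanges::end(sr))
  out[score <= 0, ] <- 0L
  out
}
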