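#' Remove artificially duplicated long reads
#'
#' Sequencing-by-emulsion protocols emit multiple identical copies of some
#' template molecules; among any group of reads with an identical
#' full-length sequence exactly one (the first in input order) is retained.
#' Linker trimming is exposed as a no-op hook for pre-cleaned inputs.
#'
#' @param reads Read `data.frame` (columns `id`, `seq`, ...).
#' @param trim_linkers Optional function applied to the sequences before
#'   duplicate detection; the default leaves them unchanged.
#' @return The deduplicated `data.frame` with attribute `n_removed` giving
#'   the number of reads discarded.
#' @export
dedup_long_reads <- function(reads, trim_linkers = identity) {
  seqs <- trim_linkers(reads$seq)
  keep <- !duplicated(seqs)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "platform") <- attr(reads, "platform")
  attr(out, "n_removed") <- sum(!keep)
  message(sum(!keep), " duplicated reads removed (", nrow(out), " retained)")
  out
}

#' Trim short reads to quality-filtered sequence tags
#'
#' Extracts a fixed high-quality window from each short read (by default
#' positions 3-32, 1-based inclusive, giving a 30-nt tag) and keeps only
#' tags in which at least `min_frac` of the positions have base-call quality
#' of at least `min_q`. With the defaults the acceptance rule is >= 27 of 30
#' positions at Phred >= 10 (`ceiling(0.9 * 30) = 27`).
#'
#' @param reads Read `data.frame` with a `qual` column (Phred+33 strings).
#' @param window Integer pair: first and last read position of the tag
#'   window (1-based, inclusive).
#' @param min_q Quality floor (a position "passes" when its quality reaches
#'   `min_q`).
#' @param min_frac Minimum fraction of passing positions in the window.
#' @return A list with `tags` (data.frame `id`, `seq`) and `rejects`
#'   (data.frame `id`, `reason` with codes `"too_short"` / `"low_quality"`).
#' @export
trim_and_filter <- function(reads, window = c(3L, 32L), min_q = 10L,
                            min_frac = 0.9) {
  stopifnot(length(window) == 2, window[1] >= 1, window[2] >= window[1],
            !is.null(reads$qual))
  w <- window[2] - window[1] + 1L
  need <- as.integer(ceiling(min_frac * w))
  len <- nchar(reads$seq)
  too_short <- len < window[2] | is.na(reads$qual)
  tag_seq <- substr(reads$seq, window[1], window[2])
  tag_qual <- substr(reads$qual, window[1], window[2])
  n_pass <- integer(nrow(reads))
  ok_len <- which(!too_short)
  if (length(ok_len)) {
    thr <- min_q + 33L
    n_pass[ok_len] <- vapply(tag_qual[ok_len],
                             function(q) sum(utf8ToInt(q) >= thr),
                             integer(1), USE.NAMES = FALSE)
  }
  accept <- !too_short & n_pass >= need
  tags <- data.frame(id = reads$id[accept], seq = tag_seq[accept],
                     stringsAsFactors = FALSE)
  rejects <- data.frame(
    id = reads$id[!accept],
    reason = ifelse(too_short[!accept], "too_short", "low_quality"),
    stringsAsFactors = FALSE)
  list(tags = tags, rejects = rejects)
}

#' Randomly subsample tags without replacement
#'
#' Equal-sized tag samples per library put two datasets on the same footing
#' for proportion estimation. The selection is uniform without replacement
#' and fully determined by the seed.
#'
#' @param tags Tag `data.frame`.
#' @param n Sample size; must not exceed the number of tags.
#' @param seed Integer seed.
#' @return A `data.frame` of exactly `n` tags (input order preserved).
#' @export
subsample_tags <- function(tags, n, seed = 1L) {
  if (n > nrow(tags))
    stop("requested ", n, " tags but only ", nrow(tags), " are available")
  if (n == nrow(tags)) return(tags)
  idx <- with_seed(seed, sort(sample.int(nrow(tags), n)))
  out <- tags[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
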