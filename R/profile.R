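#' Pool clustered reads into repeat-family databases
#'
#' Merges the member reads of clusters carrying the same family label into
#' one read database per family; clusters without a label are pooled as
#' `"unclassified"`. These databases drive windowed repeat annotation of
#' query sequences.
#'
#' @param clusters A `read_clusters` object.
#' @param labels Named character vector mapping cluster labels (e.g.
#'   `"CL1"`) to family labels; clusters absent from `labels` go to
#'   `"unclassified"`.
#' @return Named list of read `data.frame`s, one per family.
#' @export
build_family_dbs <- function(clusters, labels = character(0)) {
  memb <- clusters$membership
  fam <- ifelse(memb$cluster %in% names(labels),
                labels[memb$cluster], "unclassified")
  if (anyDuplicated(memb$read_id))
    stop("read assigned to multiple clusters: ",
         memb$read_id[duplicated(memb$read_id)][1L])
  split_ids <- split(memb$read_id, fam)
  lapply(split_ids, function(ids)
    clusters$reads[clusters$reads$id %in% ids, , drop = FALSE])
}

# All distinct local alignments of `read` against `query` scoring at least
# min_score, found greedily: best alignment first, then recurse left and
# right of its query footprint.
align_all_hits <- function(read, query, min_score, q_offset = 0L) {
  if (nchar(query) < 20L) return(NULL)
  st <- .cpp_sw_pair(read, query)
  if (st[["score"]] < min_score) return(NULL)
  hit <- data.frame(q_start = st[["b_start"]] + q_offset,
                    q_end = st[["b_end"]] + q_offset,
                    score = st[["score"]])
  left <- if (st[["b_start"]] > 1L)
    align_all_hits(read, substr(query, 1L, st[["b_start"]] - 1L),
                   min_score, q_offset) else NULL
  right <- if (st[["b_end"]] < nchar(query))
    align_all_hits(read, substr(query, st[["b_end"]] + 1L, nchar(query)),
                   min_score, q_offset + st[["b_end"]]) else NULL
  rbind(hit, left, right)
}

#' Windowed repeat annotation of a query sequence
#'
#' Locally aligns every read of every family database to the query (both
#' strands; a read aligning at several distinct places contributes one hit
#' per alignment), keeps alignments with score at least `min_score` (match
#' +1 / mismatch -1 / gap -2), and converts per-base alignment depth into
#' copy numbers by dividing by the fold-coverage at which the reads sampled
#' the genome: depth at a position sampled once per haploid genome is
#' `coverage`, so `depth / coverage` estimates how many genomic copies of
#' the local sequence the read databases saw. Depth is averaged in sliding
#' windows.
#'
#' @param query Query sequence (character scalar) or a named length-1
#'   character vector.
#' @param databases Named list of read `data.frame`s from
#'   [build_family_dbs()].
#' @param coverage Fold-coverage of the genome by the database reads (> 0).
#' @param min_score Minimum local alignment score.
#' @param window,step Window width and step in bp (0-based half-open window
#'   coordinates in the output).
#' @param seed_k Length of the exact-match prefilter k-mer.
#' @return A `data.frame` with `query`, `win_start`, `win_end`, `family`,
#'   `hits` (mean alignment depth in the window) and `copies`
#'   (`hits / coverage`).
#' @export
profile_sequence <- function(query, databases, coverage, min_score = 50L,
                             window = 1000L, step = 100L, seed_k = 12L) {
  if (coverage <= 0) stop("coverage must be positive")
  qname <- if (!is.null(names(query))) names(query)[1L] else "query"
  query <- as.character(query[1L])
  n <- nchar(query)
  if (n < window) stop("query shorter than one window")
  qk <- unique(kmer_windows(query, seed_k))
  qenv <- new.env(hash = TRUE, size = max(29L, length(qk)))
  for (km in qk) assign(km, TRUE, envir = qenv)
  has_seed <- function(s) {
    w <- kmer_windows(s, seed_k)
    for (km in w) if (!is.null(get0(km, envir = qenv))) return(TRUE)
    FALSE
  }
  win_start <- seq(0L, n - window, by = step)
  win_end <- win_start + window
  pieces <- lapply(names(databases), function(famname) {
    db <- databases[[famname]]
    depth <- numeric(n)
    if (nrow(db)) {
      ivs <- list()
      for (i in seq_len(nrow(db))) {
        for (s in c(db$seq[i], revcomp(db$seq[i]))) {
          if (!has_seed(s)) next
          hits <- align_all_hits(s, query, min_score)
          if (!is.null(hits)) ivs[[length(ivs) + 1L]] <- hits
        }
      }
      if (length(ivs)) {
        iv <- do.call(rbind, ivs)
        depth <- .cpp_interval_depth(as.integer(iv$q_start),
                                     as.integer(iv$q_end), n)
      }
    }
    cumd <- c(0, cumsum(depth))
    hits <- (cumd[win_end + 1L] - cumd[win_start + 1L]) / window
    data.frame(query = qname, win_start = win_start, win_end = win_end,
               family = famname, hits = hits, copies = hits / coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
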