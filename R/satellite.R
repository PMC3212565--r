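#' k-mer census of sequence tags
#'
#' Counts every length-`k` window of every tag (once per occurrence); under
#' the `"both-strands"` policy the reverse complement of each window is
#' counted as well, making the spectrum strand-symmetric. Satellite
#' monomers are reconstructed from these counts.
#'
#' @param tags Tag `data.frame` (columns `id`, `seq`) or character vector of
#'   tag sequences.
#' @param k k-mer length (the useful range for 30-nt tags is 10-17).
#' @param strand_policy `"both-strands"` (default) or `"as-is"`.
#' @return An object of class `kmer_spectrum`: list with `k`, `counts`
#'   (named integer vector), `strand_policy`.
#' @export
kmer_census <- function(tags, k, strand_policy = c("both-strands", "as-is")) {
  strand_policy <- match.arg(strand_policy)
  seqs <- if (is.data.frame(tags)) tags$seq else tags
  if (length(seqs) && any(nchar(seqs) < k))
    stop("k = ", k, " exceeds the length of some tags")
  win <- kmer_windows(seqs, k)
  if (strand_policy == "both-strands" && length(win)) win <- c(win, revcomp(win))
  counts <- if (length(win)) table(win) else integer(0)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(k = as.integer(k), counts = counts,
                 strand_policy = strand_policy),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum: k =", x$k, ",", length(x$counts), "distinct k-mers,",
      "policy", x$strand_policy, "\n")
  invisible(x)
}

# Hash-backed count lookup (0 for absent k-mers).
spectrum_env <- function(spectrum) {
  env <- new.env(hash = TRUE, size = max(29L, length(spectrum$counts)))
  nm <- names(spectrum$counts)
  for (i in seq_along(nm)) assign(nm[i], spectrum$counts[[i]], envir = env)
  env
}

lookup_counts <- function(env, kmers) {
  vapply(kmers, function(km) {
    v <- get0(km, envir = env, ifnotfound = 0L)
    as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Reconstruct a satellite consensus monomer from a k-mer spectrum
#'
#' Greedy walk through the k-mer de Bruijn-like overlap structure: start at
#' the globally most frequent k-mer (on its lexicographically smaller
#' strand when the spectrum is strand-symmetric) and repeatedly extend by
#' the highest-count k-mer overlapping the current end by `k - 1` bases,
#' considering only k-mers whose count reaches `count_floor_frac` of the
#' spectrum maximum (which suppresses sequencing-error k-mers). The walk
#' terminates when it revisits a previously used k-mer — closing the
#' circular consensus of a tandem monomer — or when no continuation clears
#' the floor, in which case a linear fragment is reported. All ties are
#' broken lexicographically, so the result is fully determined by the
#' spectrum.
#'
#' @param spectrum A [kmer_census()] result.
#' @param count_floor_frac Extension floor as a fraction of the maximum
#'   k-mer count.
#' @return An object of class `consensus_monomer`: list with `sequence`
#'   (canonical rotation for circular results), `length`, `circular`,
#'   `support` (per-position frequency of the consensus base among spanning
#'   k-mers, aligned to `sequence`), `k`. Returns `NULL` (with a warning)
#'   when no k-mer clears the floor.
#' @export
reconstruct_monomer <- function(spectrum, count_floor_frac = 0.01) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  counts <- spectrum$counts
  if (!length(counts)) {
    warning("empty spectrum: no monomer")
    return(NULL)
  }
  k <- spectrum$k
  floor_count <- count_floor_frac * max(counts)
  env <- spectrum_env(spectrum)
  top <- max(counts)
  start_cands <- sort(names(counts)[counts == top])
  start <- start_cands[1L]
  if (spectrum$strand_policy == "both-strands") {
    rc <- revcomp(start)
    if (rc < start) start <- rc
  }
  path <- character(0)
  seen <- new.env(hash = TRUE)
  cur <- start
  step <- 0L
  max_steps <- length(counts) + 1L
  repeat {
    path <- c(path, cur)
    assign(cur, length(path), envir = seen)
    suffix <- substr(cur, 2L, k)
    nxt <- paste0(suffix, c("A", "C", "G", "T"))
    cnt <- lookup_counts(env, nxt)
    ok <- cnt >= floor_count & cnt > 0
    if (!any(ok)) {
      seq <- paste0(path[1L], paste0(substr(path[-1L], k, k), collapse = ""))
      return(structure(list(sequence = seq, length = nchar(seq),
                            circular = FALSE,
                            support = position_support(spectrum, seq, circular = FALSE),
                            k = k),
                       class = "consensus_monomer"))
    }
    best <- which(ok & cnt == max(cnt[ok]))[1L]  # which() is in A<C<G<T order
    cur <- nxt[best]
    prev_pos <- get0(cur, envir = seen, ifnotfound = NA_integer_)
    if (!is.na(prev_pos)) {
      cycle <- path[prev_pos:length(path)]
      seq <- paste0(substr(cycle, 1L, 1L), collapse = "")
      # canonical over both strands when the spectrum is strand-symmetric,
      # so the same monomer sampled in either orientation canonicalises
      # identically
      canon <- canonical_rotation(seq,
                                  both_strands = spectrum$strand_policy ==
                                    "both-strands")
      return(structure(list(sequence = canon, length = nchar(canon),
                            circular = TRUE,
                            support = position_support(spectrum, canon, circular = TRUE),
                            k = k),
                       class = "consensus_monomer"))
    }
    step <- step + 1L
    if (step > max_steps) stop("walk failed to terminate (corrupt spectrum?)")
  }
}

#' @export
print.consensus_monomer <- function(x, ...) {
  cat(if (x$circular) "Circular" else "Linear (fragment)",
      "consensus monomer:", x$length, "bp (k =", x$k, ")\n")
  cat(x$sequence, "\n")
  cat("min position support:", round(min(x$support), 3), "\n")
  invisible(x)
}

# Windows (as start offsets into the possibly-circular sequence) covering
# position p, and their k-mer strings.
consensus_windows <- function(seq, k, circular) {
  n <- nchar(seq)
  if (circular) {
    d <- paste0(seq, substr(seq, 1L, k - 1L))
    substring(d, seq_len(n), seq_len(n) + k - 1L)
  } else {
    m <- n - k + 1L
    substring(seq, seq_len(m), seq_len(m) + k - 1L)
  }
}

# Per-position frequency of the consensus base among spanning k-mers:
# counts of consensus windows covering p versus the same windows with the
# base at p substituted by each alternative.
position_support <- function(spectrum, seq, circular) {
  k <- spectrum$k
  n <- nchar(seq)
  env <- spectrum_env(spectrum)
  wins <- consensus_windows(seq, k, circular)
  wcnt <- lookup_counts(env, wins)
  nw <- length(wins)
  support <- numeric(n)
  alt_bases <- c("A", "C", "G", "T")
  for (p in seq_len(n)) {
    # windows covering position p: starts p-k+1 .. p (circular) bounded for linear
    starts <- (p - k + 1L):p
    if (circular) starts <- ((starts - 1L) %% n) + 1L else starts <- starts[starts >= 1L & starts <= nw]
    if (!length(starts)) { support[p] <- NA_real_; next }
    cons_mean <- mean(wcnt[starts])
    base <- substr(seq, p, p)
    alt_mean <- 0
    for (b in setdiff(alt_bases, base)) {
      aw <- vapply(starts, function(s) {
        w <- wins[s]
        off <- if (circular) ((p - s) %% n) + 1L else p - s + 1L
        substr(w, off, off) <- b
        w
      }, character(1))
      alt_mean <- alt_mean + mean(lookup_counts(env, aw))
    }
    tot <- cons_mean + alt_mean
    support[p] <- if (tot > 0) cons_mean / tot else NA_real_
  }
  support
}

#' Call sequence variants against a consensus monomer
#'
#' Detects positions where an alternative base is carried by a substantial
#' fraction of the spanning k-mers (an alternative path that diverges from
#' and rejoins the consensus), and merges adjacent variant positions into
#' variant records. The relative frequency of a variant is the count of its
#' substituted k-mers relative to consensus plus alternatives at the same
#' positions.
#'
#' @param spectrum The [kmer_census()] the consensus was built from.
#' @param consensus A [reconstruct_monomer()] result.
#' @param min_rel_freq Minimum relative frequency to report.
#' @return A `data.frame` with `start`, `end` (consensus coordinates),
#'   `sequence` (the variant bases) and `freq`; zero rows when no variant
#'   reaches the threshold.
#' @export
call_variants <- function(spectrum, consensus, min_rel_freq = 0.05) {
  stopifnot(inherits(consensus, "consensus_monomer"))
  if (min_rel_freq >= 1) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), freq = numeric(0)))
  }
  k <- spectrum$k
  seq <- consensus$sequence
  n <- nchar(seq)
  env <- spectrum_env(spectrum)
  wins <- consensus_windows(seq, k, consensus$circular)
  wcnt <- lookup_counts(env, wins)
  nw <- length(wins)
  var_base <- rep(NA_character_, n)
  var_freq <- rep(NA_real_, n)
  for (p in seq_len(n)) {
    starts <- (p - k + 1L):p
    if (consensus$circular) starts <- ((starts - 1L) %% n) + 1L
    else starts <- starts[starts >= 1L & starts <= nw]
    if (!length(starts)) next
    cons_mean <- mean(wcnt[starts])
    base <- substr(seq, p, p)
    best_b <- NA_character_; best_f <- 0
    for (b in setdiff(c("A", "C", "G", "T"), base)) {
      aw <- vapply(starts, function(s) {
        w <- wins[s]
        off <- if (consensus$circular) ((p - s) %% n) + 1L else p - s + 1L
        substr(w, off, off) <- b
        w
      }, character(1))
      am <- mean(lookup_counts(env, aw))
      f <- if (am + cons_mean > 0) am / (am + cons_mean) else 0
      if (f > best_f) { best_f <- f; best_b <- b }
    }
    if (!is.na(best_b) && best_f >= min_rel_freq && best_f < 0.5) {
      var_base[p] <- best_b
      var_freq[p] <- best_f
    }
  }
  hit <- which(!is.na(var_base))
  if (!length(hit)) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), freq = numeric(0)))
  }
  runs <- split(hit, cumsum(c(1L, diff(hit) != 1L)))
  do.call(rbind, lapply(runs, function(idx) {
    data.frame(start = idx[1L], end = idx[length(idx)],
               sequence = paste0(var_base[idx], collapse = ""),
               freq = mean(var_freq[idx]), stringsAsFactors = FALSE)
  }))
}

#' Select a conserved probe window on a consensus monomer
#'
#' Chooses the window (within the allowed length range, on the canonical
#' rotation of the consensus, wrapping around for circular monomers) that
#' maximises the minimum per-position support, breaking ties by the longest
#' window and then the leftmost start. In variant-targeting mode the window
#' must cover a given variant record and the probe carries the variant
#' bases, yielding probes that discriminate a subfamily from the consensus.
#'
#' @param consensus A [reconstruct_monomer()] result.
#' @param length_range Minimum and maximum probe length.
#' @param variant Optional single-row variant record from [call_variants()].
#' @return A list with `probe` (sequence), `start`, `length`, `min_support`.
#' @export
design_probe <- function(consensus, length_range = c(26L, 50L), variant = NULL) {
  stopifnot(inherits(consensus, "consensus_monomer"))
  n <- consensus$length
  if (n < length_range[1L])
    stop("consensus (", n, " bp) shorter than the minimum probe length")
  seq <- consensus$sequence
  support <- consensus$support
  if (!is.null(variant)) {
    substr(seq, variant$start, variant$end) <- variant$sequence
  }
  max_len <- min(length_range[2L], n)
  starts <- seq_len(if (consensus$circular) n else n)
  dseq <- if (consensus$circular) paste0(seq, seq) else seq
  dsupp <- if (consensus$circular) c(support, support) else support
  best <- NULL
  for (len in length_range[1L]:max_len) {
    for (s in starts) {
      if (!consensus$circular && s + len - 1L > n) next
      if (!is.null(variant) &&
          !(s <= variant$start && s + len - 1L >= variant$end)) next
      ms <- min(dsupp[s:(s + len - 1L)])
      if (is.null(best) || ms > best$min_support ||
          (ms == best$min_support && (len > best$length ||
                                      (len == best$length && s < best$start)))) {
        best <- list(probe = substr(dseq, s, s + len - 1L),
                     start = s, length = len, min_support = ms)
      }
    }
  }
  if (is.null(best)) stop("no admissible probe window")
  best
}
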