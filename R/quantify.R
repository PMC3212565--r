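#' Build a tag-assignment index over clustered long reads
#'
#' Prepares the data structures used to assign short sequence tags to read
#' clusters: an exact-match table of every tag-length window of every
#' clustered read (both strands), mapped to the winning cluster under the
#' assignment tie-break (larger cluster first, then smaller cluster id), and
#' a seed index of non-overlapping tag-piece k-mers that guarantees (by the
#' pigeonhole principle) that any tag within `max_mismatches <= 2` edits of
#' a read shares at least one exact 10-mer piece with it.
#'
#' @param clusters A `read_clusters` object.
#' @param tag_length Tag length in nt.
#' @return An object of class `tag_index`.
#' @export
build_tag_index <- function(clusters, tag_length = 30L) {
  memb <- clusters$membership
  stopifnot(nrow(memb) > 0)
  reads <- clusters$reads[clusters$reads$id %in% memb$read_id, , drop = FALSE]
  cl_of <- stats::setNames(memb$cluster, memb$read_id)
  sizes <- clusters$sizes
  cl_rank <- order(-as.integer(sizes), as.integer(sub("^CL", "", names(sizes))))
  # rank 1 = preferred cluster under the tie-break (larger size, smaller id)
  pref <- stats::setNames(seq_along(cl_rank), names(sizes)[cl_rank])

  fwd <- reads$seq
  rev <- revcomp(fwd)
  read_cluster <- as.character(cl_of[reads$id])

  window_table <- function(seqs) {
    wl <- lapply(seqs, function(s) {
      m <- nchar(s) - tag_length + 1L
      if (m < 1L) return(character(0))
      substring(s, seq_len(m), seq_len(m) + tag_length - 1L)
    })
    data.table::data.table(window = unlist(wl, use.names = FALSE),
                           cluster = rep(read_cluster, lengths(wl)))
  }
  exact <- data.table::rbindlist(list(window_table(fwd), window_table(rev)))
  exact[, rank := pref[cluster]]
  data.table::setorder(exact, window, rank)
  exact <- exact[!duplicated(window), .(window, cluster)]
  data.table::setkey(exact, window)

  piece_len <- 10L
  n_pieces <- tag_length %/% piece_len
  seed_table <- function(seqs, strand) {
    sl <- lapply(seqs, function(s) {
      m <- nchar(s) - piece_len + 1L
      if (m < 1L) return(character(0))
      substring(s, seq_len(m), seq_len(m) + piece_len - 1L)
    })
    data.table::data.table(kmer = unlist(sl, use.names = FALSE),
                           ridx = rep(seq_along(seqs), lengths(sl)),
                           pos = unlist(lapply(lengths(sl), seq_len), use.names = FALSE),
                           strand = strand)
  }
  seeds <- data.table::rbindlist(list(seed_table(fwd, "+"), seed_table(rev, "-")))
  data.table::setkey(seeds, kmer)

  structure(list(exact = exact, seeds = seeds, fwd = fwd, rev = rev,
                 read_cluster = read_cluster, pref = pref,
                 tag_length = tag_length, piece_len = piece_len,
                 n_pieces = n_pieces),
            class = "tag_index")
}

#' Assign sequence tags to read clusters
#'
#' Each tag is assigned to the cluster containing the clustered read with
#' the smallest edit distance to the tag (substitutions and gaps all cost
#' one), searched over both strands, provided that distance does not exceed
#' `max_mismatches`; otherwise the tag is unassigned. At equal best distance
#' across clusters the larger cluster wins, then the smaller cluster id.
#' Exact hits are resolved through a window hash; inexact hits through
#' pigeonhole-seeded banded alignment, which is exact for
#' `max_mismatches <= 2` with the index's 10-mer pieces.
#'
#' @param tags Tag `data.frame` (columns `id`, `seq`, all of the index's tag
#'   length).
#' @param index A [build_tag_index()] object.
#' @param max_mismatches Maximum edit distance (default 2).
#' @return A `data.frame` with `id`, `cluster` (`NA` when unassigned) and
#'   `distance` (`NA` when unassigned).
#' @export
assign_tags <- function(tags, index, max_mismatches = 2L) {
  stopifnot(inherits(index, "tag_index"),
            all(nchar(tags$seq) == index$tag_length))
  n <- nrow(tags)
  cluster <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  if (n == 0) return(data.frame(id = character(0), cluster = character(0),
                                distance = integer(0)))
  hit <- index$exact[data.table::data.table(window = tags$seq), on = "window",
                     mult = "first"]
  exact_ok <- !is.na(hit$cluster)
  cluster[exact_ok] <- hit$cluster[exact_ok]
  distance[exact_ok] <- 0L

  todo <- which(!exact_ok)
  if (length(todo) && max_mismatches > 0) {
    pl <- index$piece_len
    offs <- (seq_len(index$n_pieces) - 1L) * pl
    qt <- data.table::rbindlist(lapply(offs, function(o) {
      data.table::data.table(
        kmer = substr(tags$seq[todo], o + 1L, o + pl),
        tag = todo, off = o)
    }))
    cand <- index$seeds[qt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(cand)) {
      cand[, diag := pos - off]
      cand <- unique(cand[, .(tag, ridx, strand, diag)])
      subj <- ifelse(cand$strand == "+", index$fwd[cand$ridx], index$rev[cand$ridx])
      d <- .cpp_edit_infix_banded(tags$seq[cand$tag], subj, cand$diag,
                                  as.integer(max_mismatches) + 1L)
      cand[, dist := d]
      cand <- cand[dist <= max_mismatches]
      if (nrow(cand)) {
        cand[, cluster := index$read_cluster[ridx]]
        cand[, rank := index$pref[cluster]]
        best <- cand[, .(dist = min(dist)), by = tag]
        cand <- merge(cand, best, by = c("tag", "dist"))
        data.table::setorder(cand, tag, rank)
        cand <- cand[!duplicated(tag)]
        cluster[cand$tag] <- cand$cluster
        distance[cand$tag] <- cand$dist
      }
    }
  }
  data.frame(id = tags$id, cluster = cluster, distance = distance,
             stringsAsFactors = FALSE)
}

#' Brute-force tag assignment by exhaustive edit-distance scan
#'
#' Reference implementation that computes the semi-global edit distance of
#' every tag against every clustered read on both strands with a full
#' dynamic programme and applies the same acceptance threshold and
#' tie-break as [assign_tags()]. Used to validate the seeded index path.
#'
#' @inheritParams assign_tags
#' @param clusters A `read_clusters` object.
#' @return Same shape as [assign_tags()].
#' @export
assign_tags_bruteforce <- function(tags, clusters, max_mismatches = 2L) {
  memb <- clusters$membership
  reads <- clusters$reads[clusters$reads$id %in% memb$read_id, , drop = FALSE]
  cl_of <- stats::setNames(memb$cluster, memb$read_id)
  read_cluster <- as.character(cl_of[reads$id])
  sizes <- clusters$sizes
  pref_order <- names(sizes)[order(-as.integer(sizes),
                                   as.integer(sub("^CL", "", names(sizes))))]
  pref <- stats::setNames(seq_along(pref_order), pref_order)
  subj <- c(reads$seq, revcomp(reads$seq))
  subj_cluster <- rep(read_cluster, 2L)
  n <- nrow(tags)
  cluster <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    d <- .cpp_edit_infix(rep(tags$seq[i], length(subj)), subj)
    dmin <- min(d)
    if (dmin <= max_mismatches) {
      cls <- unique(subj_cluster[d == dmin])
      cluster[i] <- cls[which.min(pref[cls])]
      distance[i] <- dmin
    }
  }
  data.frame(id = tags$id, cluster = cluster, distance = distance,
             stringsAsFactors = FALSE)
}

#' Male/female abundance ratio statistic
#'
#' The statistic `p_male / (p_male + p_female)`: 0.5 for equal abundance, 0.67 for a
#' two-fold male excess, 0.25 for a three-fold female excess. Undefined
#' (`NA`) when both proportions are zero.
#'
#' @param p_male,p_female Genome proportions (any common scale).
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
mf_ratio <- function(p_male, p_female) {
  s <- p_male + p_female
  ifelse(s > 0, p_male / s, NA_real_)
}

#' Estimate per-cluster genome proportions from tag assignments
#'
#' Proportions are fractions of the sampled tags per library (so spike-in
#' tags count against the totals, as when controls are part of the
#' sequenced sample). Clusters whose mean proportion falls below the
#' reporting floor are flagged as unreliable.
#'
#' @param assign_male,assign_female Assignment `data.frame`s from
#'   [assign_tags()].
#' @param total_male,total_female Tag totals per library (default: number of
#'   rows of each assignment, i.e. all sampled tags).
#' @param clusters Optional `read_clusters` object used to attach the mean
#'   GC content of each cluster's long reads.
#' @param reporting_floor Minimum mean proportion for a reliable estimate
#'   (default 0.005% = 5e-5).
#' @return A `data.frame` of class `proportion_table`: `cluster`,
#'   `tags_male`, `tags_female`, `p_male`, `p_female`, `mf_ratio`, `gc`,
#'   `reliable`, ordered by cluster rank.
#' @export
quantify <- function(assign_male, assign_female,
                     total_male = nrow(assign_male),
                     total_female = nrow(assign_female),
                     clusters = NULL, reporting_floor = 5e-5) {
  if (total_male <= 0 || total_female <= 0) stop("tag totals must be positive")
  cm <- table(assign_male$cluster)
  cf <- table(assign_female$cluster)
  all_cl <- union(names(cm), names(cf))
  if (!is.null(clusters)) all_cl <- union(all_cl, names(clusters$sizes))
  all_cl <- all_cl[order(as.integer(sub("^CL", "", all_cl)))]
  tm <- as.integer(ifelse(all_cl %in% names(cm), cm[all_cl], 0L))
  tf <- as.integer(ifelse(all_cl %in% names(cf), cf[all_cl], 0L))
  out <- data.frame(cluster = all_cl, tags_male = tm, tags_female = tf,
                    p_male = tm / total_male, p_female = tf / total_female,
                    stringsAsFactors = FALSE)
  out$mf_ratio <- mf_ratio(out$p_male, out$p_female)
  out$gc <- NA_real_
  if (!is.null(clusters)) {
    gc_by_cl <- vapply(out$cluster, function(cl) {
      r <- cluster_reads(clusters, cl)
      if (!nrow(r)) return(NA_real_)
      stats::weighted.mean(gc_content(r$seq), nchar(r$seq))
    }, numeric(1))
    out$gc <- as.numeric(gc_by_cl)
  }
  out$reliable <- (out$p_male + out$p_female) / 2 >= reporting_floor
  attr(out, "total_male") <- total_male
  attr(out, "total_female") <- total_female
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' Flag sex-differential clusters using spike-in controls
#'
#' The spike-in controls define how far the male/female ratio statistic can
#' stray from its expectation through measurement alone. The calibration
#' envelope is the most extreme control deviation from 0.5 (controls with
#' asymmetric expectations contribute their full observed deviation,
#' augmented by their miss of the expectation), and clusters whose
#' `mf_ratio` deviates from 0.5 by more than that envelope are flagged as
#' genuinely sex-differential.
#'
#' @param table A `proportion_table` from [quantify()].
#' @param controls A `data.frame` with columns `cluster` (control cluster
#'   label), `expected_male`, `expected_female` (expected proportions).
#' @return The input table with logical column `flagged` (control clusters
#'   are never flagged) plus attributes `envelope` (the deviation threshold)
#'   and `controls` (per-control observed/expected report).
#' @export
calibrate_with_controls <- function(table, controls) {
  if (is.null(controls) || nrow(controls) == 0) {
    warning("no controls supplied: sex-differential flagging disabled")
    table$flagged <- NA
    return(table)
  }
  rows <- match(controls$cluster, table$cluster)
  if (anyNA(rows)) stop("control cluster(s) absent from table: ",
                        paste(controls$cluster[is.na(rows)], collapse = ", "))
  obs <- table$mf_ratio[rows]
  if (all(is.na(obs))) {
    warning("no control received any tags: flagging disabled")
    table$flagged <- NA
    return(table)
  }
  expd <- mf_ratio(controls$expected_male, controls$expected_female)
  dev_from_half <- abs(obs - 0.5)
  miss <- abs(obs - expd)
  envelope <- max(dev_from_half + ifelse(abs(expd - 0.5) < 1e-12, 0, miss),
                  na.rm = TRUE)
  table$flagged <- !is.na(table$mf_ratio) &
    abs(table$mf_ratio - 0.5) > envelope & table$reliable
  table$flagged[rows] <- FALSE
  attr(table, "envelope") <- envelope
  attr(table, "controls") <- data.frame(
    cluster = controls$cluster, expected_mf = expd, observed_mf = obs,
    deviation = miss, stringsAsFactors = FALSE)
  table
}

#' Copy number from a genome proportion
#'
#' `copies = proportion * genome_1C / unit_length`.
#'
#' @param proportion Genome proportion (fraction, not percent).
#' @param genome_1C Haploid genome size in bp.
#' @param unit_length Repeat unit length in bp (> 0).
#' @return Estimated copies per haploid genome.
#' @export
copy_number <- function(proportion, genome_1C, unit_length) {
  if (any(unit_length <= 0)) stop("unit_length must be positive")
  proportion * genome_1C / unit_length
}

#' Fold-coverage of a genome by sequencing
#'
#' @param total_bases Total sequenced bases.
#' @param genome_1C Haploid genome size in bp (> 0).
#' @return `total_bases / genome_1C`.
#' @export
genome_coverage <- function(total_bases, genome_1C) {
  if (any(genome_1C <= 0)) stop("genome_1C must be positive")
  total_bases / genome_1C
}

#' Expected male/female abundance ratio of a Y-dense repeat
#'
#' For a repeat present at unit density on the autosomes and the X
#' chromosome and at `fold` times that density on the Y, with the Y and X
#' occupying `y_frac` and `x_frac` of the male genome (the female genome
#' being autosomes plus two X), the male:female ratio of the repeat's
#' genome fractions is `(1 - x_frac - y_frac) + x_frac + fold * y_frac`.
#' With X = 7.5%, Y = 10% and a ten-fold Y density this is 1.9 — the scale
#' of total-DNA differences a chromosome-biased repeat can produce.
#'
#' @param y_frac,x_frac Fractions of the male genome on Y and X.
#' @param fold Density fold-increase on Y.
#' @return The male:female abundance ratio.
#' @export
sex_linked_abundance_ratio <- function(y_frac = 0.10, x_frac = 0.075, fold = 10) {
  stopifnot(y_frac >= 0, x_frac >= 0, y_frac + x_frac < 1, fold >= 0)
  a <- 1 - x_frac - y_frac
  # male fraction = (a + x + fold*y) * d / 1; female fraction = (a + 2x) d / (a + 2x) = d
  a + x_frac + fold * y_frac
}

#' GC-bias diagnostic for male/female proportion tables
#'
#' Library preparation and sequencing chemistry can sample GC-rich template
#' less (or more) efficiently in one library than the other, which shows up
#' as an association between cluster GC content and the deviation of the
#' male/female ratio statistic from 0.5. This reports the Spearman rank
#' correlation between `gc` and `mf_ratio - 0.5` with a seeded permutation
#' p-value (two-sided). A negative correlation means GC-rich clusters are
#' shifted toward the female library.
#'
#' @param table A `proportion_table` with a non-`NA` `gc` column.
#' @param n_perm Number of permutations (>= 999 recommended).
#' @param seed Integer seed for the permutations.
#' @return A list with `rho`, `p_value`, `n` (clusters used). `rho` is `NA`
#'   when GC is constant across clusters.
#' @export
gc_bias_diagnostic <- function(table, n_perm = 999L, seed = 1L) {
  ok <- !is.na(table$gc) & !is.na(table$mf_ratio)
  gc <- table$gc[ok]
  dev <- table$mf_ratio[ok] - 0.5
  n <- length(gc)
  if (n < 10L) stop("need at least 10 clusters with GC and mf_ratio")
  if (stats::sd(gc) == 0 || stats::sd(dev) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(gc, dev, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      stats::cor(gc, sample(dev), method = "spearman"), numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, n = n)
}
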