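#' Default per-position expected quality profiles
#'
#' Length-36 vectors of expected Phred scores for simulated short reads. The
#' first two and last four cycles are noticeably worse than the interior
#' (which is why quantification trims tags to positions 3-32), and the two
#' samples differ in overall quality: the female library is modelled as the
#' better sequencing run, so that with the two libraries' raw read counts it
#' yields about 1.7-fold more quality-filtered tags than the male library.
#'
#' @param sample `"male"` or `"female"`.
#' @return Numeric vector of 36 expected Phred scores.
#' @export
default_quality_profile <- function(sample = c("male", "female")) {
  sample <- match.arg(sample)
  interior <- if (sample == "male") 15.35 else 18.0
  c(rep(interior - 4, 2), rep(interior, 30), rep(interior - 6, 4))
}

#' Configure a read simulation
#'
#' @param platform `"long"` (shotgun reads of a few hundred bases, no
#'   qualities) or `"short"` (fixed 36-nt reads with per-base qualities).
#' @param n_reads Number of reads to draw.
#' @param mean_length,length_sd Gaussian read-length model for long reads
#'   (truncated at `[50, 2 * mean_length]`); short reads are always 36 nt.
#' @param sub_rate,ins_rate,del_rate Per-base error rates in `[0, 0.05]`.
#'   For short reads with `error_from_quality = TRUE` the substitution rate
#'   is instead derived per base from the simulated quality
#'   (`10^(-q/10)`), and `sub_rate` is ignored.
#' @param duplicate_rate Fraction of long reads that are exact copies of
#'   other emitted reads (emulating emulsion-PCR duplication artifacts).
#' @param gc_bias_slope Change in log sampling odds per unit GC fraction of
#'   the read; 0 means uniform sampling, positive values oversample GC-rich
#'   fragments.
#' @param quality_profile Per-position expected Phred scores (short reads);
#'   defaults to [default_quality_profile()]`("male")`.
#' @param quality_read_sd,quality_pos_sd Standard deviations of the
#'   read-level and per-position quality noise around the profile.
#' @param error_from_quality Couple short-read substitution errors to the
#'   simulated base qualities.
#' @param seed Integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(platform = c("long", "short"), n_reads,
                            mean_length = 250, length_sd = 60,
                            sub_rate = 0, ins_rate = 0, del_rate = 0,
                            duplicate_rate = 0, gc_bias_slope = 0,
                            quality_profile = default_quality_profile("male"),
                            quality_read_sd = 5, quality_pos_sd = 2,
                            error_from_quality = TRUE, seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(n_reads >= 0,
            sub_rate >= 0, sub_rate <= 0.05,
            ins_rate >= 0, ins_rate <= 0.05,
            del_rate >= 0, del_rate <= 0.05,
            duplicate_rate >= 0, duplicate_rate <= 0.2)
  if (platform == "short") {
    mean_length <- 36
    length_sd <- 0
    stopifnot(length(quality_profile) == 36)
  }
  structure(list(platform = platform, n_reads = as.integer(n_reads),
                 mean_length = mean_length, length_sd = length_sd,
                 sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 duplicate_rate = duplicate_rate, gc_bias_slope = gc_bias_slope,
                 quality_profile = quality_profile,
                 quality_read_sd = quality_read_sd,
                 quality_pos_sd = quality_pos_sd,
                 error_from_quality = error_from_quality,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

# Apply substitution/insertion/deletion errors to one sequence.
apply_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate <= 0 && ins_rate <= 0 && del_rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  alt <- c("A", "C", "G", "T")
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    for (i in hit) bases[i] <- sample(setdiff(alt, bases[i]), 1L)
  }
  if (del_rate > 0) {
    keep <- stats::runif(length(bases)) >= del_rate
    bases <- bases[keep]
  }
  if (ins_rate > 0) {
    ins <- which(stats::runif(length(bases)) < ins_rate)
    if (length(ins)) {
      out <- character(0); prev <- 1L
      for (i in ins) {
        out <- c(out, bases[prev:i], sample(alt, 1L))
        prev <- i + 1L
      }
      if (prev <= length(bases)) out <- c(out, bases[prev:length(bases)])
      bases <- out
    }
  }
  paste(bases, collapse = "")
}

#' Simulate shotgun reads from a genome sequence
#'
#' Draws read start positions uniformly (or with GC-dependent sampling odds
#' when `gc_bias_slope != 0`), samples both strands with probability 0.5,
#' applies the configured error model and, for long reads, duplicates a
#' configured fraction of reads to emulate amplification artifacts. Short
#' reads receive per-base Phred qualities drawn around the configured
#' per-position profile.
#'
#' @param genome A single character string (genome sequence).
#' @param config A [read_sim_config()].
#' @param id_prefix Prefix for read identifiers.
#' @return A `data.frame` with columns `id`, `seq`, `qual` (character Phred+33
#'   string, `NA` for long reads), `start`, `strand`, `is_duplicate`, and
#'   attribute `platform`.
#' @export
simulate_reads <- function(genome, config, id_prefix = "read") {
  stopifnot(inherits(config, "read_sim_config"), nchar(genome) > 0)
  n <- config$n_reads
  if (n == 0) {
    warning("n_reads = 0: returning an empty read set")
    out <- data.frame(id = character(0), seq = character(0), qual = character(0),
                      start = integer(0), strand = character(0),
                      is_duplicate = logical(0), stringsAsFactors = FALSE)
    attr(out, "platform") <- config$platform
    return(out)
  }
  G <- nchar(genome)
  with_seed(config$seed, {
    draw_fragments <- function(m) {
      if (config$platform == "long") {
        len <- round(stats::rnorm(m, config$mean_length, config$length_sd))
        len <- pmin(pmax(len, 50L), 2L * config$mean_length, G)
      } else {
        len <- rep(36L, m)
        if (G < 36L) stop("genome shorter than the 36-nt read length")
      }
      start <- floor(stats::runif(m, 1, G - len + 2))
      data.frame(start = as.integer(start), len = as.integer(len))
    }
    if (config$gc_bias_slope != 0) {
      cand <- draw_fragments(4L * n)
      frag <- substring(genome, cand$start, cand$start + cand$len - 1L)
      w <- exp(config$gc_bias_slope * gc_content(frag))
      pick <- sample.int(nrow(cand), n, prob = w)
      frags <- cand[pick, , drop = FALSE]
    } else {
      frags <- draw_fragments(n)
    }
    seqs <- substring(genome, frags$start, frags$start + frags$len - 1L)
    minus <- stats::runif(n) < 0.5
    seqs[minus] <- revcomp(seqs[minus])
    strand <- ifelse(minus, "-", "+")
    qual <- rep(NA_character_, n)

    if (config$platform == "short") {
      prof <- config$quality_profile
      roff <- stats::rnorm(n, 0, config$quality_read_sd)
      qmat <- matrix(round(rep(prof, each = n) + roff +
                             stats::rnorm(n * 36L, 0, config$quality_pos_sd)),
                     nrow = n)
      qmat[qmat < 2] <- 2L; qmat[qmat > 41] <- 41L
      if (config$error_from_quality) {
        perr <- 10^(-qmat / 10)
        err <- matrix(stats::runif(n * 36L) < perr, nrow = n)
        if (any(err)) {
          chm <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = n, byrow = TRUE)
          alt <- c("A", "C", "G", "T")
          idx <- which(err)
          chm[idx] <- vapply(chm[idx], function(b) sample(setdiff(alt, b), 1L),
                             character(1))
          seqs <- apply(chm, 1L, paste, collapse = "")
        }
      } else if (config$sub_rate > 0) {
        seqs <- vapply(seqs, apply_errors, character(1),
                       config$sub_rate, 0, 0, USE.NAMES = FALSE)
      }
      qual <- vapply(seq_len(n), function(i)
        rawToChar(as.raw(qmat[i, ] + 33L)), character(1))
    } else {
      if (config$sub_rate > 0 || config$ins_rate > 0 || config$del_rate > 0)
        seqs <- vapply(seqs, apply_errors, character(1),
                       config$sub_rate, config$ins_rate, config$del_rate,
                       USE.NAMES = FALSE)
    }

    is_dup <- rep(FALSE, n)
    if (config$platform == "long" && config$duplicate_rate > 0 && n > 1) {
      dup <- which(stats::runif(n) < config$duplicate_rate)
      dup <- dup[dup > 1L]
      for (i in dup) {
        src <- sample.int(i - 1L, 1L)
        seqs[i] <- seqs[src]
        frags$start[i] <- frags$start[src]
        strand[i] <- strand[src]
        is_dup[i] <- TRUE
      }
    }

    out <- data.frame(id = sprintf("%s_%06d", id_prefix, seq_len(n)),
                      seq = seqs, qual = qual, start = frags$start,
                      strand = strand, is_duplicate = is_dup,
                      stringsAsFactors = FALSE)
    attr(out, "platform") <- config$platform
    out
  })
}

#' Add spike-in control reads to a read pool
#'
#' Appends reads sampled from foreign control sequences so that the expected
#' base fraction of each control among all reads in the augmented pool
#' equals its requested mass fraction. This emulates adding known amounts of
#' control DNA to a sample before sequencing (e.g. two phage DNAs at a 3:1
#' mass ratio totalling 3% of the sample).
#'
#' @param reads A read pool from [simulate_reads()].
#' @param controls Named character vector of control sequences.
#' @param mass_fractions Numeric vector (same length/names as `controls`) of
#'   requested mass fractions of the final pool; total must be < 0.5.
#' @param config The [read_sim_config()] used for the genomic reads (controls
#'   are sequenced with the same platform and error model).
#' @param seed Seed for control read sampling.
#' @param id_prefix Infix used in control read identifiers (keep distinct
#'   across pools that will be combined).
#' @return The augmented pool with an extra column `control` (control name or
#'   `NA`) and attribute `spike_in_truth`, a data.frame of requested and
#'   realized base fractions per control.
#' @export
add_spike_ins <- function(reads, controls, mass_fractions, config, seed = 1L,
                          id_prefix = "spk") {
  stopifnot(length(controls) == length(mass_fractions), all(mass_fractions >= 0),
            sum(mass_fractions) < 0.5)
  if (any(nchar(controls) == 0)) stop("empty control sequence")
  if (is.null(names(controls))) names(controls) <- paste0("control", seq_along(controls))
  names(mass_fractions) <- names(controls)
  reads$control <- rep(NA_character_, nrow(reads))
  if (all(mass_fractions == 0)) {
    attr(reads, "spike_in_truth") <- data.frame(
      control = names(controls), requested = mass_fractions,
      realized = 0, stringsAsFactors = FALSE)
    return(reads)
  }
  genomic_bp <- sum(nchar(reads$seq))
  total_bp <- genomic_bp / (1 - sum(mass_fractions))
  pieces <- list(reads)
  realized <- numeric(length(controls))
  for (i in seq_along(controls)) {
    target_bp <- mass_fractions[i] * total_bp
    if (target_bp <= 0) next
    mean_len <- if (config$platform == "short") 36 else config$mean_length
    n_i <- max(1L, round(target_bp / mean_len))
    cfg <- config
    cfg$n_reads <- as.integer(n_i)
    cfg$gc_bias_slope <- 0
    cfg$duplicate_rate <- 0
    cfg$seed <- derive_seed(seed, i)
    ctrl_reads <- simulate_reads(controls[[i]], cfg,
                                 id_prefix = paste0(names(controls)[i], "_",
                                                    id_prefix))
    ctrl_reads$control <- names(controls)[i]
    realized[i] <- sum(nchar(ctrl_reads$seq))
    pieces[[length(pieces) + 1L]] <- ctrl_reads
  }
  out <- do.call(rbind, pieces)
  attr(out, "platform") <- attr(reads, "platform")
  attr(out, "spike_in_truth") <- data.frame(
    control = names(controls), requested = as.numeric(mass_fractions),
    realized = realized / sum(nchar(out$seq)), stringsAsFactors = FALSE)
  out
}

#' Label simulated reads with their source repeat family
#'
#' Assigns each read the planted family whose coordinates overlap the read's
#' sampled interval the most (at least half the read); reads from single-copy
#' sequence are labelled `"background"` and spike-in reads keep their control
#' name.
#'
#' @param reads Read pool from [simulate_reads()] (optionally augmented by
#'   [add_spike_ins()]).
#' @param pair The [build_genome_pair()] result the reads were drawn from.
#' @param sex `"male"` or `"female"`: which genome the reads came from.
#' @return Character vector of family labels, parallel to `reads`.
#' @export
label_reads <- function(reads, pair, sex) {
  co <- pair$coords[pair$coords$sex == sex, , drop = FALSE]
  len <- nchar(reads$seq)
  lab <- rep("background", nrow(reads))
  if (nrow(co)) {
    q <- IRanges::IRanges(start = reads$start, width = pmax(len, 1L))
    s <- IRanges::IRanges(start = co$start, end = co$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                              s[S4Vectors::subjectHits(ov)]))
      dt <- data.table::data.table(read = S4Vectors::queryHits(ov),
                                   fam = co$family[S4Vectors::subjectHits(ov)],
                                   w = w)
      best <- dt[, .(fam = fam[which.max(w)], w = max(w)), by = read]
      keep <- best$w >= len[best$read] / 2
      lab[best$read[keep]] <- best$fam[keep]
    }
  }
  if (!is.null(reads$control)) lab[!is.na(reads$control)] <- reads$control[!is.na(reads$control)]
  lab
}
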