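#' Describe a simulated repeat family
#'
#' A declarative description of one repeat family to be planted in a
#' simulated genome pair. Four kinds are supported: `dispersed` elements
#' (copies scattered between stretches of single-copy background, emulating
#' retroelements), `tandem` satellites (one contiguous head-to-tail array of
#' the monomer), `rdna_like` units (a tandem array of a composite unit whose
#' intergenic spacer embeds its own short tandem subrepeat block, emulating
#' satellites that originate inside the rDNA spacer), and `spike_in`
#' sequences (foreign control DNA that is never placed in the genome but is
#' added to read pools at known mass fractions).
#'
#' @param name Family label.
#' @param kind One of `"dispersed"`, `"tandem"`, `"rdna_like"`, `"spike_in"`.
#' @param unit_length Monomer/unit length in bp (>= 20).
#' @param copies_male,copies_female Copy numbers per haploid genome.
#' @param divergence Per-site substitution rate applied independently to each
#'   copy relative to the family master sequence, in `[0, 0.3]`.
#' @param gc_target GC fraction of the master sequence, in `[0.2, 0.8]`.
#' @param monomer_variants Optional list of planted monomer variants, each a
#'   `list(pos =, base =, freq =)`: at each copy, with probability `freq` the
#'   base at `pos` is replaced by `base`. Frequencies must sum to <= 1.
#' @param subrepeat_length For `rdna_like` only: monomer length of the tandem
#'   subrepeat embedded in the spacer (default 40 bp).
#' @return An object of class `repeat_family`.
#' @export
repeat_family <- function(name, kind = c("dispersed", "tandem", "rdna_like", "spike_in"),
                          unit_length, copies_male, copies_female = copies_male,
                          divergence = 0, gc_target = 0.4,
                          monomer_variants = NULL, subrepeat_length = 40L) {
  kind <- match.arg(kind)
  stopifnot(unit_length >= 20, copies_male >= 0, copies_female >= 0,
            divergence >= 0, divergence <= 0.3,
            gc_target >= 0.2, gc_target <= 0.8)
  if (!is.null(monomer_variants)) {
    freqs <- vapply(monomer_variants, `[[`, numeric(1), "freq")
    stopifnot(all(freqs > 0), sum(freqs) <= 1)
  }
  structure(list(name = name, kind = kind, unit_length = as.integer(unit_length),
                 copies_male = as.integer(copies_male),
                 copies_female = as.integer(copies_female),
                 divergence = divergence, gc_target = gc_target,
                 monomer_variants = monomer_variants,
                 subrepeat_length = as.integer(subrepeat_length)),
            class = "repeat_family")
}

#' Describe a simulated male/female genome pair
#'
#' @param families List of [repeat_family()] objects.
#' @param genome_1C_male,genome_1C_female Haploid genome sizes in bp. The
#'   single-copy background (shared between the sexes) fills whatever the
#'   repeat families do not occupy in the female genome; any male size
#'   beyond his repeats plus that shared background becomes male-specific
#'   background (see [build_genome_pair()]).
#' @param background_gc GC fraction of the i.i.d. single-copy background.
#' @param seed Integer seed; a fixed seed yields byte-identical genomes.
#' @return An object of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(families, genome_1C_male, genome_1C_female = genome_1C_male,
                            background_gc = 0.37, seed = 1L) {
  stopifnot(length(families) > 0, genome_1C_male > 0, genome_1C_female > 0)
  stopifnot(all(vapply(families, inherits, logical(1), "repeat_family")))
  nm <- vapply(families, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate family names: ", nm[duplicated(nm)][1])
  structure(list(families = families, genome_1C_male = genome_1C_male,
                 genome_1C_female = genome_1C_female,
                 background_gc = background_gc, seed = as.integer(seed)),
            class = "genome_sim_spec")
}

# One mutated copy of a master monomer, with planted variants applied.
make_copy <- function(master, divergence, variants = NULL) {
  s <- mutate_sequence(master, divergence)
  if (!is.null(variants)) {
    for (v in variants) {
      if (stats::runif(1) < v$freq) substr(s, v$pos, v$pos) <- v$base
    }
  }
  s
}

# Master sequence of one family. For rdna_like the unit is a composite:
# gene-like half followed by a spacer whose central block is a tandem array
# of a short subrepeat monomer.
make_master <- function(fam) {
  if (fam$kind != "rdna_like") return(random_dna(fam$unit_length, fam$gc_target))
  gene_len <- floor(fam$unit_length * 0.5)
  igs_len <- fam$unit_length - gene_len
  sub_block <- floor(igs_len * 0.5)
  n_sub <- max(2L, floor(sub_block / fam$subrepeat_length))
  sub_monomer <- random_dna(fam$subrepeat_length, fam$gc_target)
  sub_array <- paste(rep(sub_monomer, n_sub), collapse = "")
  pad <- igs_len - nchar(sub_array)
  left <- floor(pad / 2)
  unit <- paste0(random_dna(gene_len, min(0.8, fam$gc_target + 0.15)),
                 random_dna(left, fam$gc_target), sub_array,
                 random_dna(pad - left, fam$gc_target))
  stopifnot(nchar(unit) == fam$unit_length)
  attr(unit, "subrepeat") <- sub_monomer
  unit
}

#' Build a simulated male/female genome pair with known repeat truth
#'
#' Plants every non-spike-in family of the spec into a shared genome layout:
#' tandem and rDNA-like families as one contiguous head-to-tail array, and
#' dispersed families as individual copies interleaved with single-copy
#' background. All copies of a family derive from a single master sequence
#' mutated at the family divergence, and the two sexes share the background
#' and the layout — as real male/female genomes of one species share their
#' autosomes. A family with more copies in one sex carries the extra copies
#' only in that sex's genome, and any male genome size beyond the shared
#' sequence is filled with male-specific (Y-like) background. The declared
#' sizes must therefore satisfy
#' `genome_1C_male - footprint_male >= genome_1C_female - footprint_female`
#' (the male genome is never smaller once repeats are removed).
#'
#' @param spec A [genome_sim_spec()].
#' @return A list of class `genome_pair` with elements `male` and `female`
#'   (character genome sequences), `truth` (per-family data.frame with copy
#'   numbers, occupied bp and exact true genome proportions per sex),
#'   `coords` (per-copy coordinate table: sex, family, start, end),
#'   `controls` (named character vector of spike-in master sequences),
#'   `masters` (family master sequences) and the spec itself.
#' @export
build_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  with_seed(spec$seed, {
    fams <- spec$families
    genomic <- fams[vapply(fams, `[[`, character(1), "kind") != "spike_in"]
    spikes <- fams[vapply(fams, `[[`, character(1), "kind") == "spike_in"]
    masters <- lapply(fams, make_master)
    names(masters) <- vapply(fams, `[[`, character(1), "name")

    footprint <- function(sex) {
      sum(vapply(genomic, function(f)
        f[[paste0("copies_", sex)]] * f$unit_length, numeric(1)))
    }
    fp_m <- footprint("male"); fp_f <- footprint("female")
    bg_shared <- spec$genome_1C_female - fp_f
    if (bg_shared < 0)
      stop("family footprint (", fp_f, " bp) exceeds genome size (",
           spec$genome_1C_female, " bp) for female genome")
    male_pad <- spec$genome_1C_male - fp_m - bg_shared
    if (male_pad < 0)
      stop("family footprint (", fp_m, " bp) plus shared background (",
           bg_shared, " bp) exceeds genome size (", spec$genome_1C_male,
           " bp) for male genome")

    # placement units over the larger copy count per family; each unit keeps
    # per-copy sequences so a sex can take a prefix of the copies
    units <- list()
    for (fam in genomic) {
      n_max <- max(fam$copies_male, fam$copies_female)
      if (n_max == 0) next
      cps <- vapply(seq_len(n_max), function(i)
        make_copy(as.character(masters[[fam$name]]), fam$divergence,
                  fam$monomer_variants), character(1))
      if (fam$kind %in% c("tandem", "rdna_like")) {
        units[[length(units) + 1L]] <- list(family = fam$name, copies = cps,
                                            tandem = TRUE, index = 1L)
      } else {
        for (i in seq_len(n_max))
          units[[length(units) + 1L]] <- list(family = fam$name,
                                              copies = cps[i],
                                              tandem = FALSE, index = i)
      }
    }
    units <- units[sample.int(length(units))]
    n_gap <- length(units) + 1L
    cuts <- if (bg_shared > 0)
      sort(sample.int(bg_shared + 1L, n_gap - 1L, replace = TRUE) - 1L)
    else rep(0L, n_gap - 1L)
    gap_sizes <- diff(c(0L, cuts, bg_shared))
    gaps <- lapply(gap_sizes, function(n)
      if (n > 0) random_dna(n, spec$background_gc) else "")
    pad <- if (male_pad > 0) random_dna(male_pad, spec$background_gc) else ""

    copies_of <- stats::setNames(
      lapply(genomic, function(f) c(male = f$copies_male,
                                    female = f$copies_female)),
      vapply(genomic, `[[`, character(1), "name"))

    assemble <- function(sex) {
      segs <- character(0); coord <- list(); pos <- 1L
      for (i in seq_along(units)) {
        if (gap_sizes[i] > 0) {
          segs <- c(segs, gaps[[i]])
          pos <- pos + gap_sizes[i]
        }
        u <- units[[i]]
        n_sex <- copies_of[[u$family]][[sex]]
        s <- if (u$tandem) {
          if (n_sex > 0) paste(u$copies[seq_len(n_sex)], collapse = "") else ""
        } else {
          if (u$index <= n_sex) u$copies else ""
        }
        if (nchar(s) > 0) {
          segs <- c(segs, s)
          coord[[length(coord) + 1L]] <- data.frame(
            sex = sex, family = u$family, start = pos,
            end = pos + nchar(s) - 1L, stringsAsFactors = FALSE)
          pos <- pos + nchar(s)
        }
      }
      if (gap_sizes[n_gap] > 0) segs <- c(segs, gaps[[n_gap]])
      if (sex == "male" && male_pad > 0) segs <- c(segs, pad)
      list(seq = paste(segs, collapse = ""),
           coords = if (length(coord)) do.call(rbind, coord) else
             data.frame(sex = character(0), family = character(0),
                        start = integer(0), end = integer(0)))
    }

    male <- assemble("male")
    female <- assemble("female")
    stopifnot(nchar(male$seq) == spec$genome_1C_male,
              nchar(female$seq) == spec$genome_1C_female)

    truth <- do.call(rbind, lapply(genomic, function(fam) {
      bp_m <- fam$copies_male * fam$unit_length
      bp_f <- fam$copies_female * fam$unit_length
      data.frame(family = fam$name, kind = fam$kind, unit_length = fam$unit_length,
                 copies_male = fam$copies_male, copies_female = fam$copies_female,
                 bp_male = bp_m, bp_female = bp_f,
                 prop_male = bp_m / spec$genome_1C_male,
                 prop_female = bp_f / spec$genome_1C_female,
                 gc = gc_content(as.character(masters[[fam$name]])),
                 stringsAsFactors = FALSE)
    }))

    controls <- vapply(spikes, function(fam) as.character(masters[[fam$name]]),
                       character(1))
    names(controls) <- vapply(spikes, `[[`, character(1), "name")

    structure(list(male = male$seq, female = female$seq, truth = truth,
                   coords = rbind(male$coords, female$coords),
                   controls = controls, masters = masters, spec = spec),
              class = "genome_pair")
  })
}

#' @export
print.genome_pair <- function(x, ...) {
  cat("Simulated genome pair: male", format(nchar(x$male), big.mark = ","),
      "bp / female", format(nchar(x$female), big.mark = ","), "bp\n")
  cat(nrow(x$truth), "planted families,", length(x$controls), "spike-in controls\n")
  print(x$truth[, c("family", "kind", "unit_length", "copies_male",
                    "copies_female", "prop_male", "prop_female")], ...)
  invisible(x)
}
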