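#' Published repeat-composition estimates for *Silene latifolia*
#'
#' Loads the bundled table of male/female genome proportions (percent of
#' the genome) estimated for the major *S. latifolia* repeat lineages and
#' families by low-pass-sequencing quantification. Leaf rows are individual
#' families; `subtotal` rows are the published per-category aggregates
#' (which include minor clades not broken out as leaf rows).
#'
#' @return A `data.frame` with columns `category`, `lineage`, `family`,
#'   `level` (`leaf` / `subtotal` / `total`), `prop_male`, `prop_female`.
#' @export
repeat_composition <- function() {
  path <- system.file("extdata", "silene_repeat_composition.tsv",
                      package = "replowpass", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "")
}

#' Summary statistics of a repeat-composition table
#'
#' Computes, averaging the two sexes: the Ty3/gypsy to Ty1/copia genome
#' proportion ratio, the total LTR-retrotransposon proportion
#' (gypsy + copia), and the per-sex satellite proportion summed over the
#' satellite families.
#'
#' @param tab A table shaped like [repeat_composition()].
#' @return A list with `gypsy_copia_ratio`, `ltr_total_percent`,
#'   `satellite_percent_male`, `satellite_percent_female`.
#' @export
composition_stats <- function(tab = repeat_composition()) {
  sub <- function(lin) tab[tab$level == "subtotal" &
                             !is.na(tab$lineage) & tab$lineage == lin, ]
  gypsy <- sub("Ty3_gypsy")
  copia <- sub("Ty1_copia")
  stopifnot(nrow(gypsy) == 1, nrow(copia) == 1)
  gypsy_mean <- mean(c(gypsy$prop_male, gypsy$prop_female))
  copia_mean <- mean(c(copia$prop_male, copia$prop_female))
  sat <- tab[tab$level == "leaf" & tab$category == "Satellites", ]
  list(gypsy_copia_ratio = gypsy_mean / copia_mean,
       ltr_total_percent = gypsy_mean + copia_mean,
       satellite_percent_male = sum(sat$prop_male),
       satellite_percent_female = sum(sat$prop_female))
}
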