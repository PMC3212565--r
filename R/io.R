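#' Read and write pipeline sequence files
#'
#' Thin wrappers around Biostrings I/O that convert between the package's
#' plain `data.frame` read representation (`id`, `seq`, optional `qual` in
#' Phred+33) and FASTA/FASTQ on disk.
#'
#' @param reads Read `data.frame` (columns `id`, `seq`, optionally `qual`).
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a read
#'   `data.frame`.
#' @name sequence_io
NULL

#' @rdname sequence_io
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

#' @rdname sequence_io
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(!is.null(reads$qual), !anyNA(reads$qual))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_reads_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' @rdname sequence_io
#' @export
write_tags_tsv <- function(reads, path) {
  utils::write.table(reads[, c("id", "seq")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_tags_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
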