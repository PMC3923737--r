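#' Read a FASTQ file into a data frame
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' per-read representation used throughout the package.
#'
#' @param path FASTQ file (Phred+33).
#' @return data.frame with columns `id`, `seq` (DNA alphabet as stored)
#'   and `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::DNAStringSet(norm_dna(reads$seq))
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#'
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet]; RNA-alphabet files are accepted
#'   (U is read as T by coercion).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  Biostrings::DNAStringSet(norm_dna(as.character(seqs)))
}

#' Write sequences to a FASTA file
#'
#' @param x named character vector or XStringSet.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the `>tag<i>_x<count>` convention so that redundancy
#' survives the round trip.
#'
#' @param tags data.frame with columns `sequence` (RNA) and `count`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  x <- setNames(norm_dna(tags$sequence),
                sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count))
  write_fasta(x, path)
}

#' Read collapsed tags from FASTA
#'
#' Inverse of [write_tags_fasta()]; counts are parsed from the `_x<count>`
#' header suffix (1 when absent).
#'
#' @param path FASTA file of collapsed tags.
#' @return data.frame with columns `sequence` (RNA), `count`, `length`.
#' @export
read_tags_fasta <- function(path) {
  x <- read_fasta(path)
  cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", names(x))))
  cnt[is.na(cnt)] <- 1L
  seqs <- norm_rna(as.character(x))
  data.frame(sequence = seqs, count = cnt, length = nchar(seqs),
             stringsAsFactors = FALSE, row.names = NULL)
}

# TSV writer shared by the report emitters (internal)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
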