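#' Quality filter for raw sRNA reads
#'
#' Retains reads whose *mean* Phred score is at least `min_q` (boundary
#' inclusive) and whose sequence contains no N. The quality statistic is
#' the read mean; a per-base interpretation is available through
#' `per_base = TRUE`.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33), as from
#'   [read_fastq()].
#' @param min_q Phred threshold (default 13).
#' @param per_base if TRUE require every base to reach `min_q` instead of
#'   the mean.
#' @return the retained rows of `reads`.
#' @export
quality_filter <- function(reads, min_q = 13, per_base = FALSE) {
  if (nrow(reads) == 0) return(reads)
  if (!all(nchar(reads$seq) == nchar(reads$qual)))
    stop("quality_filter(): quality strings must match sequence lengths")
  scores <- lapply(reads$qual, function(q) utf8ToInt(q) - 33L)
  stat <- if (per_base) vapply(scores, min, numeric(1))
          else vapply(scores, mean, numeric(1))
  keep <- stat >= min_q & !grepl("[Nn]", reads$seq)
  reads[keep, , drop = FALSE]
}

#' Trim adapter sequences
#'
#' Removes the longest suffix of each read that overlaps a prefix of the 3'
#' adapter by at least `min_overlap` nt with at most one mismatch per 10 nt
#' of overlap; the mirrored rule trims a 5' adapter first when one is
#' given. Reads without a qualifying overlap pass through unchanged.
#'
#' @param reads data.frame with `id`, `seq` and optionally `qual`.
#' @param adapter_3p 3' adapter sequence ("" to skip).
#' @param adapter_5p 5' adapter sequence ("" to skip).
#' @param min_overlap minimum overlap, nt.
#' @return `reads` with trimmed `seq` (and `qual`, kept in register).
#' @export
trim_adapters <- function(reads, adapter_3p, adapter_5p = "",
                          min_overlap = 6) {
  if (nrow(reads) == 0) return(reads)
  if (nchar(adapter_3p) == 0 && nchar(adapter_5p) == 0) return(reads)
  ov <- .trim_overlaps_cpp(norm_dna(reads$seq), norm_dna(adapter_3p),
                           norm_dna(adapter_5p), as.integer(min_overlap))
  n <- nchar(reads$seq)
  from <- ov[, 1] + 1L
  to <- n - ov[, 2]
  reads$seq <- substring(reads$seq, from, to)
  if (!is.null(reads$qual)) reads$qual <- substring(reads$qual, from, to)
  reads
}

#' Length filter
#'
#' Retains reads or tags whose length lies in `[min_len, max_len]`
#' (bounds inclusive).
#'
#' @param x data.frame with a `seq` or `sequence` column.
#' @param min_len,max_len length window, nt (defaults 18-25).
#' @return the retained rows.
#' @export
length_filter <- function(x, min_len = 18, max_len = 25) {
  if (min_len > max_len)
    stop("length_filter(): min_len must not exceed max_len")
  col <- if ("sequence" %in% names(x)) "sequence" else "seq"
  n <- nchar(x[[col]])
  x[n >= min_len & n <= max_len, , drop = FALSE]
}

#' Collapse reads to unique tags
#'
#' One tag per distinct sequence (after normalization to the RNA alphabet),
#' with its redundancy count. Counts sum to the input read count.
#'
#' @param reads data.frame with a `seq` column, or a character vector.
#' @return data.frame with columns `sequence` (RNA), `count`, `length`,
#'   ordered by decreasing count then sequence.
#' @export
collapse_tags <- function(reads) {
  seqs <- if (is.character(reads)) reads else reads$seq
  seqs <- norm_rna(seqs)
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$length <- nchar(out$sequence)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length distribution report
#'
#' Per-length totals of reads and unique tags over a length window, with
#' read percentages of the window total.
#'
#' @param tags collapsed tags from [collapse_tags()].
#' @param min_len,max_len window bounds, nt.
#' @return data.frame with columns `length`, `reads`, `unique_tags`,
#'   `percent`.
#' @export
length_distribution <- function(tags, min_len = 18, max_len = 25) {
  lens <- min_len:max_len
  reads <- vapply(lens, function(l) sum(tags$count[tags$length == l]),
                  numeric(1))
  uniq <- vapply(lens, function(l) sum(tags$length == l), integer(1))
  total <- sum(reads)
  data.frame(length = lens, reads = as.integer(reads), unique_tags = uniq,
             percent = if (total > 0) percent(reads, total) else 0)
}

#' Clean a raw sRNA library
#'
#' Standard preprocessing chain: quality/N filter, adapter trimming,
#' length window, tag collapsing.
#'
#' @param reads raw reads data.frame (`id`, `seq`, `qual`).
#' @param adapter_3p,adapter_5p adapter sequences ("" to skip trimming).
#' @param min_q mean-Phred threshold.
#' @param min_len,max_len retained length window, nt.
#' @return list with `tags` (collapsed), `length_distribution`, and
#'   `stats` (reads surviving each step).
#' @export
preprocess_reads <- function(reads, adapter_3p = "", adapter_5p = "",
                             min_q = 13, min_len = 18, max_len = 25) {
  n0 <- nrow(reads)
  qf <- quality_filter(reads, min_q = min_q)
  tr <- trim_adapters(qf, adapter_3p, adapter_5p)
  lf <- length_filter(tr, min_len, max_len)
  tags <- collapse_tags(lf)
  list(tags = tags,
       length_distribution = length_distribution(tags, min_len, max_len),
       stats = data.frame(step = c("input", "quality", "trimmed", "length"),
                          reads = c(n0, nrow(qf), nrow(tr), nrow(lf))))
}
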