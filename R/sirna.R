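#' Select 24-nt tags
#'
#' The heterochromatic siRNA size class in plants.
#'
#' @param tags collapsed tags.
#' @param length selected length, nt.
#' @return the rows with that exact length.
#' @export
select_24nt <- function(tags, length = 24) {
  tags[tags$length == length, , drop = FALSE]
}

#' Detect siRNA-producing loci
#'
#' A locus is a dispersed 24-nt read pattern: on one contig, at least
#' `min_starts` distinct 5' start positions spanning at least `min_span`
#' nt, with no single block (delta-clustered 5' starts) holding more than
#' `max_block_fraction` of the reads — the opposite of the one/two-block
#' signature of miRNA processing. Loci on contigs already carrying an
#' accepted precursor call are suppressed. Strands are pooled; strand
#' balance is not required.
#'
#' @param anchors anchors of 24-nt tags ([anchor_tags()] output).
#' @param min_starts minimum distinct 5' starts.
#' @param min_span minimum span of those starts, nt.
#' @param max_block_fraction maximum read fraction of any single block.
#' @param delta block-clustering tolerance, nt.
#' @param exclude_contigs contigs to suppress (e.g. accepted precursors).
#' @return data.frame of loci: `contig`, `start`, `end`, `n_starts`,
#'   `total_reads`, `largest_block_fraction`, `strands`.
#' @export
detect_sirna_loci <- function(anchors, min_starts = 10, min_span = 100,
                              max_block_fraction = 0.5, delta = 3,
                              exclude_contigs = character(0)) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), n_starts = integer(0),
                      total_reads = integer(0),
                      largest_block_fraction = numeric(0),
                      strands = character(0))
  if (nrow(anchors) == 0) return(empty)
  anchors$fp <- five_prime_start(anchors)
  out <- list()
  for (ctg in setdiff(unique(anchors$contig), exclude_contigs)) {
    a <- anchors[anchors$contig == ctg, , drop = FALSE]
    starts <- sort(unique(a$fp))
    span <- diff(range(a$fp))
    if (length(starts) < min_starts || span < min_span) next
    # largest delta-block read fraction (strands pooled)
    a <- a[order(a$fp), , drop = FALSE]
    blk <- cumsum(c(TRUE, diff(a$fp) > delta))
    frac <- max(tapply(a$count, blk, sum)) / sum(a$count)
    if (frac > max_block_fraction) next
    out[[length(out) + 1L]] <- data.frame(
      contig = ctg, start = min(a$start), end = max(a$end),
      n_starts = length(starts), total_reads = sum(a$count),
      largest_block_fraction = frac,
      strands = paste(sort(unique(a$strand)), collapse = ""),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}
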