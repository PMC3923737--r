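#' Scan a mature miRNA against transcripts
#'
#' Expectation-scored complementarity search. Every transcript window is
#' compared with the reverse complement of the miRNA; per-position
#' penalties are 0 for a Watson-Crick pair, 0.5 for a G:U wobble, 1 for a
#' mismatch and 2 for a single-nt bulge (at most one per site), doubled
#' at miRNA positions 2-13 (the seed-proximal region). Hits at or below
#' `max_expectation` are reported, overlapping hits deduplicated to the
#' minimum-expectation window. The inhibition hint is "cleavage" unless
#' miRNA positions 9-11 contain a mismatch ("translation"). Both strands
#' of each transcript are searched; coordinates are reported on the given
#' orientation.
#'
#' @param mature mature miRNA sequence (RNA or DNA, 18-25 nt).
#' @param transcripts transcript sequences (DNAStringSet, named character
#'   vector, or FASTA path).
#' @param max_expectation score cutoff (4.0 for canonical miRNAs; 5.0 is
#'   the conventional isomiR cutoff).
#' @param mirna_id identifier used in the output.
#' @param both_strands search the reverse strand too.
#' @return data.frame of hits: `mirna`, `transcript`, `start`, `end`
#'   (1-based inclusive, given orientation), `strand`, `expectation`,
#'   `inhibition`, `alignment` (three-line string: miRNA 3'->5', match
#'   line, target 5'->3').
#' @export
scan_targets <- function(mature, transcripts, max_expectation = 4.0,
                         mirna_id = "mirna", both_strands = TRUE) {
  m <- nchar(mature)
  if (m < 18 || m > 25)
    stop("scan_targets(): mature length must be 18-25 nt")
  transcripts <- as_contigs(transcripts)
  mir_dna <- norm_dna(mature)
  out <- list()
  for (t in seq_along(transcripts)) {
    tseq <- as.character(transcripts[[t]])
    tlen <- nchar(tseq)
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      s <- if (strand == "+") tseq else revcomp(tseq)
      hits <- .scan_expectation_cpp(mir_dna, s, max_expectation)
      if (nrow(hits) == 0) next
      for (h in seq_len(nrow(hits))) {
        st0 <- hits[h, "start"]; en0 <- hits[h, "end"] # 0-based half-open
        if (strand == "+") {
          start <- st0 + 1L; end <- en0
        } else {
          start <- tlen - en0 + 1L; end <- tlen - st0
        }
        site <- substr(s, st0 + 1, en0)
        aln <- format_target_alignment(mir_dna, site, hits[h, "gap_kind"],
                                       hits[h, "gap_index"])
        out[[length(out) + 1L]] <- data.frame(
          mirna = mirna_id, transcript = names(transcripts)[t],
          start = as.integer(start), end = as.integer(end), strand = strand,
          expectation = hits[h, "expectation"],
          inhibition = if (hits[h, "mm911"] > 0) "translation" else "cleavage",
          alignment = aln, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), expectation = numeric(0),
                      inhibition = character(0), alignment = character(0)))
  dedupe_hits(hits)
}

# keep the minimum-expectation hit among mutually overlapping windows on
# the same transcript and strand (internal)
dedupe_hits <- function(hits) {
  hits <- hits[order(hits$transcript, hits$strand, hits$expectation,
                     hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i &
                 hits$transcript == hits$transcript[i] &
                 hits$strand == hits$strand[i] &
                 hits$start <= hits$end[i] & hits$end >= hits$start[i])
    keep[j] <- FALSE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# three-line alignment: miRNA 3'->5' / match line / target 5'->3'
# (internal)
format_target_alignment <- function(mir_dna, site, gap_kind, gap_index) {
  qr <- strsplit(paste(rev(strsplit(mir_dna, "")[[1]]), collapse = ""),
                 "")[[1]] # miRNA 3'->5'
  tg <- strsplit(site, "")[[1]]
  if (gap_kind == 1) { # bulged target nt at site index gap_index (0-based)
    qr <- append(qr, "-", after = gap_index)
  } else if (gap_kind == 2) { # bulged miRNA nt
    tg <- append(tg, "-", after = gap_index)
  }
  match_char <- function(q, t) {
    if (q == "-" || t == "-") return(" ")
    if (paste0(q, t) %in% c("AT", "TA", "GC", "CG")) return("|")
    if (paste0(q, t) %in% c("GT", "TG")) return("o")
    " "
  }
  mid <- mapply(match_char, qr, tg)
  paste(paste(qr, collapse = ""), paste(mid, collapse = ""),
        paste(tg, collapse = ""), sep = "\n")
}

#' Scan many miRNAs and summarize targets per miRNA
#'
#' @param matures named character vector of mature sequences.
#' @param transcripts transcript sequences.
#' @param max_expectation cutoff applied to every scan.
#' @return list with `hits` (row-bound [scan_targets()] output) and
#'   `summary` (per-miRNA target counts plus `mean_targets`, printed to
#'   one decimal in the TSV report).
#' @export
predict_targets <- function(matures, transcripts, max_expectation = 4.0) {
  hits <- do.call(rbind, lapply(names(matures), function(id) {
    scan_targets(matures[[id]], transcripts, max_expectation,
                 mirna_id = id)
  }))
  if (is.null(hits)) hits <- scan_targets(strrep("A", 21), character(0))
  list(hits = hits, summary = targets_per_mirna_summary(hits))
}

#' Targets-per-miRNA summary
#'
#' @param hits data.frame of target hits.
#' @return list with `per_mirna` (data.frame `mirna`, `n_targets`) and
#'   `mean_targets` (mean distinct targets per miRNA with at least one
#'   hit; `NA` when there are none).
#' @export
targets_per_mirna_summary <- function(hits) {
  if (nrow(hits) == 0)
    return(list(per_mirna = data.frame(mirna = character(0),
                                       n_targets = integer(0)),
                mean_targets = NA_real_))
  per <- do.call(rbind, lapply(split(hits, hits$mirna), function(h) {
    data.frame(mirna = h$mirna[1],
               n_targets = length(unique(h$transcript)),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_mirna = per, mean_targets = mean(per$n_targets))
}
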