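#' Classify tags against ncRNA reference classes
#'
#' A tag is assigned to an RNA class when its sequence occurs exactly
#' (zero mismatches, full tag containment) in some reference of that class
#' on either strand. Multi-class hits are resolved by a fixed priority
#' order (`rRNA > tRNA > snRNA > snoRNA > cpRNA > mtRNA` by default, the
#' filtering-table column order); unmatched tags get class `"none"`.
#' Exact containment stands in for a zero-mismatch short-read alignment
#' and makes the classification fully reproducible; a mismatch budget is
#' available via `max_mismatch`.
#'
#' @param tags collapsed tags ([collapse_tags()]).
#' @param references named list of class references, each a
#'   [Biostrings::DNAStringSet], character vector, or FASTA path.
#' @param priority class priority order; defaults to the order of
#'   `references`.
#' @param max_mismatch allowed substitutions (default 0).
#' @return `tags` with an added `ncrna_class` column.
#' @export
classify_tags <- function(tags, references, priority = names(references),
                          max_mismatch = 0) {
  if (length(references) == 0 || is.null(names(references)))
    stop("classify_tags(): a named, nonempty reference map is required")
  refs <- lapply(references, function(r) {
    if (is.character(r) && length(r) == 1 && file.exists(r)) r <- read_fasta(r)
    if (is.character(r)) r <- Biostrings::DNAStringSet(norm_dna(r))
    if (length(r) == 0) stop("classify_tags(): empty reference set")
    r
  })
  cls <- rep("none", nrow(tags))
  if (nrow(tags) == 0) {
    tags$ncrna_class <- character(0)
    return(tags)
  }
  pat_fwd <- Biostrings::DNAStringSet(norm_dna(tags$sequence))
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  for (cl in rev(priority)) { # reverse order so high priority wins last
    subject <- refs[[cl]]
    hit <- logical(nrow(tags))
    for (w in unique(Biostrings::width(pat_fwd))) {
      idx <- which(Biostrings::width(pat_fwd) == w)
      for (pats in list(pat_fwd[idx], pat_rev[idx])) {
        pd <- if (max_mismatch > 0)
          Biostrings::PDict(pats, max.mismatch = max_mismatch)
        else Biostrings::PDict(pats)
        got <- unique(unlist(Biostrings::vwhichPDict(
          pd, subject, max.mismatch = max_mismatch)))
        if (length(got)) hit[idx[got]] <- TRUE
      }
    }
    cls[hit] <- cl
  }
  tags$ncrna_class <- cls
  tags
}

#' Remove classified tags
#'
#' Retains exactly the tags with class `"none"`; the removed read total
#' equals the sum of the class totals.
#'
#' @param classified output of [classify_tags()].
#' @return list with `retained` (tags), `removed` (tags), and `totals`
#'   (reads retained/removed).
#' @export
remove_classified <- function(classified) {
  keep <- classified$ncrna_class == "none"
  list(retained = classified[keep, , drop = FALSE],
       removed = classified[!keep, , drop = FALSE],
       totals = c(retained = sum(classified$count[keep]),
                  removed = sum(classified$count[!keep])))
}

#' Length-by-class filtering summary
#'
#' A filtering-table-style report: per read length (default 18-25 nt) and
#' per ncRNA class, read totals and percentages of that length's total,
#' plus an "all filters" column (the sum of the class columns) and a
#' grand-total row.
#'
#' @param classified output of [classify_tags()].
#' @param min_len,max_len report window, nt.
#' @param classes class column order; defaults to the classes present.
#' @return data.frame mirroring the filtering-table layout; percentages
#'   are computed with [percent()] (half-up, 2 decimals).
#' @export
filter_summary <- function(classified, min_len = 18, max_len = 25,
                           classes = c("rRNA", "tRNA", "snRNA", "snoRNA",
                                       "cpRNA", "mtRNA")) {
  lens <- min_len:max_len
  grand <- sum(classified$count[classified$length %in% lens])
  rows <- lapply(lens, function(l) {
    at <- classified[classified$length == l, , drop = FALSE]
    total <- sum(at$count)
    row <- data.frame(length = as.character(l), total_reads = total,
                      total_percent = if (grand > 0) percent(total, grand)
                                      else 0)
    allf <- 0
    for (cl in classes) {
      cnt <- sum(at$count[at$ncrna_class == cl])
      allf <- allf + cnt
      row[[paste0(cl, "_reads")]] <- cnt
      row[[paste0(cl, "_percent")]] <- if (total > 0) percent(cnt, total)
                                       else 0
    }
    row$all_filters_reads <- allf
    row$all_filters_percent <- if (total > 0) percent(allf, total) else 0
    row
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(length = "Total", total_reads = grand,
                    total_percent = if (grand > 0) percent(grand, grand)
                                    else 0)
  for (cl in classes) {
    cnt <- sum(out[[paste0(cl, "_reads")]])
    tot[[paste0(cl, "_reads")]] <- cnt
    tot[[paste0(cl, "_percent")]] <- if (grand > 0) percent(cnt, grand)
                                     else 0
  }
  tot$all_filters_reads <- sum(out$all_filters_reads)
  tot$all_filters_percent <- if (grand > 0)
    percent(tot$all_filters_reads, grand) else 0
  rbind(out, tot)
}
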