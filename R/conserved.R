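#' Read a mature-miRNA reference
#'
#' Parses a miRBase-style mature FASTA. The family label is extracted with
#' a case-insensitive grammar capturing `miR`/`MIR` plus the leading
#' integer, so letter variants (`miR166a`, `MIR166b-5p`) collapse to one
#' family (`MIR166`). Records whose id does not parse are kept and flagged.
#'
#' @param x FASTA path, named character vector, or a data.frame already
#'   holding `id` and `sequence`.
#' @return data.frame with columns `id`, `family` (NA when unparsed) and
#'   `sequence` (RNA-normalized).
#' @export
read_mature_reference <- function(x) {
  if (is.data.frame(x)) {
    df <- data.frame(id = x$id, sequence = norm_rna(x$sequence),
                     stringsAsFactors = FALSE)
  } else {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      ss <- read_fasta(x)
      x <- setNames(as.character(ss), names(ss))
    }
    df <- data.frame(id = names(x), sequence = norm_rna(unname(x)),
                     stringsAsFactors = FALSE)
  }
  df$family <- parse_mir_family(df$id)
  df[, c("id", "family", "sequence")]
}

#' Parse miRNA family labels from identifiers
#'
#' @param ids character vector of miRNA identifiers.
#' @return character vector like `"MIR166"`, `NA` where no family parses.
#' @export
parse_mir_family <- function(ids) {
  m <- regmatches(ids, regexpr("mir[-_]?[0-9]+", ids, ignore.case = TRUE))
  out <- rep(NA_character_, length(ids))
  hit <- grepl("mir[-_]?[0-9]+", ids, ignore.case = TRUE)
  out[hit] <- paste0("MIR", gsub("[^0-9]", "", m))
  out
}

#' Match tags against a mature-miRNA reference
#'
#' A tag matches iff its sequence is byte-identical (after RNA
#' normalization) to a reference sequence: same length, zero mismatches.
#' A tag matching several reference entries yields one row per entry.
#'
#' @param tags collapsed tags.
#' @param reference mature reference ([read_mature_reference()] output or
#'   anything it accepts).
#' @return data.frame with columns `sequence`, `count`, `ref_id`, `family`.
#' @export
match_mature <- function(tags, reference) {
  reference <- read_mature_reference(reference)
  if (nrow(reference) == 0) stop("match_mature(): empty mature reference")
  idx <- match(reference$sequence, norm_rna(tags$sequence))
  hit <- !is.na(idx)
  out <- data.frame(sequence = tags$sequence[idx[hit]],
                    count = tags$count[idx[hit]],
                    ref_id = reference$id[hit],
                    family = reference$family[hit],
                    stringsAsFactors = FALSE)
  out[order(out$family, out$ref_id), , drop = FALSE]
}

#' Summarize matched miRNA families
#'
#' One row per family with the number of distinct matched mature
#' sequences and total reads (each distinct tag counted once per family,
#' so multi-reference hits are not double counted).
#'
#' @param matches output of [match_mature()].
#' @return list with `families` (data.frame `family`, `member_count`,
#'   `total_reads`) and `mean_members` (average members per family).
#' @export
summarize_families <- function(matches) {
  if (nrow(matches) == 0)
    return(list(families = data.frame(family = character(0),
                                      member_count = integer(0),
                                      total_reads = integer(0)),
                mean_members = NA_real_))
  fams <- split(matches, matches$family)
  families <- do.call(rbind, lapply(names(fams), function(f) {
    m <- fams[[f]]
    u <- !duplicated(m$sequence)
    data.frame(family = f, member_count = sum(u),
               total_reads = sum(m$count[u]), stringsAsFactors = FALSE)
  }))
  families <- families[order(-families$total_reads), , drop = FALSE]
  rownames(families) <- NULL
  list(families = families,
       mean_members = sum(families$member_count) / nrow(families))
}
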