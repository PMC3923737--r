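#' Anchor tags on contigs by perfect matching
#'
#' Reports every exact occurrence of every tag on either strand of the
#' contig set. Coordinates are 1-based inclusive on the + strand of the
#' contig (BED-like 0-based half-open coordinates are used only in the
#' TSV writers).
#'
#' @param tags collapsed tags.
#' @param contigs [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path.
#' @return data.frame with columns `sequence`, `count`, `contig`, `start`,
#'   `end`, `strand`.
#' @export
anchor_tags <- function(tags, contigs) {
  contigs <- as_contigs(contigs)
  if (length(contigs) == 0) stop("anchor_tags(): contigs must be nonempty")
  rows <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    pat <- Biostrings::DNAString(norm_dna(tags$sequence[i]))
    hits <- list(`+` = Biostrings::vmatchPattern(pat, contigs),
                 `-` = Biostrings::vmatchPattern(
                   Biostrings::reverseComplement(pat), contigs))
    part <- lapply(names(hits), function(strand) {
      r <- unlist(hits[[strand]])
      if (length(r) == 0) return(NULL)
      data.frame(sequence = tags$sequence[i], count = tags$count[i],
                 contig = names(r), start = IRanges::start(r),
                 end = IRanges::end(r), strand = strand,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, part)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sequence = character(0), count = integer(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  rownames(out) <- NULL
  out
}

as_contigs <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs))
    contigs <- read_fasta(contigs)
  if (is.character(contigs)) {
    stopifnot(!is.null(names(contigs)))
    contigs <- Biostrings::DNAStringSet(norm_dna(contigs))
  }
  contigs
}

# 5' start of an anchor in contig coordinates (internal)
five_prime_start <- function(anchors) {
  ifelse(anchors$strand == "+", anchors$start, anchors$end)
}

#' Detect anchored-read blocks
#'
#' Single-linkage clustering of anchors by 5' start within `delta` nt, per
#' contig and strand. A contig strand has a valid block pattern when its
#' top one or two blocks jointly contain at least `containment` of that
#' strand's anchored reads — the read geometry expected from precise
#' hairpin processing, as opposed to degradation or siRNA-like smears.
#'
#' @param anchors output of [anchor_tags()].
#' @param delta clustering tolerance on 5' starts, nt.
#' @param containment required joint read fraction of the top two blocks.
#' @param min_tag_count tags below this redundancy are ignored when the
#'   containment fraction is computed (degradation noise is dominated by
#'   singletons); blocks themselves are built from all anchors.
#' @return list with `blocks` (data.frame `contig`, `strand`, `block`,
#'   `span_start`, `span_end`, `n_anchors`, `total_reads`) and `verdicts`
#'   (data.frame `contig`, `strand`, `n_blocks`, `top2_fraction`, `valid`).
#' @export
detect_blocks <- function(anchors, delta = 3, containment = 0.9,
                          min_tag_count = 2) {
  if (nrow(anchors) == 0)
    return(list(blocks = data.frame(), verdicts = data.frame()))
  anchors$fp <- five_prime_start(anchors)
  key <- interaction(anchors$contig, anchors$strand, drop = TRUE)
  blocks <- list(); verdicts <- list()
  for (k in levels(key)) {
    a <- anchors[key == k, , drop = FALSE]
    a <- a[order(a$fp), , drop = FALSE]
    newblk <- c(TRUE, diff(a$fp) > delta)
    a$block <- cumsum(newblk)
    b <- do.call(rbind, lapply(split(a, a$block), function(g) {
      data.frame(contig = g$contig[1], strand = g$strand[1],
                 block = g$block[1], span_start = min(g$start),
                 span_end = max(g$end), n_anchors = nrow(g),
                 total_reads = sum(g$count), stringsAsFactors = FALSE)
    }))
    solid <- vapply(split(a, a$block), function(g)
      sum(g$count[g$count >= min_tag_count]), numeric(1))
    tot <- sum(solid)
    top2 <- sum(head(sort(solid, decreasing = TRUE), 2))
    frac <- if (tot > 0) top2 / tot else 0
    blocks[[k]] <- b
    verdicts[[k]] <- data.frame(contig = b$contig[1], strand = b$strand[1],
                                n_blocks = nrow(b),
                                top2_fraction = frac,
                                valid = frac >= containment,
                                stringsAsFactors = FALSE)
  }
  list(blocks = do.call(rbind, c(blocks, list(make.row.names = FALSE))),
       verdicts = do.call(rbind, c(verdicts, list(make.row.names = FALSE))))
}

#' Excise candidate precursor windows
#'
#' Two-block case: the joint block span plus `flank` on both sides.
#' One-block case: two windows, the block span plus `flank` extended by
#' `ext` nt leftward and rightward in turn (the mature miRNA may sit on
#' either arm). Windows are clipped to contig bounds and capped at
#' `max_len`; windows shorter than `min_window` are dropped with a reason.
#'
#' @param blocks,verdicts output of [detect_blocks()].
#' @param contigs contig sequences.
#' @param max_len maximum window length, nt.
#' @param flank flank added around block spans, nt.
#' @param ext one-block extension length, nt.
#' @param min_window minimum usable window, nt (twice a mature plus a
#'   minimal loop).
#' @param min_second_reads minimum reads for the partner block of a
#'   two-block window.
#' @param min_second_fraction minimum read share of the partner block
#'   relative to the top block (guards against stray degradation tags
#'   mimicking a second block).
#' @return data.frame of windows: `contig`, `strand`, `start`, `end`,
#'   `kind`, `dropped`, `reason`.
#' @export
extract_windows <- function(blocks, verdicts, contigs, max_len = 300,
                            flank = 20, ext = 150, min_window = 50,
                            min_second_reads = 2,
                            min_second_fraction = 0.05) {
  contigs <- as_contigs(contigs)
  widths <- setNames(Biostrings::width(contigs), names(contigs))
  out <- list()
  ok <- verdicts[verdicts$valid, , drop = FALSE]
  for (r in seq_len(nrow(ok))) {
    v <- ok[r, ]
    b <- blocks[blocks$contig == v$contig & blocks$strand == v$strand, ,
                drop = FALSE]
    b <- b[order(-b$total_reads), , drop = FALSE]
    W <- widths[[v$contig]]
    clip <- function(s, e) c(max(1L, s), min(W, e))
    add <- function(s, e, kind) {
      se <- clip(s, e)
      len <- se[2] - se[1] + 1L
      dropped <- len < min_window
      out[[length(out) + 1L]] <<- data.frame(
        contig = v$contig, strand = v$strand, start = se[1], end = se[2],
        kind = kind, dropped = dropped,
        reason = if (dropped) "window_too_short" else "",
        stringsAsFactors = FALSE)
    }
    if (nrow(b) >= 2 &&
        b$total_reads[2] >= max(min_second_reads,
                                min_second_fraction * b$total_reads[1])) {
      s <- min(b$span_start[1:2]) - flank
      e <- max(b$span_end[1:2]) + flank
      if (e - s + 1L <= max_len) add(s, e, "two_block")
    }
    # the mature may sit on either arm: always try both one-block windows
    add(b$span_start[1] - flank - ext, b$span_end[1] + flank,
        "one_block_left")
    add(b$span_start[1] - flank, b$span_end[1] + flank + ext,
        "one_block_right")
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      kind = character(0), dropped = logical(0),
                      reason = character(0))
  res
}

#' Precursor acceptance criteria
#'
#' Two presets: `"strict"` (|MFE| within 40-100 kcal/mol, |MFEI| > 0.85)
#' and `"loose"` (|MFE| within 17-110, |MFEI| > 0.5). Both require at
#' least `min_reads` anchored reads and the mature block confined to one
#' arm (terminal-loop overlap of at most `max_loop_overlap` nt).
#'
#' @param preset "strict" or "loose".
#' @param mfe_range,min_mfei,min_reads,max_loop_overlap overrides.
#' @return list of class `precursor_criteria`.
#' @export
precursor_criteria <- function(preset = c("strict", "loose"),
                               mfe_range = NULL, min_mfei = NULL,
                               min_reads = 10, max_loop_overlap = 4) {
  preset <- match.arg(preset)
  if (is.null(mfe_range))
    mfe_range <- if (preset == "strict") c(40, 100) else c(17, 110)
  if (is.null(min_mfei))
    min_mfei <- if (preset == "strict") 0.85 else 0.5
  structure(list(preset = preset, mfe_range = mfe_range,
                 min_mfei = min_mfei, min_reads = min_reads,
                 max_loop_overlap = max_loop_overlap),
            class = "precursor_criteria")
}

#' Evaluate a candidate precursor window
#'
#' Folds the window, excises the hairpin domain hosting the top-count
#' read block (re-folding the refined span), computes MFE, AMFE and MFEI,
#' and applies the acceptance criteria: (i) a single-hairpin structure
#' (exactly one terminal loop on the candidate span); (ii) |MFE| within
#' the configured range; (iii) |MFEI| above the threshold; (iv) at least
#' `min_reads` anchored reads; (v) the top-count block confined to one
#' arm, overlapping the terminal loop by at most `max_loop_overlap` nt.
#' A folding failure rejects the candidate with reason `fold_error`.
#'
#' @param window one row of [extract_windows()] output.
#' @param anchors anchors on the window's contig.
#' @param contigs contig sequences.
#' @param engine a [builtin_fold_engine()] or compatible engine.
#' @param criteria a [precursor_criteria()].
#' @param delta block-clustering tolerance, nt.
#' @param refine_pad nt kept around the excised hairpin domain.
#' @return a `precursor_call` list: sequence, structure, mfe, length,
#'   gc_percent, amfe, mfei, per-criterion flags, verdict, reject reasons,
#'   mature arm, canonical tag and isomiR table.
#' @export
evaluate_candidate <- function(window, anchors, contigs,
                               engine = builtin_fold_engine(),
                               criteria = precursor_criteria(),
                               delta = 3, refine_pad = 5) {
  contigs <- as_contigs(contigs)
  wstart <- window$start; wend <- window$end
  get_seq <- function(s, e) {
    x <- as.character(Biostrings::subseq(contigs[[window$contig]], s, e))
    if (window$strand == "-") x <- revcomp(x)
    norm_rna(x)
  }
  local_anchors <- function(s, e) {
    a <- anchors[anchors$contig == window$contig &
                   anchors$strand == window$strand &
                   anchors$start >= s & anchors$end <= e, , drop = FALSE]
    if (nrow(a) > 0) {
      if (window$strand == "+") {
        a$wstart <- a$start - s + 1L
        a$wend <- a$end - s + 1L
      } else {
        a$wstart <- e - a$end + 1L
        a$wend <- e - a$start + 1L
      }
    }
    a
  }
  top_block_span <- function(a) {
    if (nrow(a) == 0) return(NULL)
    a2 <- a[order(a$wstart), , drop = FALSE]
    blk <- cumsum(c(TRUE, diff(a2$wstart) > delta))
    reads <- tapply(a2$count, blk, sum)
    g <- a2[blk == as.integer(names(reads)[which.max(reads)]), ,
            drop = FALSE]
    c(min(g$wstart), max(g$wend))
  }

  fail <- function(call, reason) {
    call$flags <- c(single_hairpin = FALSE, mfe_range = FALSE,
                    mfei = FALSE, min_reads = FALSE, arm_overlap = FALSE)
    call$verdict <- "rejected"
    call$reject_reasons <- reason
    class(call) <- "precursor_call"
    call
  }
  base_call <- list(contig = window$contig, strand = window$strand,
                    start = wstart, end = wend, kind = window$kind,
                    criteria = criteria, structure = NA_character_,
                    mfe = NA_real_, amfe = NA_real_, mfei = NA_real_,
                    sequence = get_seq(wstart, wend),
                    length = wend - wstart + 1L,
                    gc_percent = NA_real_,
                    anchors = local_anchors(wstart, wend))

  wseq <- base_call$sequence
  fold <- tryCatch(fold_sequence(engine, wseq), error = function(e) NULL)
  if (is.null(fold)) return(fail(base_call, "fold_error"))

  # excise the hairpin domain hosting the top-count block
  a <- base_call$anchors
  bspan <- top_block_span(a)
  if (is.null(bspan)) return(fail(base_call, "no_anchored_reads"))
  dom <- db_domains(fold$structure)
  hosts <- dom[bspan[1] >= dom$start - refine_pad &
                 bspan[2] <= dom$end + refine_pad, , drop = FALSE]
  if (nrow(hosts) == 0) return(fail(base_call, "no_hairpin_at_block"))
  d <- hosts[which.max(hosts$end - hosts$start), ]
  rs <- max(1L, d$start - refine_pad)
  re <- min(nchar(wseq), d$end + refine_pad)
  if (window$strand == "+") {
    cstart <- wstart + rs - 1L
    cend <- wstart + re - 1L
  } else {
    cstart <- wend - re + 1L
    cend <- wend - rs + 1L
  }
  refined <- rs > 1L || re < nchar(wseq)
  call <- base_call
  call$start <- cstart; call$end <- cend
  call$sequence <- get_seq(cstart, cend)
  call$length <- nchar(call$sequence)
  call$gc_percent <- gc_percent(call$sequence)
  call$anchors <- local_anchors(cstart, cend)
  if (refined) {
    fold <- tryCatch(fold_sequence(engine, call$sequence),
                     error = function(e) NULL)
    if (is.null(fold)) return(fail(call, "fold_error"))
  }
  call$structure <- fold$structure
  call$mfe <- fold$mfe
  call$amfe <- amfe(fold$mfe, call$length)
  call$mfei <- if (call$gc_percent > 0)
    mfei(fold$mfe, call$length, call$gc_percent) else NA_real_

  a <- call$anchors
  loops <- db_terminal_loops(fold$structure)
  flags <- c(single_hairpin = nrow(loops) == 1,
             mfe_range = abs(fold$mfe) >= criteria$mfe_range[1] &&
               abs(fold$mfe) <= criteria$mfe_range[2],
             mfei = !is.na(call$mfei) && abs(call$mfei) > criteria$min_mfei,
             min_reads = sum(a$count) >= criteria$min_reads,
             arm_overlap = FALSE)
  call$loop <- if (nrow(loops) == 1) c(loops$start[1], loops$end[1])
               else NULL
  bspan <- top_block_span(a)
  if (nrow(loops) == 1 && !is.null(bspan)) {
    ov <- max(0L, min(bspan[2], loops$end[1]) -
                max(bspan[1], loops$start[1]) + 1L)
    flags["arm_overlap"] <- ov <= criteria$max_loop_overlap
    loop_mid <- (loops$start[1] + loops$end[1]) / 2
    call$mature_arm <- if (mean(bspan) < loop_mid) "5p" else "3p"
    call$top_block_span <- bspan
    call$loop_overlap <- ov
  }
  call$flags <- flags
  call$verdict <- if (all(flags)) "accepted" else "rejected"
  call$reject_reasons <- paste(names(flags)[!flags], collapse = ",")
  class(call) <- "precursor_call"
  if (call$verdict == "accepted") call <- assign_canonical(call)
  call
}

#' Assign the canonical miRNA and isomiRs of an accepted call
#'
#' The canonical miRNA is the most frequent anchored tag (ties broken by
#' the lexicographically smallest sequence); every other anchored tag is
#' an isomiR, labelled with its arm relative to the terminal loop.
#'
#' @param call an accepted `precursor_call`.
#' @return the call with `canonical` (list `sequence`, `count`, `arm`) and
#'   `isomirs` (data.frame) filled in.
#' @export
assign_canonical <- function(call) {
  a <- call$anchors
  if (is.null(a) || nrow(a) == 0) return(call)
  a <- a[order(-a$count, a$sequence), , drop = FALSE]
  arm_of <- function(ws, we) {
    if (is.null(call$loop)) return(NA_character_)
    if ((ws + we) / 2 < mean(call$loop)) "5p" else "3p"
  }
  call$canonical <- list(sequence = a$sequence[1], count = a$count[1],
                         arm = arm_of(a$wstart[1], a$wend[1]))
  rest <- a[-1, , drop = FALSE]
  call$isomirs <- if (nrow(rest)) {
    data.frame(sequence = rest$sequence, count = rest$count,
               arm = mapply(arm_of, rest$wstart, rest$wend),
               stringsAsFactors = FALSE)
  } else data.frame(sequence = character(0), count = integer(0),
                    arm = character(0))
  call
}

#' Label an accepted call as known or novel
#'
#' Known iff the canonical tag perfectly matches the mature reference
#' (the conserved-matching rule); novel otherwise.
#'
#' @param call an accepted `precursor_call` with a canonical tag.
#' @param mature_reference mature reference (see
#'   [read_mature_reference()]).
#' @return the call with a `novelty` field ("known"/"novel").
#' @export
classify_known_vs_novel <- function(call, mature_reference) {
  ref <- read_mature_reference(mature_reference)
  known <- !is.null(call$canonical) &&
    norm_rna(call$canonical$sequence) %in% ref$sequence
  call$novelty <- if (known) "known" else "novel"
  call
}

#' Discover pre-miRNA candidates end to end
#'
#' Anchors tags, detects block patterns, excises windows, folds and
#' evaluates each candidate, assigns canonical/isomiR tags, labels
#' known/novel, and deduplicates overlapping accepted calls on a contig
#' (keeping the call with more anchored reads, then lower MFE).
#'
#' @param tags collapsed tags.
#' @param contigs contig sequences.
#' @param mature_reference optional mature reference for known/novel
#'   labelling.
#' @param engine folding engine.
#' @param criteria acceptance criteria.
#' @param delta block tolerance, nt.
#' @param flank,ext,max_len,min_window window parameters
#'   (see [extract_windows()]).
#' @return list with `anchors`, `blocks`, `verdicts`, `windows`, `calls`
#'   (all evaluated calls), `accepted` (deduplicated accepted calls) and
#'   `table` (summary data.frame, one row per evaluated candidate).
#' @export
discover_precursors <- function(tags, contigs, mature_reference = NULL,
                                engine = builtin_fold_engine(),
                                criteria = precursor_criteria(),
                                delta = 3, flank = 20, ext = 150,
                                max_len = 300, min_window = 50) {
  contigs <- as_contigs(contigs)
  anchors <- anchor_tags(tags, contigs)
  bl <- detect_blocks(anchors, delta = delta)
  windows <- extract_windows(bl$blocks, bl$verdicts, contigs,
                             max_len = max_len, flank = flank, ext = ext,
                             min_window = min_window)
  live <- windows[!windows$dropped, , drop = FALSE]
  calls <- lapply(seq_len(nrow(live)), function(i) {
    call <- evaluate_candidate(live[i, ], anchors, contigs, engine,
                               criteria, delta = delta)
    if (call$verdict == "accepted" && !is.null(mature_reference))
      call <- classify_known_vs_novel(call, mature_reference)
    call
  })

  acc <- Filter(function(cl) cl$verdict == "accepted", calls)
  if (length(acc) > 1) {
    keep <- rep(TRUE, length(acc))
    ord <- order(vapply(acc, function(cl) -sum(cl$anchors$count), numeric(1)),
                 vapply(acc, function(cl) cl$mfe, numeric(1)))
    acc <- acc[ord]
    for (i in seq_along(acc)) {
      if (!keep[i]) next
      for (j in seq_along(acc)) {
        if (j <= i || !keep[j]) next
        same <- acc[[i]]$contig == acc[[j]]$contig
        if (same && acc[[i]]$start <= acc[[j]]$end &&
            acc[[j]]$start <= acc[[i]]$end)
          keep[j] <- FALSE
      }
    }
    acc <- acc[keep]
  }

  list(anchors = anchors, blocks = bl$blocks, verdicts = bl$verdicts,
       windows = windows, calls = calls, accepted = acc,
       table = precursor_call_table(calls))
}

#' Tabulate precursor calls
#'
#' @param calls list of `precursor_call` objects.
#' @return data.frame, one row per call, with coordinates, energies,
#'   per-criterion flags, verdict and canonical tag.
#' @export
precursor_call_table <- function(calls) {
  if (length(calls) == 0)
    return(data.frame(contig = character(0)))
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(contig = cl$contig, strand = cl$strand, start = cl$start,
               end = cl$end, kind = cl$kind, length = cl$length,
               gc_percent = round(cl$gc_percent, 2),
               mfe = cl$mfe, amfe = round(cl$amfe, 2),
               mfei = round(cl$mfei, 3),
               reads = sum(cl$anchors$count),
               flag_single_hairpin = cl$flags[["single_hairpin"]],
               flag_mfe_range = cl$flags[["mfe_range"]],
               flag_mfei = cl$flags[["mfei"]],
               flag_min_reads = cl$flags[["min_reads"]],
               flag_arm_overlap = cl$flags[["arm_overlap"]],
               verdict = cl$verdict,
               reject_reasons = cl$reject_reasons,
               mature_arm = if (is.null(cl$mature_arm)) NA_character_
                            else cl$mature_arm,
               canonical = if (is.null(cl$canonical)) NA_character_
                           else cl$canonical$sequence,
               canonical_count = if (is.null(cl$canonical)) NA_integer_
                                 else cl$canonical$count,
               n_isomirs = if (is.null(cl$isomirs)) NA_integer_
                           else nrow(cl$isomirs),
               novelty = if (is.null(cl$novelty)) NA_character_
                         else cl$novelty,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
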