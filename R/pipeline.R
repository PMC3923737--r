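#' Pipeline configuration
#'
#' Collects input paths and stage thresholds, validating them before any
#' work is done. Inputs may be file paths or in-memory objects (a
#' `synth_study` can be passed directly to [run_pipeline()]).
#'
#' @param srna_fastq sRNA FASTQ path (or reads data.frame).
#' @param mature_reference mature miRNA FASTA path (or data.frame).
#' @param ncrna_references named list of per-class FASTA paths (or
#'   sequence sets).
#' @param contigs assembled contig FASTA path (or DNAStringSet).
#' @param stage_reads named list (`L1`, `L2`, ...) of mRNA FASTA paths
#'   (or read data.frames).
#' @param out_dir output directory for reports.
#' @param adapter_3p,adapter_5p adapter sequences ("" to skip).
#' @param min_q mean-Phred threshold.
#' @param min_len,max_len retained sRNA length window, nt.
#' @param preset precursor criteria preset ("strict"/"loose").
#' @param min_reads anchored-read threshold for precursor acceptance.
#' @param alpha dual-test significance gate.
#' @param max_expectation,isomir_max_expectation target-scan cutoffs.
#' @param sirna_min_starts,sirna_min_span,sirna_max_block_fraction siRNA
#'   locus rule parameters.
#' @param seed RNG seed recorded in the manifest.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(srna_fastq, mature_reference, ncrna_references,
                            contigs, stage_reads, out_dir,
                            adapter_3p = "", adapter_5p = "",
                            min_q = 13, min_len = 18, max_len = 25,
                            preset = "strict", min_reads = 10,
                            alpha = 0.001, max_expectation = 4.0,
                            isomir_max_expectation = 5.0,
                            sirna_min_starts = 10, sirna_min_span = 100,
                            sirna_max_block_fraction = 0.5, seed = 1L) {
  if (min_len > max_len)
    stop("pipeline_config(): min_len must not exceed max_len")
  if (alpha <= 0 || alpha > 1)
    stop("pipeline_config(): alpha must lie in (0, 1]")
  if (min_q < 0 || min_reads < 0 || max_expectation < 0)
    stop("pipeline_config(): thresholds must be non-negative")
  for (p in c(list(srna_fastq, mature_reference, contigs),
              ncrna_references, stage_reads)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop(sprintf("pipeline_config(): input path does not exist: %s", p))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Preprocess, ncRNA filtering, conserved matching, precursor discovery,
#' stage-wise differential representation, target prediction and siRNA
#' locus detection, writing every intermediate report to `out_dir`
#' together with a run manifest recording the seed, thresholds and
#' per-stage read conservation.
#'
#' @param config a [pipeline_config()], or a `synth_study` (all inputs
#'   taken in memory and `out_dir` required via `...`).
#' @param ... overrides passed to [pipeline_config()] when `config` is a
#'   `synth_study`.
#' @return list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, ...) {
  if (inherits(config, "synth_study")) {
    study <- config
    config <- pipeline_config(
      srna_fastq = study$srna$reads,
      mature_reference = data.frame(id = study$mature_reference$id,
                                    sequence = study$mature_reference$sequence),
      ncrna_references = study$ncrna_refs,
      contigs = study$contigs,
      stage_reads = study$mrna$stage_reads,
      adapter_3p = study$config$adapter_3p,
      seed = study$config$seed, ...)
  }
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed,
                   thresholds = config[c("min_q", "min_len", "max_len",
                                         "preset", "min_reads", "alpha",
                                         "max_expectation")])

  # --- preprocess -----------------------------------------------------
  reads <- if (is.data.frame(config$srna_fastq)) config$srna_fastq
           else read_fastq(config$srna_fastq)
  prep <- preprocess_reads(reads, adapter_3p = config$adapter_3p,
                           adapter_5p = config$adapter_5p,
                           min_q = config$min_q, min_len = config$min_len,
                           max_len = config$max_len)
  write_tags_fasta(prep$tags, file.path(out_dir, "tags.fasta"))
  write_tsv(prep$length_distribution,
            file.path(out_dir, "length_distribution.tsv"))
  manifest$conservation <- list(
    input_reads = nrow(reads),
    collapsed_reads = sum(prep$tags$count),
    collapse_conserved = sum(prep$tags$count) ==
      prep$stats$reads[prep$stats$step == "length"])

  # --- ncRNA filtering -------------------------------------------------
  classified <- classify_tags(prep$tags, config$ncrna_references)
  summ <- filter_summary(classified, config$min_len, config$max_len)
  write_tsv(summ, file.path(out_dir, "filter_summary.tsv"))
  rem <- remove_classified(classified)
  retained <- rem$retained
  write_tags_fasta(retained, file.path(out_dir, "tags_filtered.fasta"))
  manifest$conservation$filter_conserved <-
    sum(rem$totals) == sum(classified$count)

  # --- conserved miRNAs ------------------------------------------------
  matches <- match_mature(retained, config$mature_reference)
  fam <- summarize_families(matches)
  write_tsv(matches, file.path(out_dir, "conserved_matches.tsv"))
  write_tsv(fam$families, file.path(out_dir, "family_summary.tsv"))

  # --- precursor discovery ---------------------------------------------
  disc <- discover_precursors(retained, config$contigs,
                              mature_reference = config$mature_reference,
                              criteria = precursor_criteria(
                                config$preset, min_reads = config$min_reads))
  write_tsv(disc$table, file.path(out_dir, "precursor_calls.tsv"))
  anchors_bed <- disc$anchors
  if (nrow(anchors_bed)) {
    bed <- data.frame(contig = anchors_bed$contig,
                      start = anchors_bed$start - 1L, # 0-based half-open
                      end = anchors_bed$end, strand = anchors_bed$strand,
                      count = anchors_bed$count)
    write_tsv(bed, file.path(out_dir, "anchors.tsv"))
  }
  accepted <- disc$accepted
  if (length(accepted)) {
    prec_seqs <- setNames(
      vapply(accepted, function(cl) cl$sequence, character(1)),
      sprintf("premir%03d", seq_along(accepted)))
    write_fasta(setNames(norm_dna(prec_seqs), names(prec_seqs)),
                file.path(out_dir, "precursors.fasta"))
    writeLines(unlist(lapply(seq_along(accepted), function(i)
      c(paste0(">", names(prec_seqs)[i]), accepted[[i]]$sequence,
        accepted[[i]]$structure))),
      file.path(out_dir, "precursors.dotbracket"))
  } else prec_seqs <- character(0)

  # --- stage-wise abundance and differential calls ---------------------
  differential <- NULL
  cm <- NULL
  if (length(accepted) && length(config$stage_reads) >= 2) {
    stage_reads <- lapply(config$stage_reads, function(p) {
      if (is.data.frame(p)) p$seq else as.character(read_fasta(p))
    })
    cols <- lapply(stage_reads, count_reads,
                   references = norm_dna(prec_seqs), max_mismatch = 0)
    cm <- count_matrix(cols,
                       lib_sizes = vapply(stage_reads, length, numeric(1)))
    rownames(cm$counts) <- names(prec_seqs)
    cm <- tmm_factors(cm)
    differential <- call_differential(cm, alpha = config$alpha)
    write_tsv(differential, file.path(out_dir, "differential_calls.tsv"))
    cmat <- data.frame(feature = rownames(cm$counts), cm$counts)
    write_tsv(cmat, file.path(out_dir, "count_matrix.tsv"))
  }

  # --- target prediction ----------------------------------------------
  targets <- NULL
  if (length(accepted)) {
    matures <- setNames(
      vapply(accepted, function(cl) cl$canonical$sequence, character(1)),
      names(prec_seqs))
    matures <- matures[!duplicated(matures)]
    targets <- predict_targets(matures, config$contigs,
                               max_expectation = config$max_expectation)
    write_tsv(targets$hits, file.path(out_dir, "target_hits.tsv"))
  }

  # --- siRNA loci -------------------------------------------------------
  t24 <- select_24nt(retained)
  sirna <- if (nrow(t24)) {
    a24 <- anchor_tags(t24, config$contigs)
    detect_sirna_loci(a24, min_starts = config$sirna_min_starts,
                      min_span = config$sirna_min_span,
                      max_block_fraction = config$sirna_max_block_fraction,
                      exclude_contigs = unique(vapply(
                        accepted, function(cl) cl$contig, character(1))))
  } else detect_sirna_loci(data.frame())
  if (nrow(sirna)) {
    bed <- data.frame(contig = sirna$contig, start = sirna$start - 1L,
                      end = sirna$end, reads = sirna$total_reads,
                      starts = sirna$n_starts,
                      block_fraction = round(sirna$largest_block_fraction, 3))
    write_tsv(bed, file.path(out_dir, "sirna_loci.tsv"))
  }

  manifest$n_accepted_precursors <- length(accepted)
  manifest$n_conserved_matches <- nrow(matches)
  manifest$n_sirna_loci <- nrow(sirna)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = config, preprocess = prep,
                 filter_summary = summ, retained = retained,
                 conserved = list(matches = matches, families = fam),
                 discovery = disc, counts = cm,
                 differential = differential, targets = targets,
                 sirna = sirna, manifest = manifest))
}
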