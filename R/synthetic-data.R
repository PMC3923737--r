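#' Configuration for the synthetic study generator
#'
#' Builds the parameter list consumed by [simulate_study()] and the
#' individual generators. Defaults emulate the composition of a mature-seed
#' small-RNA library: hairpin precursors whose mature reads pile up in one
#' or two tight blocks with isomiR end-heterogeneity, non-coding RNA
#' contaminants at class-specific rates matching a typical filtering table
#' (rRNA dominant, then cpRNA), a 24-nt-dominated length distribution for
#' non-miRNA reads, and three developmental stages with known fold changes
#' for a subset of features.
#'
#' @param seed integer RNG seed used by [simulate_study()].
#' @param n_precursors number of true pre-miRNA hairpins.
#' @param precursor_len_range hard nt bounds for precursor lengths.
#' @param precursor_len_mean,precursor_len_sd parameters of the truncated
#'   normal length distribution inside `precursor_len_range` (defaults
#'   chosen to emulate reported plant pre-miRNA length averages ~150 nt).
#' @param gc_range GC fraction range for precursors and background.
#' @param mature_len_range mature miRNA length bounds, nt.
#' @param isomir_offset_sd SD (nt) of the rounded-Gaussian 5'/3' end
#'   offsets that create isomiRs.
#' @param reads_per_precursor_range per-precursor read count bounds.
#' @param ncrna_class_rates named fractions of total reads per ncRNA class.
#' @param degradation_rate fraction of reads that are random degradation
#'   fragments of the contig pool.
#' @param sirna_rate fraction of reads from dispersed 24-nt siRNA loci.
#' @param n_sirna_loci number of planted siRNA-producing loci.
#' @param n_targets number of target transcripts carrying planted sites.
#' @param n_stages number of mRNA libraries (stages).
#' @param stage_fold_changes optional named list mapping feature id to a
#'   numeric vector of `n_stages` relative abundances; when `NULL` a
#'   default map is drawn (80% flat, 20% with 4-8 fold patterns).
#' @param differential_fraction fraction of features given a non-flat
#'   default stage pattern.
#' @param read_quality_mean Phred score of normal-quality bases.
#' @param low_quality_fraction fraction of sRNA reads emitted below the
#'   quality floor (Phred 8) to exercise the Q<13 filter.
#' @param n_fraction fraction of sRNA reads with an injected N.
#' @param adapter_3p fixed 3' adapter appended to every sRNA insert.
#' @param read_length raw sRNA read length after adapter read-through.
#' @param min_loop minimum hairpin terminal loop, nt.
#' @param arm_mismatch_rate per-base mutation rate on the 3p arm.
#' @param base_offset nt of lower stem below the mature duplex.
#' @param star_fraction fraction of a two-block precursor's reads on the
#'   star arm.
#' @param two_block_fraction fraction of precursors with reads on both arms.
#' @param known_fraction fraction of precursors whose mature is taken from
#'   the synthetic mature-miRNA reference (conserved families).
#' @param mrna_read_length mRNA read length, nt.
#' @param mrna_depth per-stage library depth multiplier (scalar or vector
#'   of `n_stages`).
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 20140213L,
                         n_precursors = 40,
                         precursor_len_range = c(70, 250),
                         precursor_len_mean = 150,
                         precursor_len_sd = 25,
                         gc_range = c(0.39, 0.47),
                         mature_len_range = c(20, 24),
                         isomir_offset_sd = 0.5,
                         reads_per_precursor_range = c(15, 300),
                         ncrna_class_rates = c(rRNA = 0.0694, tRNA = 0.0060,
                                               snRNA = 0.0005, snoRNA = 0.0005,
                                               cpRNA = 0.0190, mtRNA = 0.0025),
                         degradation_rate = 0.10,
                         sirna_rate = 0.05,
                         n_sirna_loci = 5,
                         n_targets = 25,
                         n_stages = 3,
                         stage_fold_changes = NULL,
                         differential_fraction = 0.2,
                         read_quality_mean = 30,
                         low_quality_fraction = 0.02,
                         n_fraction = 0.005,
                         adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                         read_length = 36,
                         min_loop = 8,
                         arm_mismatch_rate = 0.10,
                         base_offset = 12,
                         star_fraction = 0.20,
                         two_block_fraction = 0.70,
                         known_fraction = 0.5,
                         mrna_read_length = 50,
                         mrna_depth = 1) {
  cfg <- as.list(environment())
  fracs <- c(cfg$ncrna_class_rates, cfg$degradation_rate, cfg$sirna_rate,
             cfg$low_quality_fraction, cfg$n_fraction, cfg$star_fraction,
             cfg$two_block_fraction, cfg$known_fraction,
             cfg$differential_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("synth_config(): all fractions must lie in [0, 1]")
  if (sum(cfg$ncrna_class_rates) + cfg$degradation_rate + cfg$sirna_rate >= 1)
    stop("synth_config(): class rates plus degradation/siRNA must sum to < 1")
  for (rng in list(cfg$precursor_len_range, cfg$mature_len_range,
                   cfg$reads_per_precursor_range, cfg$gc_range))
    if (length(rng) != 2 || diff(rng) < 0)
      stop("synth_config(): ranges must be ordered pairs")
  req <- 2 * cfg$mature_len_range[2] + cfg$min_loop
  if (cfg$precursor_len_range[1] < req)
    stop(sprintf("synth_config(): precursor_len_range[1] must be >= %d", req))
  class(cfg) <- "synth_config"
  cfg
}

# sRNA read-length distribution for non-precursor sources: 24-nt dominated,
# with the secondary 21/22-nt modes typical of seed libraries (internal)
srna_length_probs <- function() {
  p <- c(`18` = 0.0265, `19` = 0.0320, `20` = 0.0361, `21` = 0.2056,
         `22` = 0.1628, `23` = 0.0957, `24` = 0.4128, `25` = 0.0285)
  p / sum(p)
}

#' Generate one hairpin precursor
#'
#' Constructs a stem-loop sequence: a random 5p arm, a terminal loop, and a
#' 3p arm that is the reverse complement of the 5p arm apart from a per-base
#' mismatch rate. The mature duplex sits `base_offset` nt above the stem
#' base; when `mature_seq` is supplied it is embedded exactly on the
#' requested arm (its duplex partner is protected from mutation so that the
#' embedded sequence is preserved).
#'
#' Uses the R session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param length total precursor length, nt; must be at least
#'   `2 * mature_len + min_loop`.
#' @param gc target GC fraction.
#' @param mature_len mature miRNA length, nt (ignored when `mature_seq`
#'   is given).
#' @param min_loop minimum terminal loop size, nt.
#' @param mismatch_rate per-base mutation rate applied to the 3p arm.
#' @param base_offset nt of stem below the mature duplex.
#' @param mature_arm "5p" or "3p": the arm carrying the mature miRNA.
#' @param mature_seq optional RNA sequence to embed as the mature miRNA.
#' @return list with `sequence` (RNA), `mature_5p`, `mature_3p`, `loop`
#'   (1-based inclusive spans), `mature_arm`, and `mature_seq` (the exact
#'   sequence of the mature span on the chosen arm).
#' @export
generate_hairpin <- function(length, gc = 0.45, mature_len = 21,
                             min_loop = 8, mismatch_rate = 0.10,
                             base_offset = 12, mature_arm = "5p",
                             mature_seq = NULL) {
  if (!is.null(mature_seq)) {
    mature_seq <- norm_rna(mature_seq)
    mature_len <- nchar(mature_seq)
  }
  if (length < 2 * mature_len + min_loop)
    stop(sprintf("generate_hairpin(): length %d too short for mature %d nt",
                 length, mature_len))
  arm <- (length - min_loop) %/% 2
  loop_len <- length - 2L * arm
  arm5 <- strsplit(random_seq(arm, gc), "")[[1]]

  start0 <- min(base_offset, arm - mature_len) # 0-based offset into the arm
  span5 <- c(start0 + 1L, start0 + mature_len)
  if (!is.null(mature_seq)) {
    emb <- if (mature_arm == "5p") mature_seq else revcomp(mature_seq, "rna")
    arm5[span5[1]:span5[2]] <- strsplit(emb, "")[[1]]
  }

  # 3p arm: mutated reverse complement of the 5p arm
  comp <- chartr("ACGU", "UGCA", paste(rev(arm5), collapse = ""))
  arm3 <- strsplit(comp, "")[[1]]
  span3 <- c(length - start0 - mature_len + 1L, length - start0)
  protected <- if (!is.null(mature_seq) && mature_arm == "3p") {
    (span3[1]:span3[2]) - (arm + loop_len) # 3p-arm-local indices
  } else integer(0)
  # deterministic mismatch count: variance in stem quality comes from
  # position and identity draws, not from a Binomial count
  eligible <- setdiff(seq_len(arm), protected)
  n_mut <- min(round(mismatch_rate * arm), length(eligible))
  mut <- sample(eligible, n_mut)
  base_w <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  for (k in mut) {
    cand <- setdiff(c("A", "C", "G", "U"), arm3[k])
    # composition-weighted replacement keeps the GC target unbiased
    arm3[k] <- sample(cand, 1, prob = base_w[cand])
  }

  seq <- paste0(paste(arm5, collapse = ""),
                random_seq(loop_len, gc),
                paste(arm3, collapse = ""))
  mat_span <- if (mature_arm == "5p") span5 else span3
  list(sequence = seq,
       mature_5p = span5,
       mature_3p = span3,
       loop = c(arm + 1L, arm + loop_len),
       mature_arm = mature_arm,
       mature_seq = substr(seq, mat_span[1], mat_span[2]))
}

# truncated-normal integer draw by rejection (internal)
rtrunc_len <- function(n, mean, sd, range) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic mature-miRNA reference
#'
#' Random mature sequences under miRBase-style headers
#' (`xxx-miR<family><letter>`), grouped into conserved families. Used both
#' as the matching reference for conserved-miRNA identification and as the
#' source of "known" matures planted in precursors.
#'
#' @param n_families number of families.
#' @param members_per_family range of member counts per family.
#' @param length_range mature length bounds, nt.
#' @return data.frame with columns `id`, `family`, `sequence` (RNA).
#' @export
generate_mature_reference <- function(n_families = 12,
                                      members_per_family = c(1, 4),
                                      length_range = c(20, 22)) {
  fam_num <- sample(c(156, 157, 159, 160, 164, 166, 167, 168, 169, 171,
                      172, 319, 390, 396, 398, 408), n_families)
  rows <- lapply(seq_len(n_families), function(i) {
    k <- sample(members_per_family[1]:members_per_family[2], 1)
    data.frame(
      id = sprintf("syn-miR%d%s", fam_num[i], letters[seq_len(k)]),
      family = sprintf("MIR%d", fam_num[i]),
      sequence = vapply(seq_len(k), function(j)
        random_seq(sample(length_range[1]:length_range[2], 1), 0.45),
        character(1)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate synthetic ncRNA reference sets
#'
#' Random reference sequences per non-coding/organellar class, used by the
#' generator to emit contaminant reads and by the classifier as the
#' filtering reference.
#'
#' @param config a [synth_config()].
#' @param n_per_class references per class.
#' @return named list of [Biostrings::DNAStringSet], one per class.
#' @export
generate_ncrna_references <- function(config, n_per_class = 4) {
  lens <- list(rRNA = c(800, 1800), tRNA = c(70, 90), snRNA = c(100, 200),
               snoRNA = c(60, 150), cpRNA = c(300, 900), mtRNA = c(300, 900))
  out <- lapply(names(config$ncrna_class_rates), function(cl) {
    lr <- lens[[cl]]
    seqs <- vapply(seq_len(n_per_class), function(i)
      norm_dna(random_seq(sample(lr[1]:lr[2], 1), runif(1, 0.4, 0.55))),
      character(1))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sprintf("%s_ref%d", cl, seq_len(n_per_class))
    x
  })
  names(out) <- names(config$ncrna_class_rates)
  out
}

# sample a read of given length from a random position of a random
# reference sequence (internal); returns RNA-alphabet inserts
sample_fragments <- function(refs, lengths) {
  refs <- as.character(refs)
  widths <- nchar(refs)
  vapply(lengths, function(l) {
    ok <- which(widths >= l)
    r <- refs[[ok[sample.int(length(ok), 1)]]]
    s <- sample.int(nchar(r) - l + 1L, 1)
    frag <- substr(r, s, s + l - 1L)
    if (runif(1) < 0.5) frag <- revcomp(frag)
    norm_rna(frag)
  }, character(1))
}

#' Generate the synthetic small-RNA library
#'
#' Emits FASTQ-style reads from four sources: (a) mature/isomiR positions
#' on the true precursors, with independent rounded-Gaussian 5'/3' end
#' offsets truncated to the precursor; (b) ncRNA references at the
#' configured class rates; (c) random degradation fragments of the contig
#' pool; (d) dispersed 24-nt reads from planted siRNA loci. Every read is
#' recorded in the truth ledger. A fixed 3' adapter is appended and reads
#' are truncated to `read_length`; a configured fraction is emitted at low
#' quality or with an injected N.
#'
#' @param config a [synth_config()].
#' @param precursors truth precursor table from [simulate_study()].
#' @param precursor_seqs named RNA character vector of precursor sequences.
#' @param ncrna_refs named list of class references.
#' @param contigs [Biostrings::DNAStringSet] contig pool (for degradation).
#' @param sirna_loci truth table of planted siRNA loci (or NULL).
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and
#'   `read_labels` (data.frame `read_id`, `source`, `feature`, `insert`).
#' @export
generate_srna_library <- function(config, precursors, precursor_seqs,
                                  ncrna_refs, contigs, sirna_loci = NULL) {
  if (nrow(precursors) == 0 && config$n_precursors > 0)
    stop("generate_srna_library(): empty precursor set")
  inserts <- character(0)
  source <- character(0)
  feature <- character(0)

  # (a) precursor-derived mature/isomiR reads
  for (i in seq_len(nrow(precursors))) {
    p <- precursors[i, ]
    seq_i <- precursor_seqs[[p$id]]
    n_i <- p$n_reads
    n_star <- if (p$two_block) rbinom(1, n_i, config$star_fraction) else 0L
    spans <- rbind(
      matrix(rep(c(p$mat_start, p$mat_end), n_i - n_star), ncol = 2,
             byrow = TRUE),
      matrix(rep(c(p$star_start, p$star_end), n_star), ncol = 2,
             byrow = TRUE))
    off5 <- round(rnorm(nrow(spans), 0, config$isomir_offset_sd))
    off3 <- round(rnorm(nrow(spans), 0, config$isomir_offset_sd))
    s <- pmax(1L, spans[, 1] + off5)
    e <- pmin(nchar(seq_i), spans[, 2] + off3)
    keep <- e - s + 1L >= 15L
    frag <- substring(seq_i, s[keep], e[keep])
    inserts <- c(inserts, frag)
    source <- c(source, rep("mirna", sum(keep)))
    feature <- c(feature, rep(p$id, sum(keep)))
  }
  n_prec_reads <- length(inserts)

  # split the remaining sources multinomially, consistent with their rates
  rates <- c(config$ncrna_class_rates,
             degradation = config$degradation_rate,
             siRNA = if (is.null(sirna_loci)) 0 else config$sirna_rate)
  frac_prec <- 1 - sum(rates)
  total <- round(n_prec_reads / frac_prec)
  n_other <- total - n_prec_reads
  alloc <- if (n_other > 0 && sum(rates) > 0)
    as.integer(rmultinom(1, n_other, rates / sum(rates)))
  else integer(length(rates))
  names(alloc) <- names(rates)

  probs <- srna_length_probs()
  draw_lengths <- function(n) as.integer(
    sample(names(probs), n, replace = TRUE, prob = probs))

  # (b) ncRNA contaminants
  for (cl in names(config$ncrna_class_rates)) {
    n_cl <- alloc[[cl]]
    if (n_cl == 0) next
    frags <- sample_fragments(ncrna_refs[[cl]], draw_lengths(n_cl))
    inserts <- c(inserts, frags)
    source <- c(source, rep(cl, n_cl))
    feature <- c(feature, rep(NA_character_, n_cl))
  }

  # (c) degradation fragments of the contig pool
  if (alloc[["degradation"]] > 0) {
    n_d <- alloc[["degradation"]]
    frags <- sample_fragments(contigs, draw_lengths(n_d))
    inserts <- c(inserts, frags)
    source <- c(source, rep("degradation", n_d))
    feature <- c(feature, rep(NA_character_, n_d))
  }

  # (d) dispersed 24-nt siRNA locus reads
  if (!is.null(sirna_loci) && alloc[["siRNA"]] > 0) {
    n_s <- alloc[["siRNA"]]
    li <- sample.int(nrow(sirna_loci), n_s, replace = TRUE)
    starts <- mapply(function(a, b) sample(a:(b - 23L), 1),
                     sirna_loci$start[li], sirna_loci$end[li])
    frags <- norm_rna(substring(as.character(contigs[sirna_loci$contig[li]]),
                                starts, starts + 23L))
    flip <- runif(n_s) < 0.5
    frags[flip] <- revcomp(frags[flip], "rna")
    inserts <- c(inserts, frags)
    source <- c(source, rep("siRNA", n_s))
    feature <- c(feature, sirna_loci$id[li])
  }

  n <- length(inserts)
  perm <- sample.int(n)
  inserts <- inserts[perm]; source <- source[perm]; feature <- feature[perm]
  ids <- sprintf("read%06d", seq_len(n))

  # raw reads: insert + 3' adapter, truncated to the machine read length
  raw <- substr(paste0(norm_dna(inserts), config$adapter_3p,
                       strrep("A", config$read_length)),
                1L, config$read_length)
  q_hi <- rawToChar(as.raw(33L + config$read_quality_mean))
  q_lo <- rawToChar(as.raw(33L + 8L))
  lowq <- runif(n) < config$low_quality_fraction
  qual <- ifelse(lowq, strrep(q_lo, config$read_length),
                 strrep(q_hi, config$read_length))
  with_n <- runif(n) < config$n_fraction
  if (any(with_n)) {
    pos <- sample.int(config$read_length, sum(with_n), replace = TRUE)
    substr(raw[with_n], pos, pos) <- "N"
  }

  list(reads = data.frame(id = ids, seq = raw, qual = qual,
                          stringsAsFactors = FALSE),
       read_labels = data.frame(read_id = ids, source = source,
                                feature = feature, insert = inserts,
                                low_quality = lowq, has_n = with_n,
                                stringsAsFactors = FALSE))
}

#' Generate stage-wise mRNA read sets
#'
#' Per-stage read counts per feature are Poisson with mean
#' `base_mean * fold_change * depth`; reads are sampled uniformly within the
#' feature span (both orientations) so that zero-mismatch counting against
#' the feature sequence recovers the truth.
#'
#' @param config a [synth_config()].
#' @param contigs contig pool.
#' @param features data.frame with `id`, `contig`, `start`, `end` (1-based
#'   spans of countable features: precursors and target transcripts).
#' @param stage_fold_changes named list `feature -> n_stages multipliers`;
#'   drawn by default.
#' @return list with `stage_reads` (list of data.frames `id`, `seq`),
#'   `abundance` (feature x stage expected counts) and `fold_changes`.
#' @export
generate_mrna_libraries <- function(config, contigs, features,
                                    stage_fold_changes = NULL) {
  n_st <- config$n_stages
  depth <- rep(config$mrna_depth, length.out = n_st)
  if (is.null(stage_fold_changes)) stage_fold_changes <- config$stage_fold_changes
  if (is.null(stage_fold_changes)) {
    patterns <- list(c(1, 1, 8), c(8, 1, 1), c(1, 8, 1), c(1, 4, 8),
                     c(8, 4, 1))
    stage_fold_changes <- lapply(seq_len(nrow(features)), function(i) {
      if (runif(1) < config$differential_fraction)
        patterns[[sample.int(length(patterns), 1)]][seq_len(n_st)]
      else rep(1, n_st)
    })
    names(stage_fold_changes) <- features$id
  }
  base_mean <- exp(runif(nrow(features), log(30), log(300)))
  expected <- t(vapply(seq_len(nrow(features)), function(i) {
    base_mean[i] * stage_fold_changes[[features$id[i]]] * depth
  }, numeric(n_st)))
  colnames(expected) <- sprintf("L%d", seq_len(n_st))

  contig_chr <- as.character(contigs)
  stage_reads <- lapply(seq_len(n_st), function(st) {
    seqs <- character(0)
    feat <- character(0)
    for (i in seq_len(nrow(features))) {
      n_i <- rpois(1, expected[i, st])
      if (n_i == 0) next
      f <- features[i, ]
      span_len <- f$end - f$start + 1L
      rl <- min(config$mrna_read_length, span_len)
      s <- f$start + sample.int(span_len - rl + 1L, n_i, replace = TRUE) - 1L
      frag <- substring(contig_chr[[f$contig]], s, s + rl - 1L)
      flip <- runif(n_i) < 0.5
      frag[flip] <- revcomp(frag[flip])
      seqs <- c(seqs, frag)
      feat <- c(feat, rep(f$id, n_i))
    }
    ord <- sample.int(length(seqs))
    # the source feature rides in the read id: this is the truth ledger
    # for per-stage counts
    data.frame(id = sprintf("L%d_%s_read%06d", st, feat[ord],
                            seq_along(ord)),
               seq = seqs[ord], feature = feat[ord],
               stringsAsFactors = FALSE)
  })
  names(stage_reads) <- sprintf("L%d", seq_len(n_st))

  abundance <- data.frame(feature = features$id, expected,
                          stringsAsFactors = FALSE)
  list(stage_reads = stage_reads, abundance = abundance,
       fold_changes = stage_fold_changes)
}

#' Simulate a complete synthetic study
#'
#' Coordinates all generators under one seed: mature-miRNA and ncRNA
#' references, precursor hairpins embedded in host contigs, decoy and
#' siRNA-locus contigs, target transcripts with planted miRNA sites, the
#' sRNA FASTQ library, and three stage-wise mRNA read sets — together with
#' the truth ledger used by every validation test.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_study` with elements `config`,
#'   `mature_reference`, `ncrna_refs`, `contigs`, `precursors` (truth),
#'   `precursor_seqs`, `sirna_loci`, `target_sites`, `features`, `srna`
#'   (reads + labels), and `mrna` (stage reads + abundance truth).
#' @export
simulate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)

  mature_ref <- generate_mature_reference()
  ncrna_refs <- generate_ncrna_references(config)

  n <- config$n_precursors
  lens <- rtrunc_len(n, config$precursor_len_mean, config$precursor_len_sd,
                     config$precursor_len_range)
  gcs <- runif(n, config$gc_range[1], config$gc_range[2])
  known <- seq_len(n) <= round(config$known_fraction * n)
  arms <- sample(c("5p", "3p"), n, replace = TRUE)
  two_block <- runif(n) < config$two_block_fraction
  n_reads <- round(runif(n, config$reads_per_precursor_range[1],
                         config$reads_per_precursor_range[2]))

  prec_rows <- list()
  precursor_seqs <- character(0)
  contig_seqs <- character(0)
  contig_names <- character(0)

  for (i in seq_len(n)) {
    mat_seq <- if (known[i]) mature_ref$sequence[sample.int(nrow(mature_ref), 1)]
               else NULL
    hp <- generate_hairpin(lens[i], gcs[i],
                           mature_len = sample(config$mature_len_range[1]:
                                               config$mature_len_range[2], 1),
                           min_loop = config$min_loop,
                           mismatch_rate = config$arm_mismatch_rate,
                           base_offset = config$base_offset,
                           mature_arm = arms[i], mature_seq = mat_seq)
    pid <- sprintf("prec%03d", i)
    cid <- sprintf("contig_p%03d", i)
    f5 <- norm_dna(random_seq(sample(30:120, 1), gcs[i]))
    f3 <- norm_dna(random_seq(sample(30:120, 1), gcs[i]))
    offset <- nchar(f5) + 1L
    contig_seqs <- c(contig_seqs, paste0(f5, norm_dna(hp$sequence), f3))
    contig_names <- c(contig_names, cid)
    precursor_seqs[pid] <- hp$sequence
    mat <- if (arms[i] == "5p") hp$mature_5p else hp$mature_3p
    star <- if (arms[i] == "5p") hp$mature_3p else hp$mature_5p
    prec_rows[[i]] <- data.frame(
      id = pid, contig = cid, offset = offset, length = lens[i],
      mature_arm = arms[i], mat_start = mat[1], mat_end = mat[2],
      star_start = star[1], star_end = star[2],
      loop_start = hp$loop[1], loop_end = hp$loop[2],
      mature_seq = hp$mature_seq, known = known[i],
      family = if (known[i])
        mature_ref$family[match(mat_seq, mature_ref$sequence)]
      else NA_character_,
      two_block = two_block[i], n_reads = n_reads[i],
      stringsAsFactors = FALSE)
  }
  precursors <- do.call(rbind, prec_rows)

  # target transcripts with planted sites
  mat_pool <- unique(precursors$mature_seq)
  target_rows <- list()
  for (j in seq_len(config$n_targets)) {
    cid <- sprintf("contig_t%03d", j)
    L <- sample(300:800, 1)
    s <- norm_dna(random_seq(L, runif(1, 0.40, 0.52)))
    mir <- mat_pool[[sample.int(length(mat_pool), 1)]]
    site <- revcomp(mir) # perfect complement, DNA
    # planted penalty: 0 (perfect) or 1-3 via mismatches outside the seed
    n_mm <- sample(0:2, 1, prob = c(0.5, 0.3, 0.2))
    penalty <- 0
    if (n_mm > 0) {
      m <- nchar(mir)
      # miRNA positions 14..m-1 carry weight 1 (outside seed-doubled region)
      pos <- sample(14:(m - 1), n_mm)
      for (pp in pos) {
        tpos <- m - pp + 1L # site index pairing miRNA position pp
        old <- substr(site, tpos, tpos)
        mirb <- substr(norm_dna(mir), pp, pp)
        # replace with a base that neither pairs nor wobbles
        bad <- setdiff(c("A", "C", "G", "T"),
                       c(old, chartr("ACGT", "TGCA", mirb),
                         if (mirb == "G") "T" else if (mirb == "T") "G"))
        substr(site, tpos, tpos) <- sample(bad, 1)
        penalty <- penalty + 1
      }
    }
    at <- sample(50:(L - nchar(site) - 50), 1)
    substr(s, at, at + nchar(site) - 1L) <- site
    contig_seqs <- c(contig_seqs, s)
    contig_names <- c(contig_names, cid)
    target_rows[[j]] <- data.frame(
      mirna_seq = mir, transcript = cid, start = at,
      end = at + nchar(site) - 1L, planted_expectation = penalty,
      stringsAsFactors = FALSE)
  }
  target_sites <- do.call(rbind, target_rows)

  # decoy contigs
  for (k in seq_len(15)) {
    contig_seqs <- c(contig_seqs,
                     norm_dna(random_seq(sample(200:600, 1),
                                         runif(1, 0.40, 0.52))))
    contig_names <- c(contig_names, sprintf("contig_d%03d", k))
  }

  # siRNA locus contigs
  sirna_rows <- list()
  for (m in seq_len(config$n_sirna_loci)) {
    cid <- sprintf("contig_s%03d", m)
    L <- sample(300:500, 1)
    contig_seqs <- c(contig_seqs, norm_dna(random_seq(L, runif(1, .4, .52))))
    contig_names <- c(contig_names, cid)
    a <- sample(20:60, 1)
    b <- a + sample(200:min(380, L - a - 20), 1)
    sirna_rows[[m]] <- data.frame(id = sprintf("sirna%02d", m), contig = cid,
                                  start = a, end = b,
                                  stringsAsFactors = FALSE)
  }
  sirna_loci <- do.call(rbind, sirna_rows)

  contigs <- Biostrings::DNAStringSet(contig_seqs)
  names(contigs) <- contig_names

  srna <- generate_srna_library(config, precursors, precursor_seqs,
                                ncrna_refs, contigs, sirna_loci)

  features <- rbind(
    data.frame(id = precursors$id, contig = precursors$contig,
               start = precursors$offset,
               end = precursors$offset + precursors$length - 1L,
               type = "precursor", stringsAsFactors = FALSE),
    data.frame(id = unique(target_sites$transcript),
               contig = unique(target_sites$transcript),
               start = 1L,
               end = Biostrings::width(contigs)[
                 match(unique(target_sites$transcript), names(contigs))],
               type = "target", stringsAsFactors = FALSE))

  mrna <- generate_mrna_libraries(config, contigs, features)

  structure(list(config = config, mature_reference = mature_ref,
                 ncrna_refs = ncrna_refs, contigs = contigs,
                 precursors = precursors, precursor_seqs = precursor_seqs,
                 sirna_loci = sirna_loci, target_sites = target_sites,
                 features = features, srna = srna, mrna = mrna),
            class = "synth_study")
}

#' Write a simulated study to disk
#'
#' Emits the study as the plain-text formats the pipeline consumes:
#' sRNA FASTQ, per-class ncRNA FASTA, mature reference FASTA, contig FASTA,
#' per-stage mRNA FASTA, and TSV truth ledgers.
#'
#' @param study a `synth_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(study$srna$reads, file.path(dir, "srna.fastq"))
  write_fasta(setNames(norm_dna(study$mature_reference$sequence),
                       study$mature_reference$id),
              file.path(dir, "mature_reference.fasta"))
  for (cl in names(study$ncrna_refs))
    write_fasta(study$ncrna_refs[[cl]],
                file.path(dir, sprintf("ncrna_%s.fasta", cl)))
  write_fasta(study$contigs, file.path(dir, "contigs.fasta"))
  for (st in names(study$mrna$stage_reads)) {
    df <- study$mrna$stage_reads[[st]]
    write_fasta(setNames(df$seq, df$id),
                file.path(dir, sprintf("mrna_%s.fasta", st)))
  }
  write_tsv(study$precursors, file.path(dir, "truth_precursors.tsv"))
  write_tsv(study$srna$read_labels, file.path(dir, "truth_read_labels.tsv"))
  write_tsv(study$sirna_loci, file.path(dir, "truth_sirna_loci.tsv"))
  write_tsv(study$target_sites, file.path(dir, "truth_target_sites.tsv"))
  write_tsv(study$mrna$abundance, file.path(dir, "truth_abundance.tsv"))
  invisible(dir)
}
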