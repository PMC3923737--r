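test_that("hairpin construction places the mature duplex inside the arms", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(70:250, 1)
    hp <- generate_hairpin(L, gc = 0.45, mature_len = 21)
    arm <- (L - 8) %/% 2
    expect_equal(nchar(hp$sequence), L)
    expect_true(hp$mature_5p[1] >= 1 && hp$mature_5p[2] <= arm)
    expect_true(hp$mature_3p[1] > hp$loop[2] && hp$mature_3p[2] <= L)
    expect_gte(hp$loop[2] - hp$loop[1] + 1, 8)
  }
  expect_error(generate_hairpin(40, mature_len = 21), "too short")
})

test_that("with no mismatches the 3p arm is the exact reverse complement", {
  set.seed(102)
  hp <- generate_hairpin(120, gc = 0.5, mature_len = 21, mismatch_rate = 0)
  arm <- (120 - 8) %/% 2
  a5 <- substr(hp$sequence, 1, arm)
  a3 <- substr(hp$sequence, 120 - arm + 1, 120)
  expect_equal(a3, revcomp(a5, "rna"))
})

test_that("generated GC content concentrates on the request", {
  set.seed(103)
  gcs <- replicate(1000, {
    hp <- generate_hairpin(100, gc = 0.45, mature_len = 21)
    gc_percent(hp$sequence) / 100
  })
  expect_lt(abs(mean(gcs) - 0.45), 0.01)
  # bulk within the +-0.05 construction target; arm mutations can push a
  # small tail slightly beyond it
  expect_lte(quantile(abs(gcs - 0.45), 0.99), 0.055)
  expect_true(all(abs(gcs - 0.45) < 0.08))
})

test_that("an embedded mature sequence survives construction on either arm", {
  set.seed(104)
  mat <- "UGAUUGAGCCGUGCCAAUAUC"
  for (arm in c("5p", "3p")) {
    hp <- generate_hairpin(140, gc = 0.45, mature_arm = arm,
                           mature_seq = mat)
    expect_equal(hp$mature_seq, mat)
    span <- if (arm == "5p") hp$mature_5p else hp$mature_3p
    expect_equal(substr(hp$sequence, span[1], span[2]), mat)
  }
})

test_that("the sRNA library conserves reads and labels every one", {
  st <- default_study()
  expect_equal(nrow(st$srna$reads), nrow(st$srna$read_labels))
  expect_identical(st$srna$reads$id, st$srna$read_labels$read_id)
  # class totals are multinomially consistent with the configured rates
  lab <- st$srna$read_labels
  n <- nrow(lab)
  for (cl in c("rRNA", "cpRNA")) {
    rate <- st$config$ncrna_class_rates[[cl]]
    obs <- mean(lab$source == cl)
    expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / n) + 1e-9)
  }
  obs_deg <- mean(lab$source == "degradation")
  expect_lt(abs(obs_deg - st$config$degradation_rate),
            3 * sqrt(0.1 * 0.9 / n))
})

test_that("turning off contaminants yields a pure precursor library", {
  cfg <- synth_config(seed = 7, n_precursors = 6,
                      ncrna_class_rates = c(rRNA = 0, tRNA = 0, snRNA = 0,
                                            snoRNA = 0, cpRNA = 0,
                                            mtRNA = 0),
                      degradation_rate = 0, sirna_rate = 0, n_sirna_loci = 1,
                      n_targets = 3)
  st <- simulate_study(cfg)
  expect_true(all(st$srna$read_labels$source == "mirna"))
})

test_that("identical seeds reproduce the study byte for byte", {
  cfg <- synth_config(seed = 42, n_precursors = 8, n_targets = 4,
                      n_sirna_loci = 2)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$srna$reads, b$srna$reads)
  expect_identical(as.character(a$contigs), as.character(b$contigs))
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(a$srna$reads, f1)
  write_fastq(b$srna$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("stage read counts are Poisson around the recorded abundances", {
  cfg <- synth_config(seed = 33, n_precursors = 120, n_targets = 80,
                      reads_per_precursor_range = c(15, 40),
                      differential_fraction = 0)
  st <- simulate_study(cfg)
  ab <- st$mrna$abundance
  expect_gte(nrow(ab), 200)
  for (stage in c("L1", "L2")) {
    reads <- st$mrna$stage_reads[[stage]]
    obs <- table(factor(reads$feature, levels = ab$feature))
    exp_cnt <- ab[[stage]]
    use <- exp_cnt >= 20
    chi <- sum((as.numeric(obs[use]) - exp_cnt[use])^2 / exp_cnt[use])
    p <- pchisq(chi, df = sum(use), lower.tail = FALSE)
    expect_gt(p, 0.005)
    expect_lt(p, 0.995)
  }
})

test_that("exact-containment counting recovers the planted stage counts", {
  st <- default_study()
  feats <- st$features[st$features$type == "precursor", ]
  refs <- setNames(substring(as.character(st$contigs[feats$contig]),
                             feats$start, feats$end), feats$id)
  reads <- st$mrna$stage_reads$L1
  prec_reads <- reads$seq[reads$feature %in% feats$id]
  counts <- count_reads(prec_reads, refs, max_mismatch = 0)
  exp_cnt <- st$mrna$abundance$L1[match(names(counts),
                                        st$mrna$abundance$feature)]
  # column total within 3 Poisson SDs of the planted expectation
  expect_lt(abs(sum(counts) - sum(exp_cnt)), 3 * sqrt(sum(exp_cnt)))
  # and per-feature agreement for well-covered features
  use <- exp_cnt >= 50
  expect_true(all(abs(counts[use] - exp_cnt[use]) <=
                    4 * sqrt(exp_cnt[use])))
})

test_that("flat fold changes give equal expected counts and depth scales them", {
  cfg <- synth_config(seed = 9, n_precursors = 6, n_targets = 3,
                      differential_fraction = 0)
  st <- simulate_study(cfg)
  ab <- st$mrna$abundance
  expect_equal(ab$L1, ab$L2)
  expect_equal(ab$L2, ab$L3)
  cfg2 <- synth_config(seed = 9, n_precursors = 6, n_targets = 3,
                       differential_fraction = 0, mrna_depth = 2)
  st2 <- simulate_study(cfg2)
  expect_equal(st2$mrna$abundance$L1, 2 * ab$L1)
})

test_that("config validation rejects malformed settings", {
  expect_error(synth_config(degradation_rate = 1.5), "fractions")
  expect_error(synth_config(precursor_len_range = c(250, 70)), "ordered")
  expect_error(synth_config(ncrna_class_rates = c(rRNA = 0.95),
                            degradation_rate = 0.1), "sum")
  expect_error(synth_config(precursor_len_range = c(40, 250)), ">=")
})
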