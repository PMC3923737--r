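test_that("anchoring reports every perfect occurrence on both strands", {
  tag <- "ACGUAGGCCAUGGAUCGAUCG"
  ctg <- paste0("TTTT", norm_dna(tag), "AAAACCCC", norm_dna(tag), "GG")
  contigs <- c(c1 = ctg, c2 = paste0("AT", revcomp(norm_dna(tag)), "CG"))
  tags <- data.frame(sequence = tag, count = 9L)
  a <- anchor_tags(tags, contigs)
  expect_equal(sum(a$contig == "c1" & a$strand == "+"), 2)
  m <- a[a$contig == "c2", ]
  expect_equal(m$strand, "-")
  # coordinates recover the tag (reverse complement on the minus strand)
  seg <- substr(contigs[["c2"]], m$start, m$end)
  expect_equal(norm_rna(revcomp(seg)), tag)
})

test_that("block detection clusters 5' starts and judges the pattern", {
  mk_anchor <- function(starts, counts, strand = "+")
    data.frame(sequence = strrep("A", 21), count = counts, contig = "c",
               start = starts, end = starts + 20L, strand = strand)
  # two tight clusters: a valid two-block pattern
  a <- mk_anchor(c(100, 101, 102, 160, 161), c(30, 10, 5, 20, 8))
  bl <- detect_blocks(a, delta = 3)
  expect_equal(nrow(bl$blocks), 2)
  expect_true(bl$verdicts$valid)
  # an even smear every 5 nt: many blocks, no containment
  b <- mk_anchor(seq(100, 300, by = 5), rep(5, 41))
  bl2 <- detect_blocks(b, delta = 3)
  expect_gt(nrow(bl2$blocks), 2)
  expect_false(bl2$verdicts$valid)
})

test_that("window excision does block-span arithmetic and clips at edges", {
  blocks <- data.frame(contig = "c", strand = "+", block = 1:2,
                       span_start = c(101L, 161L), span_end = c(121L, 180L),
                       n_anchors = c(3L, 2L), total_reads = c(40L, 12L))
  verd <- data.frame(contig = "c", strand = "+", n_blocks = 2L,
                     top2_fraction = 1, valid = TRUE)
  contigs <- c(c = strrep("A", 400))
  w <- extract_windows(blocks, verd, contigs, flank = 20)
  two <- w[w$kind == "two_block", ]
  expect_equal(c(two$start, two$end), c(81L, 200L))
  # a block at the contig edge clips to bounds
  blocks2 <- blocks[1, ]; blocks2$span_start <- 5L; blocks2$span_end <- 25L
  verd2 <- verd; verd2$n_blocks <- 1L
  w2 <- extract_windows(blocks2, verd2, contigs, flank = 20)
  expect_true(all(w2$start >= 1 & w2$end <= 400))
  # windows below the minimum usable size are dropped with a reason
  contigs3 <- c(c = strrep("A", 30))
  blocks3 <- blocks[1, ]; blocks3$span_start <- 5L; blocks3$span_end <- 25L
  w3 <- extract_windows(blocks3, verd2, contigs3, flank = 2, ext = 0)
  expect_true(all(w3$dropped))
  expect_true(all(w3$reason == "window_too_short"))
})

test_that("candidate evaluation applies each criterion and records reasons", {
  set.seed(501)
  hp <- generate_hairpin(150, gc = 0.43, mature_len = 21, mismatch_rate = 0.1)
  ctg <- c(host = paste0(strrep("T", 60), norm_dna(hp$sequence),
                         strrep("G", 60)))
  mat <- substr(hp$sequence, hp$mature_5p[1], hp$mature_5p[2])
  star <- substr(hp$sequence, hp$mature_3p[1], hp$mature_3p[2])
  tags <- data.frame(sequence = c(mat, star), count = c(12L, 3L))
  disc <- discover_precursors(tags, ctg, criteria = precursor_criteria())
  expect_equal(length(disc$accepted), 1)
  cl <- disc$accepted[[1]]
  expect_true(all(cl$flags))
  expect_equal(cl$mature_arm, "5p")
  expect_equal(cl$canonical$sequence, mat)
  expect_equal(cl$isomirs$sequence, star)
  # same geometry with 9 reads fails the read threshold
  tags2 <- data.frame(sequence = c(mat, star), count = c(6L, 3L))
  disc2 <- discover_precursors(tags2, ctg)
  expect_equal(length(disc2$accepted), 0)
  expect_true(any(grepl("min_reads", disc2$table$reject_reasons)))
  # a tag centered on the terminal loop violates the arm rule
  loop_mid <- (hp$loop[1] + hp$loop[2]) %/% 2
  ltag <- substr(hp$sequence, loop_mid - 10, loop_mid + 10)
  disc3 <- discover_precursors(data.frame(sequence = ltag, count = 30L), ctg)
  expect_equal(length(disc3$accepted), 0)
  expect_true(any(grepl("arm_overlap", disc3$table$reject_reasons)))
})

test_that("canonical assignment takes the top count with lexicographic ties", {
  call <- structure(list(
    anchors = data.frame(sequence = c("UUUU", "AAAA", "CCCC"),
                         count = c(100L, 100L, 30L),
                         wstart = c(10L, 10L, 60L), wend = c(13L, 13L, 63L)),
    loop = c(30, 40)), class = "precursor_call")
  out <- assign_canonical(call)
  expect_equal(out$canonical$sequence, "AAAA") # tie broken lexicographically
  expect_equal(out$canonical$arm, "5p")
  expect_equal(nrow(out$isomirs), 2)
  expect_true(all(out$isomirs$count <= out$canonical$count))
})

test_that("known/novel labels follow the perfect-match rule", {
  ref <- data.frame(id = "xxx-miR1", sequence = "UGAUUGAGCCGUGCCAAUAUC")
  call <- structure(list(canonical = list(sequence = "UGAUUGAGCCGUGCCAAUAUC")),
                    class = "precursor_call")
  expect_equal(classify_known_vs_novel(call, ref)$novelty, "known")
  call$canonical$sequence <- "UGAUUGAGCCGUGCCAAUAUG"
  expect_equal(classify_known_vs_novel(call, ref)$novelty, "novel")
})

test_that("accepted calls verify their recorded criteria when re-checked", {
  disc <- default_discovery()
  eng <- builtin_fold_engine()
  for (cl in head(disc$accepted, 8)) {
    f <- fold_sequence(eng, cl$sequence)
    expect_equal(f$mfe, cl$mfe)
    expect_equal(f$structure, cl$structure)
    expect_equal(nrow(db_terminal_loops(f$structure)), 1)
    expect_true(abs(cl$mfe) >= 40 && abs(cl$mfe) <= 100)
    expect_gt(abs(cl$mfei), 0.85)
    expect_gte(sum(cl$anchors$count), 10)
    expect_equal(mfei(cl$mfe, cl$length, cl$gc_percent), cl$mfei)
  }
})

test_that("planted mature reads anchor inside their host precursor spans", {
  st <- default_study()
  disc <- default_discovery()
  tr <- st$precursors
  for (i in sample(seq_len(nrow(tr)), 10)) {
    a <- disc$anchors[disc$anchors$contig == tr$contig[i] &
                        disc$anchors$sequence == tr$mature_seq[i] &
                        disc$anchors$strand == "+", ]
    expect_gte(nrow(a), 1)
    expect_true(all(a$start >= tr$offset[i] &
                      a$end <= tr$offset[i] + tr$length[i] - 1))
  }
})
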