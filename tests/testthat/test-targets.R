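mir <- "UGAUUGAGCCGUGCCAAUAUC" # 21 nt

# build a transcript holding a site derived from the perfect complement
with_site <- function(site, pad5 = 40, pad3 = 40, name = "t") {
  setNames(paste0(strrep("A", pad5), site, strrep("G", pad3)), name)
}
perfect_site <- revcomp(mir)

# mutate the site base pairing miRNA position `pos` to a non-pairing,
# non-wobble base
mutate_at <- function(site, pos, m = nchar(mir)) {
  t_idx <- m - pos + 1
  mirb <- substr(norm_dna(mir), pos, pos)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(chartr("ACGT", "TGCA", mirb),
                   if (mirb == "G") "T" else if (mirb == "T") "G"))
  substr(site, t_idx, t_idx) <- bad[1]
  site
}

test_that("a perfect complement scores zero with a cleavage hint", {
  h <- scan_targets(mir, with_site(perfect_site), 4.0)
  expect_equal(nrow(h), 1)
  expect_equal(h$expectation, 0)
  expect_equal(h$inhibition, "cleavage")
  expect_equal(c(h$start, h$end), c(41, 61))
  lines <- strsplit(h$alignment, "\n")[[1]]
  expect_equal(lines[2], strrep("|", 21))
})

test_that("penalties follow the position-weighted scheme", {
  # mismatch at position 15 (outside the seed-proximal region): 1.0
  h15 <- scan_targets(mir, with_site(mutate_at(perfect_site, 15)), 4.0)
  expect_equal(min(h15$expectation), 1.0)
  # mismatch at position 5 (seed-proximal, doubled): 2.0
  h5 <- scan_targets(mir, with_site(mutate_at(perfect_site, 5)), 4.0)
  expect_equal(min(h5$expectation), 2.0)
  # G:U wobble at position 5: 0.5 doubled to 1.0
  m5 <- substr(norm_dna(mir), 5, 5)
  site <- perfect_site
  t_idx <- nchar(mir) - 5 + 1
  substr(site, t_idx, t_idx) <- if (m5 == "G") "T" else "G"
  hgu <- scan_targets(mir, with_site(site), 4.0)
  expect_equal(min(hgu$expectation), 1.0)
  # central mismatch (positions 9-11) switches the hint to translation
  h10 <- scan_targets(mir, with_site(mutate_at(perfect_site, 10)), 4.0)
  best <- h10[which.min(h10$expectation), ]
  expect_equal(best$inhibition, "translation")
})

test_that("the expectation cutoff excludes and filtering is monotone", {
  # 2 seed mismatches + 1 outside: expectation 5 > 4 excluded at 4.0
  site <- mutate_at(mutate_at(mutate_at(perfect_site, 5), 7), 15)
  tx <- with_site(site)
  expect_equal(nrow(scan_targets(mir, tx, 4.0)), 0)
  h5 <- scan_targets(mir, tx, 5.0)
  expect_equal(min(h5$expectation), 5.0)
  # lowering the cutoff never adds hits
  tx2 <- with_site(mutate_at(perfect_site, 15))
  hits_by_cut <- vapply(c(0, 1, 2, 4), function(ct)
    nrow(scan_targets(mir, tx2, ct)), numeric(1))
  expect_true(all(diff(hits_by_cut) >= 0))
})

test_that("expectation is invariant to transcript padding", {
  a <- scan_targets(mir, with_site(perfect_site, 10, 200), 4.0)
  b <- scan_targets(mir, with_site(perfect_site, 300, 15), 4.0)
  expect_equal(a$expectation, b$expectation)
  expect_equal(a$start - 11, b$start - 301)
})

test_that("a single-nt bulge costs 2 (doubled in the seed region)", {
  # insert a bulged nt in the target opposite miRNA positions 15/16
  t_idx <- nchar(mir) - 15 + 1
  site <- paste0(substr(perfect_site, 1, t_idx), "A",
                 substr(perfect_site, t_idx + 1, nchar(perfect_site)))
  h <- scan_targets(mir, with_site(site), 4.0)
  expect_equal(min(h$expectation), 2.0)
})

test_that("planted fixture sites are recovered at their planted scores", {
  st <- default_study()
  ts <- st$target_sites
  perfect <- ts[ts$planted_expectation == 0, ]
  for (i in seq_len(nrow(perfect))) {
    h <- scan_targets(perfect$mirna_seq[i],
                      st$contigs[perfect$transcript[i]], 4.0)
    hit <- h[h$start <= perfect$start[i] & h$end >= perfect$start[i], ]
    expect_gte(nrow(hit), 1)
    expect_equal(min(hit$expectation), 0)
  }
  # imperfect sites (penalties 1-3) are recovered within the 4.0 cutoff
  imp <- ts[ts$planted_expectation > 0, ]
  if (nrow(imp)) {
    rec <- vapply(seq_len(nrow(imp)), function(i) {
      h <- scan_targets(imp$mirna_seq[i], st$contigs[imp$transcript[i]], 4.0)
      any(h$start <= imp$start[i] & h$end >= imp$start[i] &
            h$expectation <= imp$planted_expectation[i] + 1e-9)
    }, logical(1))
    expect_gte(mean(rec), 0.9)
  }
})

test_that("per-miRNA summaries average distinct targets", {
  hits <- data.frame(mirna = c("m1", "m1", "m2"),
                     transcript = c("t1", "t2", "t1"),
                     start = 1L, end = 21L, strand = "+",
                     expectation = 0, inhibition = "cleavage",
                     alignment = "")
  s <- targets_per_mirna_summary(hits)
  expect_equal(s$per_mirna$n_targets[s$per_mirna$mirna == "m1"], 2)
  expect_equal(s$mean_targets, 1.5)
  empty <- targets_per_mirna_summary(hits[0, ])
  expect_equal(nrow(empty$per_mirna), 0)
  expect_true(is.na(empty$mean_targets))
})

test_that("mature length bounds are enforced", {
  expect_error(scan_targets(strrep("A", 17), c(t = strrep("T", 100))),
               "18-25")
})
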