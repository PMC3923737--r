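toy_tags <- function(seqs, counts = rep(1L, length(seqs))) {
  data.frame(sequence = norm_rna(seqs), count = as.integer(counts),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

test_that("classification uses exact containment with the priority order", {
  shared <- "ACGUACGUACGUACGUACGU"
  cp_only <- "GGGGCCCCAAAAUUUUGGCC"
  refs <- list(
    rRNA = paste0("AAAA", norm_dna(shared), "TTTT"),
    tRNA = paste0("CCCC", norm_dna(shared), "GGGG"),
    snRNA = "TTTTTTTTTTTTTTTTTTTTTTTTTTTTTT",
    snoRNA = "GGGGGGGGGGGGGGGGGGGGGGGGGGGGGG",
    cpRNA = paste0("TT", revcomp(cp_only), "AA"), # reverse strand only
    mtRNA = "CACACACACACACACACACACACACACACA")
  tags <- toy_tags(c(shared, cp_only, "AUAUAUGCGCAUAUAUGCGC"))
  cls <- classify_tags(tags, refs)
  expect_equal(cls$ncrna_class,
               c("rRNA",   # hits rRNA and tRNA; priority resolves to rRNA
                 "cpRNA",  # matches only the reverse complement
                 "none"))
  expect_error(classify_tags(tags, list()), "named")
})

test_that("removal retains exactly the unclassified tags and conserves reads", {
  st <- default_study()
  cls <- default_tags()$classified
  rem <- remove_classified(cls)
  expect_true(all(rem$retained$ncrna_class == "none"))
  expect_equal(sum(rem$totals), sum(cls$count))
  expect_equal(nrow(rem$retained) + nrow(rem$removed), nrow(cls))
  # every precursor-derived clean read survives the filter
  lab <- st$srna$read_labels
  mir_inserts <- unique(norm_rna(
    lab$insert[lab$source == "mirna" & !lab$low_quality & !lab$has_n &
                 nchar(lab$insert) >= 18 & nchar(lab$insert) <= 25]))
  expect_true(all(mir_inserts %in% rem$retained$sequence))
})

test_that("observed class fractions track the configured rates", {
  st <- default_study()
  cls <- default_tags()$classified
  n <- sum(cls$count)
  for (cl in c("rRNA", "cpRNA", "tRNA")) {
    rate <- st$config$ncrna_class_rates[[cl]]
    # rates are defined on raw reads; cleaned totals shift them slightly,
    # so allow 3 binomial SDs plus the preprocessing loss margin
    obs <- sum(cls$count[cls$ncrna_class == cl]) / n
    expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / n) + 0.01)
  }
})

test_that("percentages are computed half-up at two decimals", {
  expect_equal(percent(968793, 13953403), 6.94)
  expect_equal(percent(132827, 369493), 35.95)
  expect_equal(percent(0, 100), 0)
  expect_equal(percent(1, 8), 12.50)
  expect_equal(percent(1, 800, 2), 0.13)  # 0.125 rounds half-up
  expect_error(percent(1, 0), "whole")
})

test_that("the filtering summary is internally consistent", {
  cls <- default_tags()$classified
  s <- filter_summary(cls)
  body <- s[s$length != "Total", ]
  tot <- s[s$length == "Total", ]
  class_cols <- paste0(c("rRNA", "tRNA", "snRNA", "snoRNA", "cpRNA",
                         "mtRNA"), "_reads")
  # all-filters column equals the sum of the class columns per length
  expect_equal(body$all_filters_reads,
               as.numeric(rowSums(body[, class_cols])))
  # grand totals equal the column sums over lengths
  expect_equal(tot$total_reads, sum(body$total_reads))
  for (cc in class_cols) expect_equal(tot[[cc]], sum(body[[cc]]))
  # classification is order-independent
  shuf <- cls[sample.int(nrow(cls)), ]
  expect_equal(filter_summary(shuf), s)
})
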