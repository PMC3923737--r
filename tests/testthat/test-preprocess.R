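mkread <- function(seq, q) {
  data.frame(id = paste0("r", seq_along(seq)), seq = seq,
             qual = vapply(seq_along(seq), function(i)
               paste(rawToChar(as.raw(33L + q[[i]])), collapse = ""),
               character(1)),
             stringsAsFactors = FALSE)
}

test_that("quality filtering applies the mean-Phred rule inclusively", {
  reads <- mkread(
    c("ACGTACGTAC", "ACGTACGTAC", "ACGNACGTAC", "ACGTACGTAC"),
    list(rep(13, 10),                  # boundary mean 13: retained
         c(rep(13, 9), 12),            # mean 12.9: removed
         rep(40, 10),                  # contains N at Q40: removed
         rep(30, 10)))                 # clean: retained
  kept <- quality_filter(reads, min_q = 13)
  expect_equal(kept$id, c("r1", "r4"))
  # idempotent
  expect_identical(quality_filter(kept, 13), kept)
  expect_error(quality_filter(data.frame(id = "x", seq = "ACGT",
                                         qual = "II")),
               "quality strings")
})

test_that("3' adapter trimming needs a 6-nt overlap and tolerates 1/10 mismatches", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTA"
  reads <- data.frame(id = c("full", "short_overlap", "one_mm"),
                      seq = c(paste0(insert, ad),
                              paste0(insert, substr(ad, 1, 5)),
                              paste0(insert, sub("^T", "A",
                                                 substr(ad, 1, 12)))),
                      stringsAsFactors = FALSE)
  out <- trim_adapters(reads, ad)
  expect_equal(out$seq[1], insert)               # full adapter removed
  expect_equal(out$seq[2], reads$seq[2])         # 5-nt overlap untouched
  expect_equal(out$seq[3], insert)               # 12-nt overlap, 1 mismatch
})

test_that("randomized insert+adapter reads are recovered near-perfectly", {
  set.seed(201)
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  inserts <- replicate(400, paste(sample(c("A", "C", "G", "T"),
                                         sample(18:25, 1), TRUE),
                                  collapse = ""))
  raw <- substr(paste0(inserts, ad, strrep("A", 40)), 1, 36)
  out <- trim_adapters(data.frame(id = seq_along(raw), seq = raw), ad)
  expect_gte(mean(out$seq == inserts), 0.99)
})

test_that("length filtering keeps the stated inclusive window", {
  reads <- data.frame(seq = c(strrep("A", 17), strrep("C", 18),
                              strrep("G", 25), strrep("T", 26)))
  out <- length_filter(reads, 18, 25)
  expect_equal(nchar(out$seq), c(18, 25))
  expect_equal(nrow(length_filter(reads[0, , drop = FALSE])), 0)
  expect_error(length_filter(reads, 26, 18), "min_len")
  # idempotent
  expect_identical(length_filter(out, 18, 25), out)
})

test_that("tag collapsing conserves counts and normalizes the alphabet", {
  tags <- collapse_tags(c("ACGU", "ACGU", "GGCC"))
  expect_equal(tags$count[tags$sequence == "ACGU"], 2)
  expect_equal(sum(tags$count), 3)
  expect_equal(collapse_tags("ACGT")$sequence, "ACGU")
  # collapse on the fixture conserves the cleaned read count
  prep <- default_tags()$prep
  expect_equal(sum(prep$tags$count),
               prep$stats$reads[prep$stats$step == "length"])
})

test_that("the length distribution sums to the library and matches truth", {
  st <- default_study()
  tags <- default_tags()$prep$tags
  ld <- length_distribution(tags)
  expect_equal(sum(ld$reads), sum(tags$count))
  expect_equal(sum(ld$unique_tags), nrow(tags))
  # 24 nt dominates the non-miRNA background by construction
  expect_equal(ld$length[which.max(ld$unique_tags)], 24)
})

test_that("the preprocessing chain is monotone in read counts", {
  st <- default_study()
  prep <- preprocess_reads(st$srna$reads, adapter_3p = st$config$adapter_3p)
  expect_true(all(diff(prep$stats$reads) <= 0))
})
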