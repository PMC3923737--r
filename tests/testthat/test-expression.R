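test_that("read counting honors the mismatch budget and multiplicity", {
  ref <- c(f1 = paste0(strrep("A", 20), "ACGTACGTACGTACGTACGTACGTAC",
                       strrep("T", 20)))
  hit <- "ACGTACGTACGTACGTACGTACGTAC"
  mm3 <- hit; substr(mm3, 1, 1) <- "T"; substr(mm3, 5, 5) <- "T"
  substr(mm3, 9, 9) <- "T"
  expect_equal(unname(count_reads(c(hit, hit), ref, 0)), 2)
  expect_equal(unname(count_reads(mm3, ref, 2)), 0)    # 3 mismatches
  expect_equal(unname(count_reads(mm3, ref, 3)), 1)
  # reverse-strand reads count too
  expect_equal(unname(count_reads(revcomp(hit), ref, 0)), 1)
})

test_that("TMM factors are exact on degenerate libraries", {
  set.seed(601)
  x <- rnbinom(50, mu = 200, size = 5) + 1L
  expect_equal(tmm_factor_vector(cbind(x, x)), c(1, 1))
  # doubling every count is pure depth: factors stay 1
  expect_equal(tmm_factor_vector(cbind(x, 2L * x)), c(1, 1))
})

test_that("TMM matches a straight-line oracle and edgeR on toy matrices", {
  set.seed(602)
  for (i in 1:5) {
    counts <- matrix(rnbinom(60, mu = exp(runif(60, log(20), log(500))),
                             size = 8), ncol = 3)
    counts[counts == 0] <- 1L
    f <- tmm_factor_vector(counts)
    expect_equal(f, oracle_tmm(counts), tolerance = 1e-10)
  }
  counts <- matrix(rnbinom(90, mu = 150, size = 6), ncol = 3)
  expect_equal(tmm_factor_vector(counts),
               unname(edgeR::calcNormFactors(counts, method = "TMM")),
               tolerance = 1e-8)
})

test_that("the A-C test matches brute-force summation and is exact at balance", {
  expect_equal(ac_test(5, 5, 1e4, 1e4), 1)
  expect_equal(ac_test(0, 0, 1e4, 2e4), 1)
  # spec toy: direct tail summation
  expect_equal(ac_test(3, 0, 1e4, 1e4), oracle_ac(3, 0, 1e4, 1e4),
               tolerance = 1e-12)
  set.seed(603)
  for (i in 1:50) {
    x <- rpois(1, sample(c(3, 20, 80), 1))
    y <- rpois(1, sample(c(3, 20, 80), 1))
    n1 <- sample(c(5e3, 1e4), 1); n2 <- sample(c(1e4, 3e4), 1)
    expect_lt(abs(ac_test(x, y, n1, n2) - oracle_ac(x, y, n1, n2)), 1e-12)
  }
  expect_error(ac_test(-1, 0, 1, 1), "non-negative")
})

test_that("the NB exact test reduces to the binomial split at zero dispersion", {
  expect_equal(nb_exact_test(7, 7), 1)
  set.seed(604)
  for (i in 1:50) {
    x <- rpois(1, 15); y <- rpois(1, 25)
    expect_lt(abs(nb_exact_test(x, y, phi = 0) - oracle_nb(x, y, 0)),
              1e-12)
    phi <- sample(c(0.1, 0.5), 1)
    expect_lt(abs(nb_exact_test(x, y, phi = phi) - oracle_nb(x, y, phi)),
              1e-12)
  }
  # p-values grow with dispersion for a fixed split
  p <- vapply(c(0, 0.1, 0.5), function(f) nb_exact_test(10, 30, phi = f),
              numeric(1))
  expect_true(all(diff(p) > 0))
  expect_error(nb_exact_test(1, 1, phi = -1), "dispersion")
})

test_that("both exact tests stay within [0, 1] across a stress grid", {
  set.seed(605)
  for (i in 1:40) {
    x <- sample(0:500, 1); y <- sample(0:500, 1)
    pa <- ac_test(x, y, 1e4, 1.7e4)
    pn <- nb_exact_test(x, y, 1e4, 1.7e4, phi = runif(1, 0, 0.4))
    expect_true(pa >= 0 && pa <= 1)
    expect_true(pn >= 0 && pn <= 1)
  }
})

test_that("dispersion estimation recovers degenerate and NB regimes", {
  cc <- matrix(rep(c(40L, 41L, 39L), each = 4), ncol = 3)
  cc_const <- matrix(rep(50L, 12), ncol = 3)
  expect_true(all(estimate_dispersion(cc_const,
                                      lib_sizes = rep(1, 3)) == 0))
  set.seed(606)
  pois <- matrix(rpois(1500, 100), ncol = 3)
  expect_lte(median(estimate_dispersion(pois)), 0.05)
})

test_that("the differential gate requires both tests at the threshold", {
  set.seed(607)
  base <- rpois(60, 120)
  counts <- cbind(L1 = c(100L, 100L, base), L2 = c(100L, 800L, base))
  cm <- count_matrix(list(L1 = counts[, 1], L2 = counts[, 2]))
  d <- call_differential(cm, alpha = 0.001)
  flagged <- d$feature[d$differentially_represented]
  expect_equal(flagged, "feature002")
  expect_true(all(d$p_nb >= 0 & d$p_nb <= 1))
  expect_true(all(d$p_ac >= 0 & d$p_ac <= 1))
  # a feature significant in only one of the two tests is never flagged
  expect_false(any(d$differentially_represented &
                     (d$p_nb > 0.001 | d$p_ac > 0.001)))
  # three libraries produce the three pairwise comparisons
  cm3 <- count_matrix(list(L1 = counts[, 1], L2 = counts[, 2],
                           L3 = counts[, 1]))
  d3 <- call_differential(cm3)
  expect_setequal(unique(d3$pair), c("L1/L2", "L1/L3", "L2/L3"))
})

test_that("stage-wise pipeline counts flag the planted fold changes", {
  st <- default_study()
  feats <- st$features[st$features$type == "precursor", ]
  refs <- setNames(substring(as.character(st$contigs[feats$contig]),
                             feats$start, feats$end), feats$id)
  cols <- lapply(st$mrna$stage_reads, function(r)
    count_reads(r$seq[r$feature %in% feats$id], refs, 0))
  cm <- count_matrix(cols)
  rownames(cm$counts) <- names(refs)
  d <- call_differential(cm)
  fc <- st$mrna$fold_changes[feats$id]
  changed <- names(fc)[vapply(fc, function(v) max(v) / min(v) >= 4,
                              logical(1))]
  flagged <- unique(d$feature[d$differentially_represented])
  # every planted >=4-fold feature is caught, and flat features are not
  expect_true(all(changed %in% flagged))
  flat <- setdiff(names(fc), changed)
  expect_lte(mean(flat %in% flagged), 0.05)
})
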