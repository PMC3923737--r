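# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixture_cache$study))
    .fixture_cache$study <- simulate_study(synth_config())
  .fixture_cache$study
}

# preprocess + ncRNA filtering of the default study
default_tags <- function() {
  if (is.null(.fixture_cache$tags)) {
    st <- default_study()
    prep <- preprocess_reads(st$srna$reads,
                             adapter_3p = st$config$adapter_3p)
    cls <- classify_tags(prep$tags, st$ncrna_refs)
    .fixture_cache$tags <- list(prep = prep, classified = cls,
                                retained = remove_classified(cls)$retained)
  }
  .fixture_cache$tags
}

default_discovery <- function() {
  if (is.null(.fixture_cache$disc)) {
    st <- default_study()
    .fixture_cache$disc <- discover_precursors(
      default_tags()$retained, st$contigs,
      mature_reference = data.frame(id = st$mature_reference$id,
                                    sequence = st$mature_reference$sequence))
  }
  .fixture_cache$disc
}

# truth-based recovery assessment of accepted calls
discovery_scores <- function(study, accepted) {
  tr <- study$precursors
  tr$mas <- tr$offset + tr$mat_start - 1
  tr$mae <- tr$offset + tr$mat_end - 1
  acc_contig <- vapply(accepted, function(cl) cl$contig, character(1))
  covered <- vapply(seq_len(nrow(tr)), function(i) {
    any(acc_contig == tr$contig[i] &
          vapply(accepted, function(cl)
            cl$start <= tr$mas[i] && cl$end >= tr$mae[i], logical(1)))
  }, logical(1))
  canon_ok <- vapply(accepted, function(cl) {
    i <- match(cl$contig, tr$contig)
    if (is.na(i)) return(NA)
    cl$canonical$sequence == tr$mature_seq[i]
  }, logical(1))
  list(recall = mean(covered),
       precision = mean(acc_contig %in% tr$contig),
       canonical_accuracy = mean(canon_ok, na.rm = TRUE))
}
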