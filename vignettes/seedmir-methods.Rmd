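---
title: "Methods: seed small-RNA analysis with seedmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed small-RNA analysis with seedmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

seedmir re-implements, as one tested pipeline, the computational analysis
of a plant-seed small-RNA sequencing experiment: a single deep-sequenced
sRNA library from mature seeds plus three stage-wise mRNA libraries
(immature, intermediate, mature; `L1`--`L3`). The stages are

1. read cleaning (quality, N content, adapter trimming, 18--25 nt window)
   and collapsing to unique tags;
2. removal of non-coding and organellar RNA classes by exact containment
   in class references;
3. conserved miRNA identification by perfect full-length identity against
   a mature miRNA reference;
4. pre-miRNA discovery from the anchoring geometry of tags on assembled
   contigs plus hairpin screening (MFE, MFEI, single-hairpin, arm rule);
5. isomiR profiling (the most frequent anchored tag is the canonical
   miRNA; all others are isomiRs);
6. stage-wise precursor/target abundance with TMM normalization and a
   dual-test differential gate (conditional NB exact test *and*
   Audic--Claverie test, both at p &le; 0.001);
7. expectation-scored miRNA target prediction;
8. detection of 24-nt siRNA-producing loci from dispersed read patterns.

Every stage is validated against a synthetic study generator
(`simulate_study()`) that emits the inputs with known ground truth.

# The discovery model

## Read anchoring and block geometry

Cleaned, filtered tags are matched against contigs with zero mismatches on
both strands (`anchor_tags()`). Dicer processing of a genuine pre-miRNA
leaves reads piled at one or two precise 5' positions, so anchors are
clustered by their 5' start within &delta; = 3 nt (`detect_blocks()`,
single linkage). A contig strand shows a credible precursor pattern when
its top one or two blocks jointly hold at least 90% of the anchored
reads. Because degradation fragments are overwhelmingly singleton tags,
the containment fraction is computed over tags seen at least twice
(`min_tag_count = 2`); without this, a handful of stray single-read
anchors on a host contig can veto a genuine low-count precursor.

## Window excision and refinement

The published description of precursor excision leaves the boundary rule
unspecified, so seedmir defines one. For a two-block pattern the
candidate window is the joint block span plus a 20-nt flank; the partner
block must carry at least `max(2, 5%)` of the top block's reads so that a
stray tag cannot masquerade as the star arm. For a one-block pattern the
mature arm is unknown, so both windows are excised (the block extended
150 nt leftward and rightward in turn); both one-block windows are always
evaluated, and overlapping accepted calls are deduplicated afterwards
(more anchored reads, then lower MFE, wins).

A raw window carries random flanking sequence that can fold into spurious
secondary hairpins, so every window is refined: the window is folded, the
top-level helix domain (`db_domains()`) hosting the top-count block is
excised with a 5-nt pad, and the refined span is re-folded. All
acceptance criteria are evaluated on the refined span, which is also the
reported precursor interval.

## Hairpin screening criteria

A refined candidate is accepted iff

* it folds into a single hairpin -- exactly one terminal loop;
* |MFE| lies within 40--100 kcal/mol (`"strict"` preset; the `"loose"`
  preset uses 17--110);
* |MFEI| > 0.85 (`"loose"`: 0.5), where AMFE = MFE/length &times; 100 and
  MFEI = AMFE / GC%;
* at least 10 anchored reads support it (a boundary stated ambiguously in
  the source material as both "at least 10" and "more than 10"; seedmir
  uses &ge; 10);
* the top block lies within one arm, overlapping the terminal loop by at
  most 4 nt. The arm label (5p/3p) comes from the block midpoint relative
  to the loop midpoint.

The canonical miRNA of an accepted precursor is its most frequent
anchored tag, ties broken by the lexicographically smallest sequence
(deterministic and order-independent); every other anchored tag is an
isomiR. A call is "known" when the canonical tag perfectly matches the
mature reference, otherwise "novel".

## The folding engine

MFE thermodynamics engines are not bit-reproducible across versions, and
the screening criteria only require energy *ranges* and the loop
topology. seedmir therefore ships a deterministic dynamic-programming
folder (`builtin_fold_engine()`, implemented in C++) over a simplified
nearest-neighbour model: per-pair energies G:C &minus;1.92, A:U
&minus;0.81, G:U &minus;0.49 kcal/mol; hairpin-loop penalty 4.0 + 0.3
kcal/mol per unpaired nt beyond 3; bulge penalty 1.0 and internal-loop
penalty 0.8 kcal/mol per unpaired nt with a joint loop cap of 10 nt;
branching restricted to the exterior loop (a multibranch structure is
representable only as separate exterior domains, which is exactly what
the single-hairpin screen needs to see). The constants were calibrated
once so that near-perfect plant-like hairpins (GC fraction
0.39--0.47, ~10% arm mismatches) fold at AMFE &asymp; &minus;40 to
&minus;48 kcal/mol per 100 nt and |MFEI| &asymp; 0.95--1.1, the range the
screening thresholds presuppose. On toy sequences (&le; 20 nt) the engine
provably returns the optimum of its own energy model (the test suite
enumerates all grammar-compatible structures). An external thermodynamic
engine can be plugged in (`viennarna_fold_engine()` wraps `RNAfold`);
absolute-energy agreement with any specific thermodynamics package is
explicitly not promised.

# Differential representation

Counting is exact-containment alignment with no indels: zero mismatches
for precursor counting, a 2-substitution budget for target transcripts
(the published positional clause "one in the seed and another in the
rest" is not operationalized; a plain budget is used).

Library scaling uses the trimmed mean of M-values exactly as published:
reference column by the upper-quartile rule, M/A over doubly-nonzero
features, 30%/5% two-sided trims on M/A, inverse-asymptotic-variance
weights, factors rescaled to geometric mean 1. The implementation is
checked against an independent straight-line transcription of the
formulas (1e-10) and against edgeR's `calcNormFactors` on toy matrices.

Two exact tests gate each library pair:

* `ac_test(x, y, n1, n2)` -- the Audic--Claverie posterior
  p(y|x) = (n2/n1)^y (x+y)! / (x! y! (1+n2/n1)^(x+y+1)), computed in log
  space; the two-sided p-value sums all outcomes no more probable than
  the observed one. This construction conditions on the first count and
  is *not* symmetric under swapping the libraries; pairs are always
  ordered (L1,L2), (L1,L3), (L2,L3) so results are deterministic.
* `nb_exact_test(x, y, phi)` -- after equalizing effective sizes
  (counts scaled to the geometric-mean size, rounded half to even), the
  split of s = x + y is conditionally beta-binomial under per-group
  NB(phi); phi = 0 reduces exactly to the binomial split test. Two-sided
  by the same minimum-likelihood construction.

A feature is differentially represented in a pair iff **both** tests are
at or below &alpha; = 0.001. No multiple-testing correction is applied
(the gate is a fixed dual-&alpha; design); BH q-values are reported for
information only.

**Dispersion.** `estimate_dispersion()` reports per-feature tagwise
values: the method-of-moments estimate max(0, (s&sup2; &minus; m)/m&sup2;)
on size-normalized counts, shrunk toward the across-feature median with a
10-pseudo-feature prior. With one library per stage, however, a feature's
own between-stage change is indistinguishable from overdispersion: a
truly 8-fold-changed feature inflates its own tagwise estimate so much
that the NB test can never reach &alpha; (the gate's power collapses to
zero). The differential gate therefore tests at the robust *common*
dispersion -- the across-feature median of the raw moment estimates,
dominated by the unchanged majority (`common_dispersion()`); this mirrors
standard practice for unreplicated count designs. Tagwise values remain
available and reported.

# Target prediction

`scan_targets()` slides the mature miRNA (18--25 nt) along every
transcript window on both strands and scores reverse-complement
pairing: Watson--Crick 0, G:U wobble 0.5, mismatch 1, single-nt bulge 2
(at most one per site), all doubled at miRNA positions 2--13 counted from
the 5' end. Hits at or below the expectation cutoff are reported (4.0
for canonical miRNAs, 5.0 conventionally for isomiRs), overlapping hits
deduplicated to the best window. The inhibition hint is "cleavage" unless
positions 9--11 contain a true mismatch. The penalty constants follow the
psRNAtarget-style scheme and are configurable; hit-for-hit agreement with
any web service version is not promised, and no target-site accessibility
(UPE) term is computed.

# siRNA loci

24-nt tags whose anchors are dispersed rather than blocked mark
heterochromatic siRNA production. The published "typical distribution
pattern" is not quantified, so seedmir operationalizes it: a contig is a
locus iff it has &ge; 10 distinct 5' starts spanning &ge; 100 nt with no
&delta;=3 block holding > 50% of reads; contigs carrying an accepted
precursor are suppressed. Strand balance is not required. All three
parameters are exposed.

# The synthetic study generator

`synth_config()` fixes the study conditions; `simulate_study()` derives
everything from one seed:

* **Precursors** -- `n_precursors = 40` hairpins, lengths
  truncated-normal (mean 150, sd 25) within 70--250 nt, matching reported
  plant pre-miRNA length averages (~150--160 nt); GC fraction uniform in
  0.39--0.47 (reported seed pre-miRNA CG contents are ~41--44%); a
  random 5p arm, 8-nt-minimum terminal loop, and a 3p arm that is the
  reverse complement with a deterministic round(10% &times; arm) mutated
  positions (a fixed count keeps stem quality controlled; the positions
  and replacement bases remain random and composition-weighted). The
  mature duplex sits 12 nt above the stem base; half the precursors embed
  a mature sequence drawn from the synthetic miRBase-style reference
  ("known"), the rest are novel.
* **Reads** -- per precursor 15--300 reads; 70% of precursors also emit
  star-arm reads at 20%. IsomiR ends are independent rounded Gaussians
  (sd 0.5 nt) truncated to the precursor; this yields a dominant
  canonical tag with decaying end variants, as in real isomiR profiles.
  Contaminants: rRNA 6.94%, tRNA 0.60%, snRNA/snoRNA 0.05% each, cpRNA
  1.90%, mtRNA 0.25% (a typical seed-library filtering profile),
  degradation fragments 10%, siRNA-locus reads 5%; non-precursor read
  lengths follow a 24-nt-dominated distribution with secondary 21/22-nt
  modes. A fixed 3' adapter is appended and reads truncated to 36 nt;
  2% of reads are emitted at Phred 8 and 0.5% with an injected N to
  exercise the cleaning stage.
* **mRNA stages** -- three libraries; per feature and stage the read
  count is Poisson(base &times; fold &times; depth) with base means
  log-uniform in 30--300; 20% of features get a 4--8-fold stage pattern.
  Reads are sampled inside the feature span so exact-containment counting
  recovers the truth.

What the generator does **not** emulate: per-cycle sequencing error
profiles, adapter chemistry beyond a fixed 3' read-through, genomic
repeats and paralogous precursor families, RNA secondary-structure bias
in library preparation, and real thermodynamic folding landscapes.
Passing tests therefore demonstrate the pipeline's logic and statistics
under controlled conditions, not performance on real libraries.

# Numerical and degenerate-input choices

* Quality "below 13" is read as mean Phred < 13 over the read (per-base
  mode available); the boundary Q = 13 is retained.
* Adapter trimming needs &ge; 6 nt overlap with &le; 1 mismatch per
  10 nt; these are common sRNA practice, not published values.
* Table percentages are rounded half-up (not R's half-even) because
  that is how the published tables round; `percent(0, n) = 0`,
  `percent(x, 0)` is an error.
* Multi-class ncRNA hits resolve by the filtering-table column order
  (rRNA > tRNA > snRNA > snoRNA > cpRNA > mtRNA); classification is
  order-independent and exact containment on either strand.
* Canonical ties break lexicographically; window dedup prefers more
  anchored reads, then lower MFE.
* Folding failures reject a candidate with reason `fold_error` rather
  than aborting the run; all rejection reasons are recorded per call.
* All randomness flows from a single configuration seed; identical seeds
  give byte-identical FASTQ and TSV outputs.

# Problem sizes used in validation

The default fixture uses 40 precursors (~7,000 sRNA reads), 25 target
transcripts, 15 decoy contigs and 5 siRNA loci; the goodness-of-fit and
type-I/power simulations use 200--1,000 features and 200 replicates.
These sizes give the statistical checks (binomial CIs, chi-square,
recovery rates) enough resolution while keeping the full suite quick to
run.

# Known limitations

* The built-in folder's energies are on their own calibrated scale;
  MFE/MFEI thresholds transfer to an external engine only after
  re-checking typical values on that engine.
* With one library per stage the dual-test gate has no replication;
  p-values quantify sampling noise under the common dispersion, not
  biological variability.
* The miRNA* duplex 2-nt-overhang check, degradome validation, GO
  annotation and phasing statistics for siRNA loci are out of scope.
* The A--C two-sided construction conditions on the first library of
  each ordered pair; swapping the pair can change the p-value slightly
  (an inherent property of the posterior construction).
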