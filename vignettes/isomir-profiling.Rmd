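---
title: "Profiling isomiRs, 3' tailing and arm usage from small RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling isomiRs, 3' tailing and arm usage from small RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRflow)
```

## The analysis model

A mature microRNA is excised from one arm of a ~70–90 nt pre-miRNA
hairpin. In deep sequencing data the products of one locus appear as a
family of isomiRs: sequence variants whose 5' and 3' ends are shifted by a
few nucleotides relative to the miRBase reference, often carrying extra 3'
nucleotides that are not encoded in the hairpin (nontemplate additions,
mostly A or U). isomiRflow quantifies, per library and between two
libraries:

* the position-shift spectra at both read ends,
* the rate and composition of 3' nontemplate additions,
* per-miRNA expression (TPM), fold changes and tissue preference,
* 5p/3p arm-usage ratios per hairpin and their change between libraries,
* the composition of the non-miRNA read classes,
* hypergeometric pathway enrichment of target-gene sets.

All coordinates are 1-based and inclusive on the hairpin sense strand, and
the internal alphabet is RNA (DNA input is converted on read-in).

### Mapping with iterative 3' trimming

Because many miRNA genes occur as near-identical paralog families, any
mismatch allowance creates ambiguous hits; the mapper therefore allows *no
mismatches*. A genuine 3' tail would then prevent any alignment, so
terminal 3' bases are conceptually trimmed one at a time until the
remaining read matches a hairpin perfectly, subject to a floor of 18
matched nucleotides. Reads whose longest perfect prefix is 17 nt or
shorter stay unmapped. The 5' end is never trimmed.

The implementation does not literally loop: the largest `L ≥ 18` such that
`read[1..L]` occurs in a hairpin equals the result of the trim-one-retry
procedure, so the mapper searches the longest perfect prefix directly via
an 18-mer hash index and extension. The literal loop survives as the
brute-force oracle in the test suite, which checks equality on thousands
of random instances, including maximality of the recovered tail (the first
tail base must mismatch the next templated base unless the alignment abuts
the hairpin 3' terminus).

Two policies matter downstream:

* **Multi-mapping.** All occurrences of the longest prefix are reported
  and share the read with equal weights `1/n`. After mature-name
  assignment, alignments of one read that share a mature name (identical
  paralog products) are merged, so a read is counted once per name.
* **Overhangs.** Bases extending past the hairpin 3' terminus cannot match
  template and therefore land in the modification suffix.

### IsomiR classification

An alignment is assigned to the mature annotation on its hairpin with the
largest overlap, provided both shifts are within the assignment window
(default |shift| ≤ 5; distributions over arbitrary shifts are not well
defined once an alignment is closer to the loop than to any mature end).
`shift5 = read start − annotated start` and `shift3 = matched end −
annotated end`, positive meaning downstream; the nontemplate suffix is
*not* part of `shift3`. Suffixes are categorized as A, U, AA, UU, AU, C,
G (the categories that dominate observed tailing), `other` for any other
non-empty suffix, `none` for untailed reads.

Alignments that overlap no annotation are handled by an arm-inference
rule: the read midpoint in the 5' half of the hairpin means 5p, else 3p
(the loop is not modeled — annotations never define it). If the inferred
arm carries no annotation, the read is an **opposite-arm** product and is
booked under a provisional locus `<hairpin>-<arm>-novel` whose coordinates
are the count-weighted modal alignment; a miRNA (annotated or provisional)
counts as *detected* with ≥ 1 assigned clean read (the count ≥ 2 filter is
already enforced upstream). If the inferred arm *is* annotated but the
alignment falls outside the shift window, the record is returned as
`unassigned` rather than silently binned.

### Quantification conventions

* **TPM denominator** — the library's total clean-read count (not the
  miRNA-mapped subtotal), keeping miRNA and contaminant classes on one
  scale; configurable (`tpm_denominator = "mirna"`).
* **Fold change** — plain ratio `TPM_b / TPM_a` with pseudocount 0 by
  default; a 0/0 pair is reported `NA` (undefined) rather than fabricated,
  because a pseudocount silently distorts ratios. Ranking of
  "differentially expressed" miRNAs is by |log fc| (the operational
  reading of "highest fold changes"; no threshold is imposed).
* **Concordance** with an external assay is the Pearson correlation of
  *log* fold changes — fold changes are ratio-scaled, and on the bundled
  breast validation table the log scale reproduces the published r = 0.89
  while the raw scale does not (0.78). Direction consistency compares the
  signs of the log fold changes.
* **Arm usage** — `ratio = 5p count / 3p count` per library and
  `log2(ratio_b / ratio_a)` across libraries, computed only for hairpins
  with both arms observed; zero-denominator cases are flagged, not
  imputed. The bundled arm-count table reproduces the miR-324 switch:
  0.68 in normal, 3.48 in tumor, log2 change +2.35.

### Preprocessing parameters

| parameter | default | rationale |
|---|---|---|
| adapter probe (`min_overlap`) | 6 nt | leftmost exact match of the adapter's first 6 bases; exact matching keeps trimming reproducible |
| untrimmed reads | discarded | an untrimmed read carries adapter bases into the tail detector and would inflate tailing estimates |
| count floor (`min_count`) | 2 | the confidence filter used for deep small-RNA libraries |
| length window | 18–30 nt | 18 matches the mapper's perfect-match floor; 30 is a conventional small-RNA ceiling |
| N-containing reads | discarded | a no-mismatch mapper cannot place them |

### Cascade order and matching

Reads unmapped to hairpins are classified by first-match-wins against the
reference classes in the order mRNA, tRNA, rRNA, snoRNA, scaRNA, snRNA,
other ncRNA, repeat, then unknown. Matching allows at most one
substitution (no indels — the operational reading of "a single nucleotide
variation"), implemented with `Biostrings::vcountPattern` and checked in
the tests against an independent single-substitution-neighborhood
enumeration. The class order is configurable and conservation under
reordering is tested. Repeat identification is a user-supplied FASTA
rather than a masking service, and splitting `unknown` by genome
alignment is out of scope.

### Enrichment

`P(X ≥ k)` under Hypergeometric(N, K, n) via the survival function, with
BH adjustment over all tested pathways. The universe defaults to all
genes appearing in ≥ 1 pathway of the supplied GMT (optionally intersected
with a user universe) — the standard reproducible choice when the original
tool's universe is not recoverable. Target-gene unions are formed from
user-supplied per-miRNA gene lists; target prediction itself is external.

## The synthetic-data generator

`generate_paired_study()` emulates the statistical structure of a deep
breast normal/tumor small-RNA comparison:

* 5' shift law: 95% at 0, 1% at −1, 4% at +1; 3' shift law: 5/20/56/15/1%
  at −2…+2, with the residual 3% split over −3/+3 (the published spectra
  report only −2…+2);
* tailing probability 17.65% (normal) and 12.45% (tumor); tail
  composition with A + U at 80% of events and AA, UU, AU, C, G ≥ 1%;
* ten-class read proportions per library matching the published
  composition (miRNA 75.24%/84.79%, etc.);
* configurable fold-change multipliers for designated miRNAs (defaults
  9.88, 0.15, 2.90, 0.49, 9.04 — effect sizes spanning the published
  validation range) and one arm-switch hairpin with 5p:3p count
  proportions 233:341 (normal) vs 317:91 (tumor);
* a fraction of hairpins annotated 5p-only while expressing both arms, to
  exercise opposite-arm detection; an optional paralog-family switch that
  clones a hairpin to exercise multi-map weighting.

Mechanics that make truth-based recovery exact:

* Hairpins and contaminant references are rejection-sampled so no 18-mer
  repeats within the reference side and nothing contains the adapter
  probe's 5-mer prefix; mapping is therefore unambiguous and every read
  trims back exactly to its insert (tailed reads are verified and the
  tail redrawn in the rare junction case where insert+tail recreates the
  probe across the adapter boundary).
* The first tail base is drawn to differ from the next templated base, so
  the mapper provably sees the whole tail; a tail base matching template
  would otherwise be absorbed into the match — correct mapper behavior,
  but it would corrupt truth joins.
* Designated-effect hairpins receive fixed abundance shares
  (down-regulated 0.18, strongly up-regulated 0.02, moderately
  up-regulated 0.05, arm-switch 0.08 of miRNA mass, with the effect arm
  at share 0.7); the background receives log-normal shares of the rest.
  This mirrors the practice of validating abundant, strongly changed
  miRNAs, and gives fold-change estimates adequate counting statistics at
  the simulated depth. A side effect is that the expected tumor miRNA
  share lands near 85%, close to the published tumor composition.
* The tumor library's mature weights are the normal weights times the
  multipliers, *unnormalized*: the excess mass is absorbed into the tumor
  miRNA class share and the contaminant classes rescaled. Consequently
  the expected whole-library TPM fold change of a designated miRNA equals
  its configured multiplier exactly.
* Everything is driven by one integer seed; identical configurations
  produce byte-identical files.
* Contaminant and unknown reads are drawn from finite pools (tens to
  hundreds of distinct windows per class), giving them the high
  per-sequence multiplicities real contaminants have.

**What the generator does not emulate:** sequencing error, quality-score
structure, ligation bias, true hairpin secondary structure, genuine
paralog sequence divergence, internal editing, and the heavy-tailed
isoform diversity of real loci. Passing recovery tests therefore
demonstrates that the pipeline measures what the generative model encodes
at realistic depth — not that every property of real tissue libraries is
captured.

## Numerical and degenerate-input choices

* Shift distributions error on empty input rather than returning NaN;
  fractions are validated to sum to 1 within 1e-9.
* Assignment ties (equal overlap with both arms) break toward the 5p arm;
  modal-coordinate ties break toward the smaller coordinate — both
  deterministic.
* The reference isoform is flagged "most abundant" also when tied with
  the top cell.
* Multi-map weights are exact reciprocals; weighted counts may be
  fractional and every summary is weight-aware.
* Fold changes are kept at full precision and rounded to two decimals
  only in display.

## Problem sizes

The recovery suite and the acceptance script simulate 100,000 reads per
library over 20 hairpins (40 mature arms) — deep enough that binomial
sampling error sits well inside the documented recovery tolerances
(±0.02 per 3'-shift value, ±0.01 on the 5'-shift-0 mass, tailing fraction
and per-class proportions, ±10% on fold-change multipliers, ±15% on arm
ratios), while a full paired run completes in seconds. Unit tests use
6-hairpin studies of a few thousand reads.

One small systematic is worth knowing: the count ≥ 2 filter removes
singleton tags, and tailed reads — spread over a larger space of distinct
sequences — lose slightly more mass than untailed ones. At the simulated
depth the measured tailing fraction sits a few tenths of a percentage
point below the generative rate (the pipeline agrees exactly with the
post-filter truth). At the multi-million-read depth of real libraries the
effect is negligible.

## Known limitations

* No internal (non-terminal) editing or A-to-I calling; a tail containing
  an internal-edit artifact is simply categorized `other`.
* No genome alignment: the `unknown` class is terminal.
* The no-mismatch policy means a true isomiR carrying a sequencing error
  in its first 18 nt is lost to the cascade, which real error rates make
  noticeable at high depth; the generator does not model this.
* Enrichment p-values depend entirely on the supplied GMT and target
  lists; published pathway p-values based on proprietary snapshots are
  not reproducible from the package.
* Arm-switch "inconsistency" has no canonical threshold; the package
  reports `log2_ratio_change` and leaves thresholding to the analyst.
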