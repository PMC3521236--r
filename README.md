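# isomiRflow

Small RNA sequencing libraries do not contain one clean sequence per
microRNA. Reads from a single miRNA locus come as a cloud of **isomiRs** —
variants of the miRBase reference mature sequence that differ by small 5'
and 3' end position shifts and by **3' nontemplate nucleotide additions**
("tailing", mostly adenine or uridine). On top of that, either arm of a
pre-miRNA hairpin (5p or 3p) can dominate mature miRNA accumulation, and
that **arm-selection preference can switch between conditions** such as
normal and tumor tissue. isomiRflow is an R package for analysts who want
to quantify all of this from raw small-RNA reads, for two libraries at a
time (e.g. a normal/tumor pair).

## What it computes

**Mapping.** After 3' adapter trimming, collapsing to unique tags, and a
confidence filter (read count ≥ 2, 18–30 nt), each clean read is aligned to
pre-miRNA hairpins with *no mismatches allowed*. Because a genuine 3' tail
would otherwise force a terminal mismatch, terminal 3' bases are trimmed
one by one until a perfect match of ≥ 18 nt remains; the removed suffix is
the candidate nontemplate addition. The implementation finds the longest
perfectly matching read prefix directly (provably identical to the literal
trim-and-retry loop, which is retained as the test oracle). Identical
paralog hits share a read with equal fractional weights, and a read that
resolves to one mature name through several paralogous hairpins is counted
once.

**IsomiR classification.** Every alignment gets a position-shift pair
relative to the annotated mature span — `shift5 = start − annotated start`,
`shift3 = matched end − annotated end` (positive = downstream; the tail is
*not* a shift) — plus a 3'-modification category from
{A, U, AA, UU, AU, C, G, other, none}. Alignments on an arm with no
annotation become *opposite-arm* products under a provisional locus.

**Quantification.** Per-miRNA counts are isomiR sums, normalized to
transcripts per million, `TPM = count / library total × 10⁶`. Between two
libraries the package reports fold changes `fc = TPM_b / TPM_a`, tissue
preference counts, Pearson correlation of log fold changes against an
external assay (e.g. stem-loop qPCR), and per-hairpin 5p/3p arm-usage
ratios with their `log2` change.

**Read-class cascade.** Reads that fail hairpin mapping are classified
into mRNA, tRNA, rRNA, snoRNA, scaRNA, snRNA, other ncRNA, repeat or
unknown by ordered matching against reference sets, allowing one
substitution.

**Enrichment.** Target-gene sets are tested for pathway over-representation
with the upper-tail hypergeometric test, `P(X ≥ k)` for
`X ~ Hypergeom(N, K, n)`, with Benjamini–Hochberg FDR correction.

**Synthetic studies.** A generator produces paired normal/tumor libraries
with a per-read truth table — known shift laws, tailing rates and
composition, class proportions, fold-change multipliers, and arm-switch
hairpins — so the whole pipeline is testable end to end without any
external download.

## Worked example

```r
library(isomiRflow)

cfg   <- synth_config(seed = 42, n_reads = 50000)
study <- generate_paired_study(cfg)

result <- run_small_rna_study(
  reads_by_library = lapply(study$libraries, `[[`, "reads"),
  hairpins       = study$refs$hairpins,
  annotations    = study$refs$annotations,
  reference_sets = study$refs$reference_sets,
  adapter        = cfg$adapter)
print(result)
#> smallrna_study: 2 library(ies)
#>
#>                                          normal    tumor
#> # clean reads                          49359.00 49459.00
#> % miRNA reads                             75.11    84.77
#> # detected pre-miRNAs                     20.00    20.00
#> # detected miRNAs                         40.00    40.00
#> # detected miRNAs at opposite arm          4.00     4.00
#> % miRNA reads with 3' end modification    16.57    11.59
#>
#> fold-change table: 40 miRNAs; arm-usage table: 20 hairpins
```

Roughly 75% of normal and 85% of tumor clean reads map to hairpins; four
provisional miRNAs are detected on unannotated arms; about 16.6% / 11.6% of
miRNA reads carry a 3' tail. The most-changed miRNAs recover the
fold-change multipliers the generator was configured with (9.88, 9.04,
0.15, 2.90, ... — `head(result$comparison$fold_changes)`):

```r
head(result$comparison$fold_changes, 4)
#>      mature_name tpm_a  tpm_b     fc preference
#>    syn-miR-03-5p  9684 104855 10.827          b
#>    syn-miR-13-5p  9948  95716  9.622          b
#>    syn-miR-05-3p 98179  14254  0.145          a
#>    syn-miR-08-5p 27330  74951  2.742          b
```

The package also ships the printed validation tables of a published breast
normal/tumor deep-sequencing comparison; recomputing fold changes from the
TPM columns and correlating with the qPCR assay:

```r
tab <- breast_fold_change_table()
cc  <- concordance(fold_change(tab$tpm_normal, tab$tpm_tumor), tab$pcr_fc)
#> r = 0.89, direction-consistent = 22/23
```

The correlation is computed on *log* fold changes (ratio-scaled data); the
sole direction flip is hsa-miR-423-3p.

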