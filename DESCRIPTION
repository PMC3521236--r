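Package: isomiRflow
Title: IsomiR Profiling, Arm Usage and Read-Class Analysis for Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small RNA sequencing libraries centred on
    microRNA sequence isoforms (isomiRs). Reads are adapter-trimmed, collapsed
    and filtered, then aligned to pre-miRNA hairpins by exact matching with
    iterative 3' end trimming, so that nontemplate 3' additions (tailing) are
    recovered alongside a mismatch-free alignment of at least 18 nt. IsomiRs
    are classified by 5'/3' position shift, 3' modification category, arm and
    opposite-arm status; libraries are quantified as transcripts per million
    with fold changes, preference counts, NGS-vs-PCR concordance and 5p/3p
    arm-usage ratios. Reads not derived from miRNAs are classified into nine
    further classes by ordered matching against reference sets allowing one
    substitution, and hypergeometric pathway enrichment with
    Benjamini-Hochberg correction is provided for target-gene sets. A
    synthetic-data generator with a per-read truth table emulates paired
    normal/tumor small RNA libraries for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    fgsea,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
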