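# Bundled validation tables from a published deep-sequencing comparison of
# normal breast and breast tumor small-RNA libraries: per-miRNA TPM values
# with NGS and stem-loop qPCR fold changes for the 23 most-changed miRNAs,
# and per-hairpin 5p/3p arm counts for 17 pre-miRNAs. Values are used
# exactly as printed (including the "has-let-7b" spelling of the source
# table).

#' Bundled breast normal/tumor miRNA fold-change validation table
#'
#' Columns: `mirna`, `tpm_normal`, `tpm_tumor`, `ngs_fc` (printed
#' tumor/normal TPM fold change), `pcr_fc` (stem-loop qPCR fold change),
#' `consistent` (same tissue preference by both assays, Y/N).
#'
#' @return data.frame of 23 miRNAs.
#' @export
breast_fold_change_table <- function() {
  read.delim(system.file("extdata", "breast_mirna_fold_changes.tsv",
                         package = "isomiRflow"), stringsAsFactors = FALSE)
}

#' Bundled breast normal/tumor 5p/3p arm-count table
#'
#' Per-hairpin mature read counts on each arm in the normal (`n5p`, `n3p`)
#' and tumor (`t5p`, `t3p`) libraries, for 17 pre-miRNAs with inconsistent
#' arm-selection preference.
#'
#' @return data.frame of 17 pre-miRNAs.
#' @export
breast_arm_count_table <- function() {
  read.delim(system.file("extdata", "breast_arm_counts.tsv",
                         package = "isomiRflow"), stringsAsFactors = FALSE)
}
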