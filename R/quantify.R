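# Library-level quantification: TPM, fold changes, preference counts,
# NGS-vs-PCR concordance, 5p/3p arm-usage ratios, and the per-library
# summary statistics.

#' TPM-normalize per-miRNA counts
#'
#' Transcripts per million: `count / library_total * 1e6`. The default
#' denominator convention in this package is the total clean-read count of
#' the library (not the miRNA-mapped subtotal), which keeps miRNA and
#' contaminant classes on one scale.
#'
#' @param counts data.frame with `mature_name` and `count` (e.g. from
#'   [aggregate_mirna()]).
#' @param library_total positive total used as the denominator.
#' @return `counts` with an added `tpm` column.
#' @export
tpm_normalize <- function(counts, library_total) {
  if (length(library_total) != 1L || !is.finite(library_total) ||
      library_total <= 0) {
    stop("library_total must be a single positive number")
  }
  counts$tpm <- counts$count / library_total * 1e6
  counts
}

#' Fold change between two TPM values
#'
#' `fc = (tpm_b + pseudo) / (tpm_a + pseudo)`. With the default
#' `pseudo = 0` a 0/0 pair is undefined and returned as `NA` rather than
#' fabricated. Vectorized.
#'
#' @param tpm_a,tpm_b non-negative expression values (a = reference, e.g.
#'   normal; b = comparison, e.g. tumor).
#' @param pseudo optional pseudocount for zero-inflated data.
#' @return numeric vector of fold changes (`NA` where undefined).
#' @export
fold_change <- function(tpm_a, tpm_b, pseudo = 0) {
  if (any(tpm_a < 0, na.rm = TRUE) || any(tpm_b < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative")
  }
  num <- tpm_b + pseudo
  den <- tpm_a + pseudo
  ifelse(den == 0 & num == 0, NA_real_,
         ifelse(den == 0, Inf, num / den))
}

#' Partition fold changes by tissue preference
#'
#' @param fc numeric vector of fold changes (b/a scale; < 1 means
#'   preferentially expressed in the reference library).
#' @return named integer vector: `n_a_preferring` (fc < 1),
#'   `n_b_preferring` (fc > 1), `n_ties` (fc == 1).
#' @export
preference_counts <- function(fc) {
  fc <- fc[!is.na(fc)]
  c(n_a_preferring = sum(fc < 1), n_b_preferring = sum(fc > 1),
    n_ties = sum(fc == 1))
}

#' Concordance of two fold-change measurements
#'
#' Pearson correlation of the log fold changes (base-invariant, since fold
#' changes are ratio-scaled) and the number of direction-consistent pairs
#' (same sign of log fc, i.e. the same tissue preference).
#'
#' @param fc_a,fc_b positive fold-change vectors of equal length (>= 3 pairs).
#' @return list with `r` and `n_direction_consistent`.
#' @export
concordance <- function(fc_a, fc_b) {
  if (length(fc_a) != length(fc_b)) stop("fold-change vectors differ in length")
  if (any(fc_a <= 0) || any(fc_b <= 0)) stop("fold changes must be positive")
  if (length(fc_a) < 3L) stop("need at least 3 pairs for a correlation")
  la <- log(fc_a)
  lb <- log(fc_b)
  list(r = cor(la, lb), n_direction_consistent = sum(sign(la) == sign(lb)))
}

#' 5p/3p arm-usage ratios for two libraries
#'
#' For hairpins with mature products on both arms: per-library 5p/3p count
#' ratios and the log2 change of the ratio between libraries. Ratios with a
#' zero denominator are `NA` and flagged, never fabricated. Vectorized over
#' hairpins.
#'
#' @param hairpin_id identifiers.
#' @param n5p,n3p arm counts in the first (e.g. normal) library.
#' @param t5p,t3p arm counts in the second (e.g. tumor) library.
#' @return data.frame with per-library ratios, `log2_ratio_change`, and a
#'   `defined` flag.
#' @export
arm_usage <- function(hairpin_id, n5p, n3p, t5p, t3p) {
  if (any(n5p + n3p + t5p + t3p == 0)) {
    stop("all four arm counts are zero for: ",
         paste(hairpin_id[n5p + n3p + t5p + t3p == 0], collapse = ", "))
  }
  ratio_a <- ifelse(n3p > 0, n5p / n3p, NA_real_)
  ratio_b <- ifelse(t3p > 0, t5p / t3p, NA_real_)
  lrc <- ifelse(!is.na(ratio_a) & !is.na(ratio_b) & ratio_a > 0 & ratio_b > 0,
                log2(ratio_b / ratio_a), NA_real_)
  data.frame(hairpin_id = hairpin_id, n5p = n5p, n3p = n3p, t5p = t5p,
             t3p = t3p, ratio_a = ratio_a, ratio_b = ratio_b,
             log2_ratio_change = lrc, defined = !is.na(lrc),
             stringsAsFactors = FALSE)
}

#' Arm counts per hairpin from isomiR records
#'
#' Sums weighted isomiR counts per (hairpin, arm) for one library,
#' including opposite-arm (provisional) products.
#'
#' @param records isomiR records of one library.
#' @return data.frame `hairpin_id`, `c5p`, `c3p`.
#' @export
arm_counts <- function(records) {
  r <- .assigned_records(records)
  s5 <- rowsum(ifelse(r$arm == "5p", r$count, 0), r$hairpin_id)
  s3 <- rowsum(ifelse(r$arm == "3p", r$count, 0), r$hairpin_id)
  data.frame(hairpin_id = rownames(s5), c5p = s5[, 1L], c3p = s3[, 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-library summary statistics
#'
#' The six headline numbers of a small-RNA library: clean reads, percent
#' miRNA reads, detected pre-miRNAs, detected miRNAs, miRNAs detected at the
#' opposite (unannotated) arm, and percent of miRNA reads carrying a 3' end
#' modification. "Detected" means at least one assigned clean read (the
#' count >= 2 filter is already enforced upstream).
#'
#' @param clean clean-read data.frame of the library.
#' @param map_result output of [map_library()] for the library.
#' @param records isomiR records of the library.
#' @return named list of the six statistics.
#' @export
library_summary <- function(clean, map_result, records) {
  n_clean <- sum(clean$count)
  mapped_counts <- sum(clean$count) - sum(map_result$unmapped$count)
  r <- .assigned_records(records)
  list(
    n_clean_reads = n_clean,
    pct_mirna_reads = 100 * mapped_counts / n_clean,
    n_detected_premirnas = length(unique(r$hairpin_id)),
    n_detected_mirnas = length(unique(r$mature_name)),
    n_detected_opposite_arm = length(unique(r$mature_name[r$opposite_arm])),
    pct_modified = 100 * modification_profile(records)$modified_fraction
  )
}

#' Build a two-library fold-change table
#'
#' Joins per-miRNA TPM of two libraries (missing miRNAs get zero), computes
#' fold changes and tissue preference, and ranks by |log fc|. The
#' "differentially expressed" shortlist is by top |log fc| ranking, the
#' operational reading of selecting the miRNAs with the highest fold
#' changes.
#'
#' @param expr_a,expr_b data.frames with `mature_name` and `tpm` for the two
#'   libraries (a = reference/normal, b = tumor).
#' @param pseudo pseudocount passed to [fold_change()].
#' @return data.frame `mature_name`, `tpm_a`, `tpm_b`, `fc`, `preference`,
#'   sorted by decreasing |log fc| (undefined fc last).
#' @export
fold_change_table <- function(expr_a, expr_b, pseudo = 0) {
  all_names <- union(expr_a$mature_name, expr_b$mature_name)
  ta <- expr_a$tpm[match(all_names, expr_a$mature_name)]
  tb <- expr_b$tpm[match(all_names, expr_b$mature_name)]
  ta[is.na(ta)] <- 0
  tb[is.na(tb)] <- 0
  fc <- fold_change(ta, tb, pseudo = pseudo)
  out <- data.frame(mature_name = all_names, tpm_a = ta, tpm_b = tb, fc = fc,
                    preference = ifelse(is.na(fc) | fc == 1, "tie",
                                        ifelse(fc > 1, "b", "a")),
                    stringsAsFactors = FALSE)
  score <- abs(log(out$fc))
  score[!is.finite(score)] <- Inf
  score[is.na(out$fc)] <- -Inf
  out[order(-score), , drop = FALSE]
}
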