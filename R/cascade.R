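# Classification cascade for reads that failed hairpin mapping: ordered
# matching against per-class reference sets, allowing at most one
# substitution (no indels), first match wins; anything left is "unknown".

#' Classify non-miRNA reads against ordered reference sets
#'
#' Each read is searched (full-length, as a substring) against the reference
#' sets in cascade order; the first class containing a match with <= 1
#' substitution wins, preferring an exact (0-mismatch) hit within the class.
#' Reads matching no class are labeled "unknown".
#'
#' @param reads data.frame with `seq`, `count`, `library` (reads already
#'   unmapped by the hairpin mapper).
#' @param reference_sets named list of character vectors of reference
#'   sequences (see [read_reference_sets()]).
#' @param order cascade precedence; defaults to the declared order of
#'   `reference_sets`.
#' @return data.frame `seq`, `count`, `library`, `class_label`,
#'   `mismatches` (0, 1, or NA for unknown).
#' @export
classify_reads <- function(reads, reference_sets,
                           order = names(reference_sets)) {
  if (!all(order %in% names(reference_sets))) {
    stop("cascade order refers to classes without a reference set")
  }
  subjects <- lapply(reference_sets[order],
                     function(s) Biostrings::RNAStringSet(unname(s)))
  n <- nrow(reads)
  label <- rep("unknown", n)
  mm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pat <- Biostrings::RNAString(reads$seq[i])
    for (cls in order) {
      if (sum(Biostrings::vcountPattern(pat, subjects[[cls]],
                                        max.mismatch = 0)) > 0) {
        label[i] <- cls
        mm[i] <- 0L
        break
      }
      if (sum(Biostrings::vcountPattern(pat, subjects[[cls]],
                                        max.mismatch = 1,
                                        with.indels = FALSE)) > 0) {
        label[i] <- cls
        mm[i] <- 1L
        break
      }
    }
  }
  out <- reads[c("seq", "count", "library")]
  out$class_label <- label
  out$mismatches <- mm
  out
}

#' Class fractions over a complete library partition
#'
#' Combines miRNA-mapped totals with cascade assignments into the 10-class
#' composition of the library's clean reads. Fractions sum to 1.
#'
#' @param assignments data.frame from [classify_reads()] (each read once;
#'   duplicated sequences are an error).
#' @param mirna_count total clean-read count assigned to miRNAs by the
#'   hairpin mapper.
#' @return named numeric vector of fractions over miRNA, the eight
#'   reference classes, and unknown.
#' @export
summarize_categories <- function(assignments, mirna_count) {
  if (anyDuplicated(assignments$seq)) {
    stop("a read appears more than once in the cascade assignments")
  }
  classes <- c("miRNA", cascade_classes(), "unknown")
  if (any(!assignments$class_label %in% setdiff(classes, "miRNA"))) {
    stop("cascade assignments may not carry the miRNA label or unknown classes")
  }
  tot <- mirna_count + sum(assignments$count)
  if (tot <= 0) stop("empty library: no reads to summarize")
  s <- tapply(assignments$count,
              factor(assignments$class_label, levels = classes),
              sum, default = 0)
  s["miRNA"] <- mirna_count
  s / tot
}

#' Write a class-fraction summary as TSV
#'
#' @param fractions named vector(s); a named list gives one row per library.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_category_tsv <- function(fractions, path) {
  if (!is.list(fractions)) fractions <- list(library = fractions)
  df <- cbind(data.frame(library = names(fractions)),
              do.call(rbind, fractions))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
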