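# Clean-read production: 3' adapter trimming, collapsing to unique tags with
# counts, and the count/length filter.

#' Trim the 3' adapter from read sequences
#'
#' Cuts each read at the leftmost exact occurrence of an adapter prefix of
#' length `min_overlap` (anywhere in the read). Matching is exact: the
#' trimming probe is `substr(adapter, 1, min_overlap)`. Reads without a hit
#' get `NA` (no-adapter marker). Vectorized and pure.
#'
#' @param seqs character vector of read sequences (DNA or RNA; normalized
#'   internally).
#' @param adapter the 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length that counts as a hit.
#' @return character vector of trimmed inserts (U alphabet), `NA` where no
#'   adapter was found.
#' @export
trim_adapter <- function(seqs, adapter, min_overlap = 6L) {
  if (length(adapter) != 1L || is.na(adapter)) stop("adapter must be a single string")
  adapter <- normalize_rna(adapter)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L || nchar(adapter) < min_overlap) {
    stop("need adapter length >= min_overlap >= 1")
  }
  seqs <- normalize_rna(seqs)
  probe <- substr(adapter, 1L, min_overlap)
  hit <- regexpr(probe, seqs, fixed = TRUE)
  out <- rep(NA_character_, length(seqs))
  found <- hit > 0L
  out[found] <- substr(seqs[found], 1L, hit[found] - 1L)
  out
}

#' Collapse reads of one library to unique sequences with counts
#'
#' @param seqs character vector of (trimmed) read sequences.
#' @param library single library label, or a vector of labels that must all
#'   be equal (mixed labels are an error).
#' @return data.frame with columns `seq`, `count`, `library`, one row per
#'   distinct sequence; `sum(count)` equals `length(seqs)`.
#' @export
collapse_reads <- function(seqs, library) {
  lib <- unique(library)
  if (length(lib) > 1L) {
    stop("collapse_reads expects reads from a single library, got: ",
         paste(lib, collapse = ", "))
  }
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(), count = integer(),
                      library = character(), stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  data.frame(seq = names(tab), count = as.integer(tab),
             library = if (length(lib)) lib else NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter collapsed reads to the clean-read set
#'
#' Keeps reads observed at least `min_count` times with length inside
#' `[min_len, max_len]`. The count floor of 2 follows the confidence filter
#' used for deep small-RNA libraries; the default length window is 18-30 nt
#' (18 matches the mapper's perfect-match floor).
#'
#' @param reads data.frame from [collapse_reads()].
#' @param min_count minimum read count (>= 1).
#' @param min_len,max_len length window in nucleotides.
#' @return the surviving subset of `reads`.
#' @export
filter_clean <- function(reads, min_count = 2L, min_len = 18L, max_len = 30L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  len <- nchar(reads$seq)
  out <- reads[reads$count >= min_count & len >= min_len & len <= max_len, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read raw reads from FASTQ or FASTA
#'
#' Qualities are ignored. Returns plain sequences (not yet normalized).
#'
#' @param path input file; format from extension unless given.
#' @param format "auto", "fastq" or "fasta".
#' @return character vector of read sequences.
#' @export
read_raw_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  as.character(Biostrings::readBStringSet(path, format = format))
}

#' Read a pre-collapsed FASTA with counts encoded in headers
#'
#' Headers use the `>id_xCOUNT` dialect common for collapsed small-RNA tags.
#'
#' @param path FASTA path.
#' @param library library label attached to all reads.
#' @return data.frame with `seq`, `count`, `library`.
#' @export
read_collapsed_fasta <- function(path, library = NA_character_) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(seq = character(), count = integer(),
                      library = character(), stringsAsFactors = FALSE))
  }
  heads <- sub("\\s.*$", "", names(set))
  m <- regmatches(heads, regexec("_x(\\d+)$", heads))
  counts <- vapply(m, function(g) if (length(g) == 2L) as.integer(g[2]) else NA_integer_,
                   integer(1))
  if (anyNA(counts)) stop("collapsed FASTA headers must end in '_xCOUNT'")
  data.frame(seq = normalize_rna(as.character(set)), count = counts,
             library = library, stringsAsFactors = FALSE)
}

#' Write collapsed reads as a count-dialect FASTA
#'
#' @param reads data.frame with `seq` and `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  ids <- sprintf("read%06d_x%d", seq_len(nrow(reads)), reads$count)
  set <- Biostrings::BStringSet(setNames(reads$seq, ids))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Run the full preprocessing stage on one library
#'
#' Adapter trimming, removal of untrimmed and N-containing reads, collapsing,
#' and the count/length filter, with per-step read accounting.
#'
#' @param seqs raw read sequences.
#' @param library library label.
#' @param adapter 3' adapter sequence, or `NULL` for pre-trimmed input.
#' @param min_overlap adapter probe length, see [trim_adapter()].
#' @param keep_untrimmed keep reads without an adapter hit as-is (default:
#'   discard, since untrimmed tails would inflate 3'-modification calls).
#' @param min_count,min_len,max_len see [filter_clean()].
#' @return list with `clean` (the clean-read data.frame) and `stats`
#'   (named numeric vector of per-step read counts).
#' @export
preprocess_library <- function(seqs, library, adapter = NULL, min_overlap = 6L,
                               keep_untrimmed = FALSE, min_count = 2L,
                               min_len = 18L, max_len = 30L) {
  n_input <- length(seqs)
  seqs <- normalize_rna(seqs)
  n_no_adapter <- 0L
  if (!is.null(adapter)) {
    trimmed <- trim_adapter(seqs, adapter, min_overlap)
    if (keep_untrimmed) {
      trimmed[is.na(trimmed)] <- seqs[is.na(trimmed)]
    } else {
      n_no_adapter <- sum(is.na(trimmed))
      trimmed <- trimmed[!is.na(trimmed)]
    }
    seqs <- trimmed
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  n_with_n <- sum(has_n)
  seqs <- seqs[!has_n]
  collapsed <- collapse_reads(seqs, library)
  clean <- filter_clean(collapsed, min_count = min_count,
                        min_len = min_len, max_len = max_len)
  list(clean = clean,
       stats = c(n_input = n_input, n_no_adapter = n_no_adapter,
                 n_with_n = n_with_n, n_collapsed_tags = nrow(collapsed),
                 n_clean_tags = nrow(clean), n_clean_reads = sum(clean$count)))
}
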