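# Reference model: pre-miRNA hairpins, mature-miRNA annotations, and per-class
# reference sets. Everything downstream uses the convention defined here:
# 1-based inclusive positions on the hairpin sense strand, RNA (U) alphabet.

.RNA_LETTERS <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Upper-cases and converts T to U. DNA input (sequencers) and RNA input
#' (miRBase-style references) thereby share one internal alphabet.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector in the A/C/G/U alphabet (other letters untouched).
#' @export
normalize_rna <- function(x) chartr("T", "U", toupper(x))

#' Read a hairpin (pre-miRNA) reference FASTA
#'
#' Parses a FASTA file of hairpin precursor sequences. Identifiers are the
#' first whitespace-delimited token of each header. Sequences are normalized
#' to the RNA alphabet; hairpins must be at least 40 nt, contain only
#' A/C/G/U after normalization, and carry unique identifiers.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `seq`, `length`.
#' @export
read_hairpin_fasta <- function(path) {
  if (!file.exists(path)) stop("hairpin FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("hairpin FASTA '", path, "' contains no records")
    return(data.frame(id = character(), seq = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_rna(as.character(set))
  as_hairpin_set(ids, seqs)
}

# Shared validation used by the FASTA reader and the synthetic generator.
as_hairpin_set <- function(ids, seqs) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate hairpin id(s): ", paste(unique(dup), collapse = ", "))
  bad <- !grepl("^[ACGU]+$", seqs)
  if (any(bad)) {
    stop("non-nucleotide character in hairpin record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  len <- nchar(seqs)
  if (any(len < 40L)) {
    stop("hairpin(s) shorter than 40 nt: ", paste(ids[len < 40L], collapse = ", "))
  }
  data.frame(id = ids, seq = seqs, length = len, stringsAsFactors = FALSE)
}

#' Write a hairpin set to FASTA
#'
#' @param hairpins data.frame as returned by [read_hairpin_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hairpin_fasta <- function(hairpins, path) {
  set <- Biostrings::BStringSet(setNames(hairpins$seq, hairpins$id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read mature-miRNA annotations from a TSV file
#'
#' The file must be tab-separated with header columns `hairpin_id`,
#' `mature_name`, `arm`, `start`, `end`. Coordinates are 1-based inclusive on
#' the hairpin. Each (hairpin, arm) pair may be annotated once; the mature
#' span must lie inside the hairpin and be 16-30 nt long.
#'
#' @param path path to the annotation TSV.
#' @param hairpins hairpin set the coordinates refer to.
#' @return validated data.frame of annotations.
#' @export
read_mature_annotations <- function(path, hairpins) {
  if (!file.exists(path)) stop("annotation TSV not found: ", path)
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("hairpin_id", "mature_name", "arm", "start", "end")
  if (!all(need %in% names(ann))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  validate_annotations(ann[need], hairpins)
}

validate_annotations <- function(ann, hairpins) {
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  unknown <- setdiff(ann$hairpin_id, hairpins$id)
  if (length(unknown)) stop("annotation refers to unknown hairpin(s): ",
                            paste(unknown, collapse = ", "))
  if (!all(ann$arm %in% c("5p", "3p"))) stop("arm must be '5p' or '3p'")
  hlen <- hairpins$length[match(ann$hairpin_id, hairpins$id)]
  bad <- ann$start < 1L | ann$start >= ann$end | ann$end > hlen
  if (any(bad)) {
    stop("annotation coordinates out of range for: ",
         paste(ann$mature_name[bad], collapse = ", "))
  }
  mlen <- ann$end - ann$start + 1L
  if (any(mlen < 16L | mlen > 30L)) {
    stop("mature length outside 16-30 nt for: ",
         paste(ann$mature_name[mlen < 16L | mlen > 30L], collapse = ", "))
  }
  key <- paste(ann$hairpin_id, ann$arm)
  if (anyDuplicated(key)) {
    stop("duplicate (hairpin, arm) annotation: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(ann) <- NULL
  ann
}

#' Locate mature miRNAs on hairpins by exact substring search
#'
#' Convenience for mature-sequence FASTA inputs without coordinates: each
#' mature sequence is located on every hairpin containing it exactly once.
#' The arm is inferred from the mature midpoint relative to the hairpin
#' midpoint (5' half = 5p). A mature occurring at more than one position
#' within a single hairpin is ambiguous and raises an error; one matching
#' nowhere is skipped with a warning.
#'
#' @param mature_fasta path to a FASTA of mature miRNA sequences.
#' @param hairpins hairpin set to search.
#' @return validated annotation data.frame.
#' @export
locate_mature_by_sequence <- function(mature_fasta, hairpins) {
  set <- Biostrings::readBStringSet(mature_fasta)
  mseqs <- normalize_rna(as.character(set))
  mnames <- sub("\\s.*$", "", names(set))
  rows <- vector("list", length(mseqs))
  for (i in seq_along(mseqs)) {
    found <- FALSE
    for (j in seq_len(nrow(hairpins))) {
      pos <- gregexpr(mseqs[i], hairpins$seq[j], fixed = TRUE)[[1]]
      if (pos[1] == -1L) next
      if (length(pos) > 1L) {
        stop("mature '", mnames[i], "' occurs at multiple positions (",
             paste(pos, collapse = ", "), ") in hairpin '", hairpins$id[j], "'")
      }
      start <- as.integer(pos[1])
      end <- start + nchar(mseqs[i]) - 1L
      mid <- (start + end) / 2
      arm <- if (mid <= hairpins$length[j] / 2) "5p" else "3p"
      rows[[i]] <- rbind(rows[[i]], data.frame(
        hairpin_id = hairpins$id[j], mature_name = mnames[i], arm = arm,
        start = start, end = end, stringsAsFactors = FALSE))
      found <- TRUE
    }
    if (!found) warning("mature '", mnames[i], "' not found in any hairpin; skipped")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(hairpin_id = character(), mature_name = character(),
                      arm = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  validate_annotations(out, hairpins)
}

#' The fixed vocabulary of non-miRNA reference classes
#'
#' Order matters: it is the default precedence of the classification cascade.
#' @return character vector of the eight reference-backed class labels.
#' @export
cascade_classes <- function() {
  c("mRNA", "tRNA", "rRNA", "snoRNA", "scaRNA", "snRNA", "other ncRNA", "repeat")
}

#' Read per-class reference sets for the non-miRNA cascade
#'
#' @param paths named character vector or list mapping class labels (a subset
#'   of [cascade_classes()]) to FASTA paths.
#' @return named list of character vectors of U-alphabet sequences.
#' @export
read_reference_sets <- function(paths) {
  labs <- names(paths)
  if (is.null(labs) || !all(labs %in% cascade_classes())) {
    stop("reference-set names must be drawn from: ",
         paste(cascade_classes(), collapse = ", "))
  }
  out <- lapply(paths, function(p) {
    set <- Biostrings::readBStringSet(p)
    if (length(set) == 0L) stop("empty reference FASTA: ", p)
    setNames(normalize_rna(as.character(set)), sub("\\s.*$", "", names(set)))
  })
  out
}
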