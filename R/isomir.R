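# IsomiR classification: assign hairpin alignments to mature annotations,
# compute 5'/3' position shifts, categorize 3' nontemplate additions, detect
# opposite-arm products, and aggregate to per-miRNA counts.
#
# Shift convention: positive = downstream (toward the hairpin 3' end);
# shift5 = read start - annotated start, shift3 = matched end - annotated
# end. The 3' shift is computed on the matched (templated) end, before any
# nontemplate suffix: tailing is not a position shift.

.MOD_CATEGORIES <- c("none", "A", "U", "AA", "UU", "AU", "C", "G", "other")

#' Categorize a 3' nontemplate suffix
#'
#' The enumerated categories are the mono- and dinucleotide additions that
#' dominate miRNA 3' tailing (A, U, AA, UU, AU, C, G); any other non-empty
#' suffix is "other" and an empty suffix is "none".
#'
#' @param mod_suffix character vector of suffixes (U alphabet).
#' @return character vector of categories.
#' @export
classify_modification <- function(mod_suffix) {
  ifelse(mod_suffix == "", "none",
         ifelse(mod_suffix %in% c("A", "U", "AA", "UU", "AU", "C", "G"),
                mod_suffix, "other"))
}

# Aggregate record rows sharing all `keys`, summing weighted counts.
.aggregate_records <- function(df, keys) {
  key <- do.call(paste, c(df[keys], list(sep = "\r")))
  agg <- rowsum(df$count, key)
  ord <- match(rownames(agg), key)
  out <- df[ord, keys, drop = FALSE]
  out$count <- as.numeric(agg[, 1L])
  rownames(out) <- NULL
  out
}

#' Classify hairpin alignments into isomiR records
#'
#' Each alignment is assigned to the mature annotation on its hairpin with
#' maximal overlap, provided both position shifts are within
#' `shift_window`. Alignments on an arm carrying no annotation become
#' opposite-arm records under a provisional locus named
#' `<hairpin>-<arm>-novel` whose coordinates are the count-weighted modal
#' alignment; alignments on an annotated arm but outside the shift window
#' are returned with status "unassigned" (and `NA` mature name) rather than
#' silently binned. Alignments of one read that resolve to the same mature
#' name (paralogous hairpins) are merged so the read is counted once per
#' name.
#'
#' @param alignments data.frame from [map_library()].
#' @param annotations validated annotation data.frame.
#' @param hairpins hairpin set (for arm inference by the midpoint rule).
#' @param shift_window maximum |shift| for assignment to an annotation.
#' @return data.frame of isomiR records with columns `mature_name`,
#'   `hairpin_id`, `arm`, `shift5`, `shift3`, `mod_suffix`, `mod_category`,
#'   `count` (weighted), `library`, `opposite_arm`, `status`, `read_start`,
#'   `read_end`.
#' @export
classify_isomirs <- function(alignments, annotations, hairpins,
                             shift_window = 5L) {
  empty <- data.frame(mature_name = character(), hairpin_id = character(),
                      arm = character(), shift5 = integer(), shift3 = integer(),
                      mod_suffix = character(), mod_category = character(),
                      count = numeric(), library = character(),
                      opposite_arm = logical(), status = character(),
                      read_start = integer(), read_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  aln <- alignments
  aln$.aln <- seq_len(nrow(aln))
  aln$read_start <- aln$start
  aln$read_end <- aln$start + aln$match_len - 1L
  ann <- annotations
  names(ann)[names(ann) == "start"] <- "ann_start"
  names(ann)[names(ann) == "end"] <- "ann_end"

  m <- merge(aln, ann, by = "hairpin_id", all.x = TRUE)
  m$overlap <- pmin(m$read_end, m$ann_end) - pmax(m$read_start, m$ann_start) + 1L
  m$overlap[is.na(m$overlap)] <- -Inf
  # best annotation per alignment; ties broken toward the 5p arm
  m <- m[order(m$.aln, -m$overlap, m$arm), , drop = FALSE]
  m <- m[!duplicated(m$.aln), , drop = FALSE]

  m$shift5 <- m$read_start - m$ann_start
  m$shift3 <- m$read_end - m$ann_end
  assigned <- !is.na(m$mature_name) & m$overlap > 0 &
    abs(m$shift5) <= shift_window & abs(m$shift3) <= shift_window

  # arm inference for non-assigned alignments: hairpin-half midpoint rule
  hlen <- hairpins$length[match(m$hairpin_id, hairpins$id)]
  mid_arm <- ifelse((m$read_start + m$read_end) / 2 <= hlen / 2, "5p", "3p")
  ann_key <- paste(annotations$hairpin_id, annotations$arm)
  on_annotated_arm <- paste(m$hairpin_id, mid_arm) %in% ann_key

  m$status <- ifelse(assigned, "annotated",
                     ifelse(on_annotated_arm, "unassigned", "opposite"))
  m$opposite_arm <- m$status == "opposite"
  m$arm[!assigned] <- mid_arm[!assigned]
  m$mature_name[!assigned] <- NA_character_

  # provisional loci for opposite-arm alignments: weighted modal coordinates
  opp <- m$status == "opposite"
  if (any(opp)) {
    w <- m$count[opp] * m$weight[opp]
    grp <- paste(m$hairpin_id[opp], m$arm[opp])
    modal <- function(v) {
      # weighted mode per group; ties broken toward the smaller coordinate
      s <- rowsum(w, paste(grp, v, sep = "\r"))
      gg <- sub("\r.*", "", rownames(s))
      vv <- as.integer(sub(".*\r", "", rownames(s)))
      o <- order(gg, -s[, 1L], vv)
      sel <- !duplicated(gg[o])
      setNames(vv[o][sel], gg[o][sel])
    }
    mstart <- modal(m$read_start[opp])
    mend <- modal(m$read_end[opp])
    m$mature_name[opp] <- paste0(m$hairpin_id[opp], "-", m$arm[opp], "-novel")
    m$shift5[opp] <- m$read_start[opp] - mstart[grp]
    m$shift3[opp] <- m$read_end[opp] - mend[grp]
  }

  m$mod_category <- classify_modification(m$mod_suffix)
  m$count <- m$count * m$weight
  keys <- c("mature_name", "hairpin_id", "arm", "shift5", "shift3",
            "mod_suffix", "mod_category", "library", "opposite_arm",
            "status", "read_start", "read_end")
  out <- .aggregate_records(m, keys)
  # paralog merge: one read, one mature name -> summed weights; collapse the
  # per-hairpin duplicates onto the alphabetically first hairpin id
  out <- out[order(out$mature_name, out$hairpin_id), , drop = FALSE]
  dupkey <- do.call(paste, c(out[c("mature_name", "shift5", "shift3",
                                   "mod_suffix", "library", "status")],
                             list(sep = "\r")))
  dupkey[is.na(out$mature_name)] <- paste0("ua\r", seq_len(nrow(out)))[is.na(out$mature_name)]
  first_h <- tapply(out$hairpin_id, dupkey, min)
  out$hairpin_id <- as.character(first_h[dupkey])
  out <- .aggregate_records(out, keys)
  rownames(out) <- NULL
  out
}

# Records usable in summaries: everything that was assigned a mature name.
.assigned_records <- function(records) {
  records[records$status != "unassigned" & !is.na(records$mature_name), ,
          drop = FALSE]
}

#' Count-weighted distribution of position shifts
#'
#' @param records isomiR records from [classify_isomirs()] (unassigned rows
#'   are ignored).
#' @param end which read end: `"5p"` (shift5) or `"3p"` (shift3).
#' @return named numeric vector of fractions over shift values (names are
#'   integers as character), summing to 1.
#' @export
summarize_shifts <- function(records, end = c("5p", "3p")) {
  end <- match.arg(end)
  r <- .assigned_records(records)
  if (nrow(r) == 0L) stop("no assigned isomiR records to summarize")
  v <- if (end == "5p") r$shift5 else r$shift3
  s <- rowsum(r$count, v)
  frac <- s[, 1L] / sum(s[, 1L])
  frac[order(as.integer(names(frac)))]
}

#' Count-weighted 3'-modification profile
#'
#' @param records isomiR records (unassigned rows ignored).
#' @return list with `fractions` (named over all modification categories,
#'   summing to 1) and `modified_fraction` (1 - fraction unmodified).
#' @export
modification_profile <- function(records) {
  r <- .assigned_records(records)
  if (nrow(r) == 0L) stop("no assigned isomiR records to summarize")
  s <- rowsum(r$count, factor(r$mod_category, levels = .MOD_CATEGORIES))
  frac <- setNames(s[, 1L] / sum(s[, 1L]), rownames(s))
  list(fractions = frac, modified_fraction = unname(1 - frac["none"]))
}

#' Aggregate isomiR records to per-miRNA counts
#'
#' Sums isomiR counts per (mature name, library) and reports whether the
#' reference isoform (shift 0,0 and no 3' modification) is the most abundant
#' isomiR of that miRNA (ties with the top count as TRUE).
#'
#' @param records isomiR records (unassigned rows ignored).
#' @return data.frame with `mature_name`, `library`, `count`,
#'   `ref_most_abundant`, `opposite_arm`.
#' @export
aggregate_mirna <- function(records) {
  r <- .assigned_records(records)
  if (nrow(r) == 0L) {
    return(data.frame(mature_name = character(), library = character(),
                      count = numeric(), ref_most_abundant = logical(),
                      opposite_arm = logical(), stringsAsFactors = FALSE))
  }
  cell <- do.call(paste, c(r[c("mature_name", "library", "shift5", "shift3",
                               "mod_suffix")], list(sep = "\r")))
  cell_sum <- rowsum(r$count, cell)[, 1L]
  grp <- sub("^([^\r]*\r[^\r]*)\r.*$", "\\1", names(cell_sum))
  top <- tapply(cell_sum, grp, max)
  is_ref <- sub("^[^\r]*\r[^\r]*\r", "", names(cell_sum)) == "0\r0\r"
  ref <- tapply(ifelse(is_ref, cell_sum, 0), grp, max)

  gkey <- do.call(paste, c(r[c("mature_name", "library")], list(sep = "\r")))
  tot <- rowsum(r$count, gkey)
  opp <- tapply(r$opposite_arm, gkey, any)
  g <- rownames(tot)
  data.frame(
    mature_name = sub("\r.*", "", g),
    library = sub(".*\r", "", g),
    count = tot[, 1L],
    ref_most_abundant = unname(ref[g] > 0 & ref[g] >= top[g]),
    opposite_arm = unname(opp[g]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Text rendering of the isomiR stack of one hairpin
#'
#' Produces an alignment picture: the hairpin sequence on top, then each
#' isomiR indented to its start position, with nontemplate 3' additions in
#' lowercase and the weighted count and (shift5, shift3) pair on the right.
#'
#' @param records isomiR records.
#' @param hairpin_id hairpin to render.
#' @param hairpins hairpin set.
#' @return character vector of report lines.
#' @export
format_hairpin_stack <- function(records, hairpin_id, hairpins) {
  hseq <- hairpins$seq[match(hairpin_id, hairpins$id)]
  if (is.na(hseq)) stop("unknown hairpin: ", hairpin_id)
  r <- .assigned_records(records)
  r <- r[r$hairpin_id == hairpin_id, , drop = FALSE]
  r <- r[order(-r$count), , drop = FALSE]
  lines <- c(paste0(">", hairpin_id), hseq)
  for (i in seq_len(nrow(r))) {
    body <- paste0(strrep(" ", r$read_start[i] - 1L),
                   substr(hseq, r$read_start[i], r$read_end[i]),
                   tolower(r$mod_suffix[i]))
    lines <- c(lines, sprintf("%-*s  %g (%+d,%+d) %s", nchar(hseq) + 4L, body,
                              r$count[i], r$shift5[i], r$shift3[i],
                              r$mature_name[i]))
  }
  lines
}

#' Write isomiR records as TSV
#'
#' @param records isomiR records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isomir_tsv <- function(records, path) {
  cols <- c("mature_name", "hairpin_id", "arm", "shift5", "shift3",
            "mod_suffix", "mod_category", "count", "library", "opposite_arm")
  write.table(records[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
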