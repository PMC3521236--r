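# End-to-end orchestration: preprocess -> map -> isomiR -> cascade ->
# quantify, per library and across two libraries, with TSV report emission
# and a machine-readable manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the small-RNA analysis on in-memory libraries
#'
#' @param reads_by_library named list of character vectors of raw read
#'   sequences (adapters still attached unless `adapter` is `NULL`).
#' @param hairpins hairpin set.
#' @param annotations validated mature annotations.
#' @param reference_sets optional named list for the non-miRNA cascade.
#' @param adapter 3' adapter (or `NULL` for pre-trimmed reads).
#' @param min_overlap,min_count,min_len,max_len preprocessing parameters.
#' @param shift_window isomiR assignment window.
#' @param tpm_denominator `"clean"` (whole-library clean reads, default) or
#'   `"mirna"` (miRNA-mapped subtotal).
#' @param fc_pseudo pseudocount for fold changes.
#' @param cascade_order class precedence for the cascade.
#' @return object of class `smallrna_study`.
#' @export
run_small_rna_study <- function(reads_by_library, hairpins, annotations,
                                reference_sets = NULL, adapter = NULL,
                                min_overlap = 6L, min_count = 2L,
                                min_len = 18L, max_len = 30L,
                                shift_window = 5L,
                                tpm_denominator = c("clean", "mirna"),
                                fc_pseudo = 0,
                                cascade_order = NULL) {
  tpm_denominator <- match.arg(tpm_denominator)
  if (is.null(names(reads_by_library))) {
    stop("reads_by_library must be a named list")
  }
  index <- .stage("index", build_hairpin_index(hairpins))
  if (!is.null(reference_sets) && is.null(cascade_order)) {
    cascade_order <- intersect(cascade_classes(), names(reference_sets))
  }
  libs <- list()
  for (lib in names(reads_by_library)) {
    pre <- .stage("preprocess", preprocess_library(
      reads_by_library[[lib]], lib, adapter = adapter,
      min_overlap = min_overlap, min_count = min_count, min_len = min_len,
      max_len = max_len))
    mp <- .stage("map", map_library(pre$clean, index))
    records <- .stage("isomir", classify_isomirs(mp$alignments, annotations,
                                                 hairpins, shift_window))
    summ <- .stage("summary", library_summary(pre$clean, mp, records))
    categories <- NULL
    assignments <- NULL
    if (!is.null(reference_sets)) {
      assignments <- .stage("classify", classify_reads(mp$unmapped,
                                                       reference_sets,
                                                       cascade_order))
      mirna_count <- sum(pre$clean$count) - sum(mp$unmapped$count)
      categories <- .stage("classify", summarize_categories(assignments,
                                                            mirna_count))
    }
    agg <- .stage("quantify", aggregate_mirna(records))
    denom <- if (tpm_denominator == "clean") sum(pre$clean$count) else
      sum(pre$clean$count) - sum(mp$unmapped$count)
    expr <- .stage("quantify", tpm_normalize(agg, denom))
    libs[[lib]] <- list(
      clean = pre$clean, stats = pre$stats, map = mp, records = records,
      summary = summ, assignments = assignments, categories = categories,
      shift5 = summarize_shifts(records, "5p"),
      shift3 = summarize_shifts(records, "3p"),
      mod_profile = modification_profile(records),
      expression = expr, library_total = denom)
  }
  comparison <- NULL
  if (length(libs) == 2L) {
    a <- names(libs)[1]
    b <- names(libs)[2]
    fc_tab <- .stage("quantify", fold_change_table(libs[[a]]$expression,
                                                   libs[[b]]$expression,
                                                   pseudo = fc_pseudo))
    ac_a <- arm_counts(libs[[a]]$records)
    ac_b <- arm_counts(libs[[b]]$records)
    ids <- union(ac_a$hairpin_id, ac_b$hairpin_id)
    g <- function(df, col) {
      v <- df[[col]][match(ids, df$hairpin_id)]
      ifelse(is.na(v), 0, v)
    }
    both <- (g(ac_a, "c5p") > 0 & g(ac_a, "c3p") > 0) |
      (g(ac_b, "c5p") > 0 & g(ac_b, "c3p") > 0)
    au <- .stage("quantify", arm_usage(ids[both], g(ac_a, "c5p")[both],
                                       g(ac_a, "c3p")[both],
                                       g(ac_b, "c5p")[both],
                                       g(ac_b, "c3p")[both]))
    comparison <- list(a = a, b = b, fold_changes = fc_tab, arm_usage = au)
  }
  params <- list(adapter = adapter, min_overlap = min_overlap,
                 min_count = min_count, min_len = min_len, max_len = max_len,
                 match_floor = index$k, shift_window = shift_window,
                 tpm_denominator = tpm_denominator, fc_pseudo = fc_pseudo,
                 cascade_order = cascade_order)
  manifest <- list(
    parameters = params,
    libraries = lapply(libs, function(l) {
      c(as.list(l$stats),
        list(n_alignments = nrow(l$map$alignments),
             n_unmapped_tags = nrow(l$map$unmapped),
             mirna_read_count = sum(l$clean$count) - sum(l$map$unmapped$count),
             cascade_read_count = sum(l$map$unmapped$count),
             n_isomir_records = nrow(l$records)))
    }))
  structure(list(libraries = libs, comparison = comparison, params = params,
                 manifest = manifest), class = "smallrna_study")
}

#' @export
print.smallrna_study <- function(x, ...) {
  cat("smallrna_study:", length(x$libraries), "library(ies)\n\n")
  stats <- vapply(x$libraries, function(l) {
    unlist(l$summary)
  }, numeric(6))
  rownames(stats) <- c("# clean reads", "% miRNA reads",
                       "# detected pre-miRNAs", "# detected miRNAs",
                       "# detected miRNAs at opposite arm",
                       "% miRNA reads with 3' end modification")
  print(round(stats, 2))
  if (!is.null(x$comparison)) {
    cat("\nfold-change table:", nrow(x$comparison$fold_changes),
        "miRNAs; arm-usage table:", nrow(x$comparison$arm_usage),
        "hairpins\n")
  }
  invisible(x)
}

#' @export
summary.smallrna_study <- function(object, ...) {
  lapply(object$libraries, `[[`, "summary")
}

#' Barplot of position-shift distributions
#'
#' @param x a `smallrna_study`.
#' @param which `"shift3"` or `"shift5"`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted matrix.
#' @export
plot.smallrna_study <- function(x, which = c("shift3", "shift5"), ...) {
  which <- match.arg(which)
  shifts <- lapply(x$libraries, `[[`, which)
  keys <- sort(as.integer(unique(unlist(lapply(shifts, names)))))
  m <- vapply(shifts, function(s) {
    v <- s[as.character(keys)]
    ifelse(is.na(v), 0, v)
  }, numeric(length(keys)))
  m <- t(m)
  colnames(m) <- keys
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    xlab = sprintf("position shift (%s' end)",
                                   if (which == "shift3") "3" else "5"),
                    ylab = "fraction of miRNA reads", ...)
  invisible(m)
}

#' Write the report bundle of a study
#'
#' Emits per-library and cross-library TSVs plus a JSON manifest; all
#' outputs are deterministic for fixed inputs.
#'
#' @param x a `smallrna_study`.
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_reports <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  summ <- data.frame(library = names(x$libraries),
                     do.call(rbind, lapply(x$libraries, function(l) {
                       as.data.frame(l$summary)
                     })), row.names = NULL)
  paths["summary"] <- tsv(summ, "library_summary.tsv")
  cats <- Filter(Negate(is.null), lapply(x$libraries, `[[`, "categories"))
  if (length(cats)) {
    paths["categories"] <- file.path(dir, "class_fractions.tsv")
    write_category_tsv(cats, paths["categories"])
  }
  for (lib in names(x$libraries)) {
    paths[paste0("isomir_", lib)] <- file.path(dir,
                                               paste0("isomirs_", lib, ".tsv"))
    write_isomir_tsv(x$libraries[[lib]]$records, paths[paste0("isomir_", lib)])
  }
  shifts <- do.call(rbind, lapply(names(x$libraries), function(lib) {
    l <- x$libraries[[lib]]
    rbind(data.frame(library = lib, end = "5p", shift = names(l$shift5),
                     fraction = as.numeric(l$shift5)),
          data.frame(library = lib, end = "3p", shift = names(l$shift3),
                     fraction = as.numeric(l$shift3)))
  }))
  paths["shifts"] <- tsv(shifts, "shift_distributions.tsv")
  mods <- do.call(rbind, lapply(names(x$libraries), function(lib) {
    f <- x$libraries[[lib]]$mod_profile$fractions
    data.frame(library = lib, category = names(f), fraction = as.numeric(f))
  }))
  paths["modifications"] <- tsv(mods, "modification_profile.tsv")
  expr <- do.call(rbind, lapply(x$libraries, `[[`, "expression"))
  paths["expression"] <- tsv(expr, "expression.tsv")
  if (!is.null(x$comparison)) {
    paths["fold_changes"] <- tsv(x$comparison$fold_changes, "fold_changes.tsv")
    paths["arm_usage"] <- tsv(x$comparison$arm_usage, "arm_usage.tsv")
  }
  paths["manifest"] <- file.path(dir, "manifest.json")
  jsonlite::write_json(x$manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Run the pipeline from a file-based configuration
#'
#' @param config list with entries: `libraries` (named list of FASTQ/FASTA
#'   paths), `hairpin_fasta`, one of `annotation_tsv` or `mature_fasta`,
#'   optional `class_references` (named FASTA paths), optional
#'   `pcr_fc_tsv` (columns `mature_name`, `fc`; external fold changes for a
#'   concordance check), optional `gmt` + `target_lists` (paths to
#'   newline-delimited gene lists; their union is tested), optional
#'   `output_dir`, plus any parameter of [run_small_rna_study()].
#' @return the `smallrna_study` object, with `concordance` and `enrichment`
#'   components when the corresponding inputs are configured.
#' @export
run_pipeline <- function(config) {
  need <- c("libraries", "hairpin_fasta")
  if (!all(need %in% names(config))) {
    stop("config must include: ", paste(need, collapse = ", "))
  }
  hairpins <- .stage("references", read_hairpin_fasta(config$hairpin_fasta))
  annotations <- .stage("references", {
    if (!is.null(config$annotation_tsv)) {
      read_mature_annotations(config$annotation_tsv, hairpins)
    } else if (!is.null(config$mature_fasta)) {
      locate_mature_by_sequence(config$mature_fasta, hairpins)
    } else stop("need annotation_tsv or mature_fasta")
  })
  reference_sets <- NULL
  if (!is.null(config$class_references)) {
    reference_sets <- .stage("references",
                             read_reference_sets(config$class_references))
  }
  reads <- .stage("input", lapply(config$libraries, read_raw_reads))
  par_names <- c("adapter", "min_overlap", "min_count", "min_len", "max_len",
                 "shift_window", "tpm_denominator", "fc_pseudo",
                 "cascade_order")
  args <- c(list(reads_by_library = reads, hairpins = hairpins,
                 annotations = annotations, reference_sets = reference_sets),
            config[intersect(par_names, names(config))])
  x <- do.call(run_small_rna_study, args)
  if (!is.null(config$pcr_fc_tsv) && !is.null(x$comparison)) {
    ext <- .stage("concordance", read.delim(config$pcr_fc_tsv,
                                            stringsAsFactors = FALSE))
    fc <- x$comparison$fold_changes
    m <- match(ext$mature_name, fc$mature_name)
    ok <- !is.na(m) & is.finite(fc$fc[m]) & fc$fc[m] > 0 &
      is.finite(ext$fc) & ext$fc > 0
    x$concordance <- .stage("concordance", concordance(fc$fc[m][ok],
                                                       ext$fc[ok]))
    x$manifest$concordance_pairs <- sum(ok)
  }
  if (!is.null(config$gmt) && !is.null(config$target_lists)) {
    pathways <- .stage("enrich", read_gmt(config$gmt))
    targets <- unique(unlist(lapply(config$target_lists, read_gene_list)))
    x$enrichment <- .stage("enrich", enrich_targets(targets, pathways))
  } else {
    x$manifest$enrichment <- "skipped (no gmt/target inputs)"
  }
  if (!is.null(config$output_dir)) {
    paths <- write_reports(x, config$output_dir)
    if (!is.null(x$enrichment)) {
      p <- file.path(config$output_dir, "enrichment.tsv")
      write.table(x$enrichment, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  x
}
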