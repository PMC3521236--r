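# Synthetic-study generator: random hairpin references with annotated mature
# arms, per-class contaminant reference sets, and paired normal/tumor read
# libraries with a per-read truth table. The defaults emulate the observed
# statistical structure of deep breast normal/tumor small-RNA libraries:
# 5'/3' position-shift spectra, 3'-tailing rates and composition, per-class
# read proportions, and 5p/3p arm-usage ratios.

.OTHER_TAILS <- c("GG", "CC", "CA", "GC", "AG", "UC", "GA", "CU")

#' Default per-class clean-read proportions
#'
#' Ten-class composition (miRNA, eight reference classes, unknown) per
#' library, normalized to sum to 1. The values mirror the composition
#' observed in deep breast normal and tumor small-RNA libraries.
#'
#' @return 2 x 10 matrix with rows `normal`, `tumor`.
#' @export
default_class_props <- function() {
  classes <- c("miRNA", cascade_classes(), "unknown")
  normal <- c(75.24, 2.16, 0.47, 0.87, 0.84, 0.04, 0.12, 9.78, 0.0349, 10.45)
  tumor <- c(84.79, 0.86, 0.37, 0.33, 0.35, 0.04, 0.14, 6.40, 0.0006, 6.70)
  m <- rbind(normal = normal / sum(normal), tumor = tumor / sum(tumor))
  colnames(m) <- classes
  m
}

#' Configuration for a synthetic small-RNA study
#'
#' All probability laws are fixed at construction; with a fixed seed the
#' generator output is byte-identical across runs. Default laws: the 5' shift
#' is dominated by 0 (95%, with -1/+1 at 1%/4%); the 3' shift is broader
#' (-2..+2 at 5/20/56/15/1%, the remaining 3% split over -3/+3); tailing
#' probabilities are 17.65% (normal) and 12.45% (tumor) with A and U making
#' up 80% of tail events; class proportions per [default_class_props()].
#'
#' @param seed integer random seed for the whole study.
#' @param n_hairpins number of hairpins.
#' @param hairpin_len_range inclusive length range (min must accommodate two
#'   mature arms, >= 2 * (mature_len + 16) + 2).
#' @param mature_len mature miRNA length in nt.
#' @param n_reads reads per library.
#' @param expression_meanlog,expression_sdlog log-normal law for hairpin
#'   expression weights.
#' @param single_arm_frac fraction of hairpins annotated on the 5p arm only
#'   (their 3p products exercise opposite-arm detection).
#' @param shift5_law,shift3_law named probability vectors over integer shifts.
#' @param tailing_prob named per-library probabilities of a 3' nontemplate
#'   tail.
#' @param tail_law named probability vector over tail categories
#'   (A, U, AA, UU, AU, C, G, other).
#' @param class_props per-library class-proportion matrix.
#' @param de_multipliers named vector of expected tumor/normal fold changes
#'   for designated mature miRNAs.
#' @param arm_switch named list: hairpin -> list(normal = c(n5p, n3p),
#'   tumor = c(t5p, t3p)) arm-count proportions per library.
#' @param arm_share_range range of the per-hairpin 5p share for
#'   non-switching hairpins.
#' @param paralog_copies extra identical copies of the first hairpin (to
#'   exercise multi-map weighting).
#' @param adapter 3' adapter appended to every synthetic read.
#' @param n_ref_seqs,ref_seq_len per-class contaminant reference set sizes.
#' @param n_windows per-class contaminant read-window pool sizes.
#' @param n_unknown unknown-read pool size.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_hairpins = 20L,
                         hairpin_len_range = c(80L, 90L),
                         mature_len = 22L,
                         n_reads = 1e5,
                         expression_meanlog = 0,
                         expression_sdlog = 1,
                         single_arm_frac = 0.2,
                         shift5_law = c("-1" = 0.01, "0" = 0.95, "1" = 0.04),
                         shift3_law = c("-3" = 0.015, "-2" = 0.05, "-1" = 0.20,
                                        "0" = 0.56, "1" = 0.15, "2" = 0.01,
                                        "3" = 0.015),
                         tailing_prob = c(normal = 0.1765, tumor = 0.1245),
                         tail_law = c(A = 0.45, U = 0.35, AA = 0.04, UU = 0.03,
                                      AU = 0.03, C = 0.04, G = 0.03,
                                      other = 0.03),
                         class_props = default_class_props(),
                         de_multipliers = c("syn-miR-03-5p" = 9.88,
                                            "syn-miR-05-3p" = 0.15,
                                            "syn-miR-08-5p" = 2.90,
                                            "syn-miR-11-3p" = 0.49,
                                            "syn-miR-13-5p" = 9.04),
                         arm_switch = list("syn-mir-02" = list(
                           normal = c(233, 341), tumor = c(317, 91))),
                         arm_share_range = c(0.2, 0.8),
                         paralog_copies = 0L,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         n_ref_seqs = c(mRNA = 12, tRNA = 8, rRNA = 8,
                                        snoRNA = 8, scaRNA = 4, snRNA = 6,
                                        "other ncRNA" = 15, "repeat" = 3),
                         ref_seq_len = 300L,
                         n_windows = c(mRNA = 50, tRNA = 20, rRNA = 20,
                                       snoRNA = 20, scaRNA = 5, snRNA = 10,
                                       "other ncRNA" = 80, "repeat" = 3),
                         n_unknown = 200L) {
  stopifnot(abs(sum(shift5_law) - 1) < 1e-9, abs(sum(shift3_law) - 1) < 1e-9,
            abs(sum(tail_law) - 1) < 1e-9,
            all(abs(rowSums(class_props) - 1) < 1e-9))
  if (hairpin_len_range[1] < 2 * (mature_len + 16) + 2) {
    stop("hairpin_len_range too short for two ", mature_len, "-nt arms")
  }
  cfg <- list(seed = as.integer(seed), n_hairpins = as.integer(n_hairpins),
              hairpin_len_range = as.integer(hairpin_len_range),
              mature_len = as.integer(mature_len), n_reads = n_reads,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              single_arm_frac = single_arm_frac, shift5_law = shift5_law,
              shift3_law = shift3_law, tailing_prob = tailing_prob,
              tail_law = tail_law, class_props = class_props,
              de_multipliers = de_multipliers, arm_switch = arm_switch,
              arm_share_range = arm_share_range,
              paralog_copies = as.integer(paralog_copies),
              adapter = normalize_rna(adapter), n_ref_seqs = n_ref_seqs,
              ref_seq_len = as.integer(ref_seq_len), n_windows = n_windows,
              n_unknown = as.integer(n_unknown))
  structure(cfg, class = "synth_config")
}

# Random RNA string.
.rand_rna <- function(len) {
  paste(sample(.RNA_LETTERS, len, replace = TRUE), collapse = "")
}

.all_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# Rejection sampler: a sequence with no occurrence of `forbidden` (adapter
# probe prefix) and no k-mer already registered in `env` (so the >= 18-nt
# exact mapper has unique hits). Registers the accepted k-mers.
.sample_clean_seq <- function(len, env, forbidden, k = 18L, register = TRUE,
                              max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    s <- .rand_rna(len)
    if (grepl(forbidden, s, fixed = TRUE)) next
    km <- .all_kmers(s, k)
    if (anyDuplicated(km)) next
    if (any(vapply(km, function(x) !is.null(env[[x]]), logical(1)))) next
    if (register) for (x in km) env[[x]] <- TRUE
    return(s)
  }
  stop("could not sample a clean sequence of length ", len,
       " (infeasible constraints)")
}

#' Generate the synthetic reference side of a study
#'
#' Hairpins (no repeated 18-mer within the set, so exact mapping is
#' unambiguous unless paralogs are requested), mature annotations (both arms;
#' a fraction annotated 5p-only), per-class contaminant reference sets,
#' contaminant/unknown read pools, and study-level expression parameters.
#' Deterministic for a fixed config.
#'
#' @param config a [synth_config()].
#' @return list with `hairpins`, `annotations` (annotated arms only),
#'   `loci` (all arms, with `annotated` flag), `reference_sets`, `pools`,
#'   `unknown_pool`, `expression`, `config`.
#' @export
generate_references <- function(config) {
  set.seed(config$seed)
  n <- config$n_hairpins
  ml <- config$mature_len
  probe <- substr(config$adapter, 1L, 5L)
  env <- new.env(hash = TRUE, parent = emptyenv())

  lens <- sample(seq(config$hairpin_len_range[1], config$hairpin_len_range[2]),
                 n, replace = TRUE)
  ids <- sprintf("syn-mir-%02d", seq_len(n))
  seqs <- vapply(lens, .sample_clean_seq, character(1), env = env,
                 forbidden = probe)
  hairpins <- as_hairpin_set(ids, seqs)

  # both-arm latent loci; 5p starts at 16, 3p ends 15 nt from the 3' terminus
  loci <- rbind(
    data.frame(hairpin_id = ids, mature_name = sprintf("syn-miR-%02d-5p",
                                                       seq_len(n)),
               arm = "5p", start = 16L, end = 16L + ml - 1L,
               stringsAsFactors = FALSE),
    data.frame(hairpin_id = ids, mature_name = sprintf("syn-miR-%02d-3p",
                                                       seq_len(n)),
               arm = "3p", start = lens - 15L - ml + 1L, end = lens - 15L,
               stringsAsFactors = FALSE)
  )
  n_single <- ceiling(config$single_arm_frac * n)
  single_ids <- if (n_single > 0) ids[(n - n_single + 1L):n] else character()
  loci$annotated <- !(loci$arm == "3p" & loci$hairpin_id %in% single_ids)
  annotations <- validate_annotations(
    loci[loci$annotated, c("hairpin_id", "mature_name", "arm", "start", "end")],
    hairpins)

  if (config$paralog_copies > 0L) {
    # identical copies of hairpin 1 sharing its mature names: multi-mapping
    pids <- sprintf("%s-p%d", ids[1], seq_len(config$paralog_copies) + 1L)
    hairpins <- rbind(hairpins, as_hairpin_set(pids, rep(seqs[1],
                                                         length(pids))))
    extra <- annotations[annotations$hairpin_id == ids[1], , drop = FALSE]
    for (pid in pids) {
      e <- extra
      e$hairpin_id <- pid
      annotations <- rbind(annotations, e)
    }
  }

  reference_sets <- lapply(setNames(nm = cascade_classes()), function(cls) {
    k <- config$n_ref_seqs[[cls]]
    setNames(vapply(rep(config$ref_seq_len, k), .sample_clean_seq,
                    character(1), env = env, forbidden = probe),
             sprintf("%s_ref_%02d", gsub(" ", "_", cls), seq_len(k)))
  })

  pools <- lapply(setNames(nm = cascade_classes()), function(cls) {
    refs <- reference_sets[[cls]]
    k <- config$n_windows[[cls]]
    wl <- sample(20:24, k, replace = TRUE)
    ri <- sample(length(refs), k, replace = TRUE)
    off <- vapply(seq_len(k), function(i) {
      sample.int(nchar(refs[ri[i]]) - wl[i] + 1L, 1L)
    }, integer(1))
    substring(refs[ri], off, off + wl - 1L)
  })

  # unknown pool: random reads matching no hairpin and no reference class
  unknown_pool <- character(0)
  while (length(unknown_pool) < config$n_unknown) {
    need <- config$n_unknown - length(unknown_pool)
    cand <- vapply(sample(20:24, need, replace = TRUE), .sample_clean_seq,
                   character(1), env = env, forbidden = probe,
                   register = FALSE)
    asg <- classify_reads(data.frame(seq = cand, count = 1L,
                                     library = "pool",
                                     stringsAsFactors = FALSE),
                          reference_sets)
    unknown_pool <- c(unknown_pool, cand[asg$class_label == "unknown"])
  }

  # study-level expression: designated-effect hairpins get fixed abundance
  # shares (the validated differentially expressed miRNAs of deep studies
  # are abundant ones; keeping strongly up-regulated miRNAs at moderate
  # abundance also keeps the tumor library's miRNA mass near observed
  # levels), the background gets log-normal shares of the remaining mass.
  de <- config$de_multipliers
  de_hair <- if (length(de)) {
    setNames(sub("-(5p|3p)$", "", chartr("R", "r", names(de))), names(de))
  } else setNames(character(), character())
  if (length(de) && !all(de_hair %in% ids)) {
    stop("de_multipliers must name matures of hairpins in the reference")
  }
  fixed <- setNames(numeric(), character())
  for (mn in names(de_hair)) {
    m <- de[[mn]]
    fixed[de_hair[[mn]]] <- if (m < 1) 0.18 else if (m > 4) 0.02 else 0.05
  }
  for (hid in setdiff(names(config$arm_switch), names(fixed))) {
    fixed[hid] <- 0.08
  }
  if (sum(fixed) >= 0.95) stop("designated-effect hairpin shares exhaust the library")
  w <- setNames(rep(NA_real_, n), ids)
  w[names(fixed)] <- fixed
  rest <- setdiff(ids, names(fixed))
  draw <- rlnorm(length(rest), config$expression_meanlog,
                 config$expression_sdlog)
  w[rest] <- (1 - sum(fixed)) * draw / sum(draw)
  share5 <- runif(n, config$arm_share_range[1], config$arm_share_range[2])
  names(share5) <- ids
  # the differential arm gets the larger share of its hairpin
  for (mn in names(de_hair)) {
    share5[de_hair[mn]] <- if (grepl("-5p$", mn)) 0.7 else 0.3
  }
  shares <- list(normal = share5, tumor = share5)
  for (hid in names(config$arm_switch)) {
    if (!hid %in% ids) stop("arm_switch hairpin not in reference: ", hid)
    for (lib in c("normal", "tumor")) {
      cts <- config$arm_switch[[hid]][[lib]]
      shares[[lib]][hid] <- cts[1] / sum(cts)
    }
  }
  list(hairpins = hairpins, annotations = annotations, loci = loci,
       reference_sets = reference_sets, pools = pools,
       unknown_pool = unknown_pool,
       expression = list(hairpin_weights = w / sum(w), arm_shares = shares),
       config = config)
}

# Mature-level sampling weights for one library (named by truth mature name).
.mature_weights <- function(refs, library, multipliers = NULL) {
  w <- refs$expression$hairpin_weights
  sh <- refs$expression$arm_shares[[library]]
  loci <- refs$loci
  u <- ifelse(loci$arm == "5p", w[loci$hairpin_id] * sh[loci$hairpin_id],
              w[loci$hairpin_id] * (1 - sh[loci$hairpin_id]))
  u <- setNames(as.numeric(u), loci$mature_name)
  if (!is.null(multipliers)) {
    miss <- setdiff(names(multipliers), names(u))
    if (length(miss)) stop("de_multipliers name(s) not in reference: ",
                           paste(miss, collapse = ", "))
    u[names(multipliers)] <- u[names(multipliers)] * multipliers
  }
  u
}

# Draw tail categories/suffixes for tailed reads; "other" tails are
# dinucleotides outside the enumerated categories.
.draw_tails <- function(k, tail_law) {
  cat <- sample(names(tail_law), k, replace = TRUE, prob = tail_law)
  suff <- ifelse(cat == "other", sample(.OTHER_TAILS, k, replace = TRUE), cat)
  list(cat = cat, suffix = suff)
}

#' Generate one synthetic read library with its truth table
#'
#' Per-read generative model: a class is drawn from the library's class
#' proportions; miRNA reads are hairpin windows displaced by draws from the
#' 5'/3' shift laws, tailed with the library's tailing probability (first
#' tail base constrained to differ from the next templated base, so the
#' mapper provably sees the whole tail); contaminant and unknown reads are
#' drawn from fixed pools. Every read gets the adapter appended and is
#' verified to trim back exactly to its insert.
#'
#' @param refs output of [generate_references()].
#' @param library `"normal"` or `"tumor"`.
#' @param weights optional mature-level sampling weights (default: the
#'   study's expression law for this library).
#' @param class_probs optional class-proportion vector (default: the
#'   config's row for this library).
#' @param n_reads optional override of the config read number.
#' @return list with `reads` (named character vector, adapter included, U
#'   alphabet) and `truth` (one row per read).
#' @export
generate_library <- function(refs, library = c("normal", "tumor"),
                             weights = NULL, class_probs = NULL,
                             n_reads = NULL) {
  library <- match.arg(library)
  config <- refs$config
  set.seed(config$seed + 1000L * match(library, c("normal", "tumor")))
  if (is.null(n_reads)) n_reads <- config$n_reads
  if (is.null(class_probs)) class_probs <- config$class_props[library, ]
  if (is.null(weights)) weights <- .mature_weights(refs, library)
  classes <- c("miRNA", cascade_classes(), "unknown")
  n_by_class <- setNames(as.vector(rmultinom(1, n_reads, class_probs[classes])),
                         classes)

  loci <- refs$loci
  hseq <- setNames(refs$hairpins$seq, refs$hairpins$id)

  # --- miRNA reads ---
  k <- n_by_class[["miRNA"]]
  midx <- sample(nrow(loci), k, replace = TRUE,
                 prob = weights[loci$mature_name])
  s5 <- sample(as.integer(names(config$shift5_law)), k, replace = TRUE,
               prob = config$shift5_law)
  s3 <- sample(as.integer(names(config$shift3_law)), k, replace = TRUE,
               prob = config$shift3_law)
  tailed <- runif(k) < config$tailing_prob[[library]]
  tail_cat <- rep("none", k)
  tail_suffix <- rep("", k)
  if (any(tailed)) {
    d <- .draw_tails(sum(tailed), config$tail_law)
    tail_cat[tailed] <- d$cat
    tail_suffix[tailed] <- d$suffix
  }
  read_start <- loci$start[midx] + s5
  read_end <- loci$end[midx] + s3
  hs <- hseq[loci$hairpin_id[midx]]
  insert <- substr(hs, read_start, read_end)
  next_base <- substr(hs, read_end + 1L, read_end + 1L)
  # first tail base must differ from the next templated base
  for (it in seq_len(200L)) {
    bad <- tailed & substr(tail_suffix, 1L, 1L) == next_base
    if (!any(bad)) break
    d <- .draw_tails(sum(bad), config$tail_law)
    tail_cat[bad] <- d$cat
    tail_suffix[bad] <- d$suffix
  }
  mirna_insert <- paste0(insert, tail_suffix)
  # adapter-junction verification: redraw tails for the rare read whose
  # insert+tail suffix recreates the trimming probe across the junction
  for (it in seq_len(200L)) {
    trimmed <- trim_adapter(paste0(mirna_insert, config$adapter),
                            config$adapter, 6L)
    bad <- is.na(trimmed) | trimmed != mirna_insert
    if (!any(bad)) break
    if (any(bad & !tailed)) stop("internal: untailed read failed trim check")
    d <- .draw_tails(sum(bad), config$tail_law)
    tail_cat[bad] <- d$cat
    tail_suffix[bad] <- d$suffix
    redo <- bad & substr(tail_suffix, 1L, 1L) == next_base
    while (any(redo)) {
      d <- .draw_tails(sum(redo), config$tail_law)
      tail_cat[redo] <- d$cat
      tail_suffix[redo] <- d$suffix
      redo <- bad & substr(tail_suffix, 1L, 1L) == next_base
    }
    mirna_insert <- paste0(insert, tail_suffix)
  }

  mirna_truth <- data.frame(
    class = "miRNA", mature_name = loci$mature_name[midx],
    hairpin_id = loci$hairpin_id[midx], arm = loci$arm[midx],
    shift5 = s5, shift3 = s3, tail = tail_suffix, tail_category = tail_cat,
    insert = mirna_insert, stringsAsFactors = FALSE)

  # --- contaminant and unknown reads ---
  other_truth <- lapply(c(cascade_classes(), "unknown"), function(cls) {
    kk <- n_by_class[[cls]]
    if (kk == 0L) return(NULL)
    pool <- if (cls == "unknown") refs$unknown_pool else refs$pools[[cls]]
    data.frame(class = cls, mature_name = NA_character_,
               hairpin_id = NA_character_, arm = NA_character_,
               shift5 = NA_integer_, shift3 = NA_integer_,
               tail = NA_character_, tail_category = NA_character_,
               insert = sample(pool, kk, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  truth <- rbind(mirna_truth, do.call(rbind, other_truth))
  truth$library <- library
  truth$read_id <- sprintf("%s_%07d", library, seq_len(nrow(truth)))
  reads <- setNames(paste0(truth$insert, config$adapter), truth$read_id)
  list(reads = reads, truth = truth)
}

#' Generate a paired normal/tumor synthetic study
#'
#' Shared references; the tumor library re-weights designated mature miRNAs
#' by the configured fold-change multipliers and applies the per-library arm
#' shares of arm-switch hairpins. The excess/deficit miRNA mass created by
#' the multipliers is absorbed into the tumor miRNA class share (contaminant
#' classes rescaled to fill), so the expected whole-library TPM fold change
#' of a designated miRNA equals its configured multiplier exactly.
#'
#' @param config a [synth_config()].
#' @return list with `refs`, `libraries` (normal/tumor read+truth lists) and
#'   `expected` (per-mature expected fc; per-hairpin expected 5p shares per
#'   library).
#' @export
generate_paired_study <- function(config) {
  refs <- generate_references(config)
  u_n_raw <- .mature_weights(refs, "normal")
  u_n <- u_n_raw / sum(u_n_raw)
  # tumor raw weights normalized against the *normal* total, so that
  # u_t_raw / u_n is exactly the intended per-mature multiplier
  u_t_raw <- .mature_weights(refs, "tumor",
                             multipliers = config$de_multipliers) / sum(u_n_raw)
  Z <- sum(u_t_raw)
  P <- config$class_props["normal", "miRNA"]
  if (P * Z >= 1) stop("fold-change multipliers leave no non-miRNA mass")
  probs_n <- config$class_props["normal", ]
  probs_t <- probs_n * (1 - P * Z) / (1 - P)
  probs_t["miRNA"] <- P * Z
  normal <- generate_library(refs, "normal", weights = u_n,
                             class_probs = probs_n)
  tumor <- generate_library(refs, "tumor", weights = u_t_raw / Z,
                            class_probs = probs_t)
  expected_fc <- u_t_raw / u_n
  list(refs = refs,
       libraries = list(normal = normal, tumor = tumor),
       expected = list(fc = expected_fc,
                       arm_shares = refs$expression$arm_shares,
                       class_probs = list(normal = probs_n, tumor = probs_t)))
}

#' Write a synthetic study to disk
#'
#' Emits per-library FASTQ (DNA alphabet, constant dummy qualities),
#' hairpin FASTA, annotation TSV, per-class reference FASTAs, the truth
#' table TSV, and an echo of the resolved configuration as key=value text.
#'
#' @param study output of [generate_paired_study()].
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (lib in names(study$libraries)) {
    p <- file.path(dir, paste0(lib, ".fastq"))
    dna <- Biostrings::DNAStringSet(chartr("U", "T", study$libraries[[lib]]$reads))
    Biostrings::writeXStringSet(dna, p, format = "fastq")
    paths[paste0("fastq_", lib)] <- p
  }
  paths["hairpins"] <- file.path(dir, "hairpins.fa")
  write_hairpin_fasta(study$refs$hairpins, paths["hairpins"])
  paths["annotations"] <- file.path(dir, "annotations.tsv")
  write.table(study$refs$annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cls in names(study$refs$reference_sets)) {
    p <- file.path(dir, paste0("ref_", gsub(" ", "_", cls), ".fa"))
    set <- Biostrings::BStringSet(study$refs$reference_sets[[cls]])
    Biostrings::writeXStringSet(set, p, width = 80L)
    paths[paste0("ref_", cls)] <- p
  }
  paths["truth"] <- file.path(dir, "truth.tsv")
  truth <- do.call(rbind, lapply(study$libraries, `[[`, "truth"))
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["config"] <- file.path(dir, "config.txt")
  cfg <- study$refs$config
  writeLines(vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(deparse(cfg[[k]]), collapse = " "))
  }, character(1)), paths["config"])
  invisible(paths)
}
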