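# In-code fixtures shared across tests.

rna_letters <- c("A", "C", "G", "U")

rand_rna <- function(len) paste(sample(rna_letters, len, replace = TRUE),
                                collapse = "")

# A deterministic 87-nt hairpin with a known mature span at 16..36 (5p arm),
# mirroring the classic single-5p-arm annotation case.
fixture_hairpin <- function() {
  set.seed(511)
  data.frame(id = "mir-fix-1", seq = rand_rna(87), length = 87L,
             stringsAsFactors = FALSE)
}

fixture_annotation <- function(hairpins = fixture_hairpin()) {
  data.frame(hairpin_id = hairpins$id[1], mature_name = "miR-fix-1-5p",
             arm = "5p", start = 16L, end = 36L, stringsAsFactors = FALSE)
}

# Random hairpin set for property tests (no constraints: the oracle and the
# implementation must agree on arbitrary sequences, including repeats).
random_hairpin_set <- function(n = NULL, len_range = c(40L, 200L)) {
  if (is.null(n)) n <- sample(1:6, 1)
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(id = paste0("h", seq_len(n)),
             seq = vapply(lens, rand_rna, character(1)),
             length = lens, stringsAsFactors = FALSE)
}

# Small synthetic-study configuration for fast end-to-end tests.
tiny_config <- function(seed = 1L, n_reads = 4000, ...) {
  synth_config(seed = seed, n_hairpins = 6L, n_reads = n_reads,
               de_multipliers = c("syn-miR-02-5p" = 4),
               arm_switch = list("syn-mir-03" = list(normal = c(3, 1),
                                                     tumor = c(1, 3))),
               single_arm_frac = 1 / 6,
               n_ref_seqs = c(mRNA = 3, tRNA = 2, rRNA = 2, snoRNA = 2,
                              scaRNA = 2, snRNA = 2, "other ncRNA" = 3,
                              "repeat" = 2),
               n_windows = c(mRNA = 8, tRNA = 5, rRNA = 5, snoRNA = 5,
                             scaRNA = 3, snRNA = 3, "other ncRNA" = 10,
                             "repeat" = 2),
               n_unknown = 30L, ...)
}

write_temp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
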