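# Helper: run alignments of the fixture hairpin through classification.
classify_fixture <- function(starts, lens, counts, suffixes = NULL,
                             shift_window = 5L) {
  hp <- fixture_hairpin()
  ann <- fixture_annotation(hp)
  if (is.null(suffixes)) suffixes <- rep("", length(starts))
  aln <- data.frame(
    read_seq = paste0(substr(hp$seq, starts, starts + lens - 1L), suffixes),
    count = counts, hairpin_id = hp$id, start = starts, match_len = lens,
    mod_suffix = suffixes, weight = 1, library = "normal",
    stringsAsFactors = FALSE)
  classify_isomirs(aln, ann, hp, shift_window = shift_window)
}

test_that("position shifts follow the annotated-coordinate convention", {
  # annotation spans 16..36; an alignment at 16 of length 21 is the reference
  rec <- classify_fixture(16L, 21L, 10L)
  expect_equal(rec$shift5, 0L)
  expect_equal(rec$shift3, 0L)
  expect_equal(rec$mod_category, "none")
  expect_equal(rec$status, "annotated")

  rec2 <- classify_fixture(17L, 19L, 5L)
  expect_equal(rec2$shift5, 1L)
  expect_equal(rec2$shift3, -1L)

  # the 3' shift is computed on the matched end, before the tail
  rec3 <- classify_fixture(16L, 21L, 5L, suffixes = "AU")
  expect_equal(rec3$shift3, 0L)
  expect_equal(rec3$mod_category, "AU")
})

test_that("alignments on an unannotated arm become opposite-arm loci", {
  # fixture hairpin is annotated 5p-only; a 3p-half alignment is opposite-arm
  rec <- classify_fixture(c(16L, 60L, 61L), c(21L, 21L, 21L),
                          c(10L, 8L, 2L))
  opp <- rec[rec$opposite_arm, ]
  expect_equal(nrow(opp), 2L)
  expect_true(all(opp$mature_name == "mir-fix-1-3p-novel"))
  expect_true(all(opp$arm == "3p"))
  # provisional coordinates sit at the modal (highest-count) alignment
  expect_equal(opp$shift5[opp$count == 8], 0L)
  expect_equal(opp$shift5[opp$count == 2], 1L)
})

test_that("alignments outside the shift window are reported unassigned", {
  hp <- fixture_hairpin()
  rec <- classify_fixture(c(16L, 26L), c(21L, 21L), c(5L, 3L))
  expect_equal(sort(rec$status), c("annotated", "unassigned"))
  expect_true(is.na(rec$mature_name[rec$status == "unassigned"]))
  # unassigned rows are excluded from shift summaries
  expect_equal(unname(summarize_shifts(rec, "5p")), 1)
})

test_that("3' modification categories follow the enumerated vocabulary", {
  expect_equal(classify_modification(c("A", "U", "AA", "UU", "AU", "C", "G")),
               c("A", "U", "AA", "UU", "AU", "C", "G"))
  expect_equal(classify_modification(""), "none")
  expect_equal(classify_modification(c("AGC", "UUU", "GA")),
               c("other", "other", "other"))
})

test_that("shift distributions are count-weighted fractions summing to one", {
  rec <- classify_fixture(c(16L, 15L, 17L), c(21L, 22L, 20L),
                          c(95L, 1L, 4L))
  d5 <- summarize_shifts(rec, "5p")
  expect_equal(d5, c("-1" = 0.01, "0" = 0.95, "1" = 0.04))
  expect_equal(sum(d5), 1, tolerance = 1e-9)

  one <- classify_fixture(16L, 21L, 7L)
  expect_equal(summarize_shifts(one, "5p"), c("0" = 1))
  expect_error(summarize_shifts(one[0, ], "5p"), "no assigned")
})

test_that("modification profiles report the modified fraction", {
  rec <- classify_fixture(rep(16L, 3), rep(21L, 3), c(88L, 8L, 4L),
                          suffixes = c("", "A", "U"))
  prof <- modification_profile(rec)
  expect_equal(prof$modified_fraction, 0.12)
  expect_equal(sum(prof$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(prof$fractions["A"]), 0.08)

  clean <- classify_fixture(16L, 21L, 10L)
  expect_equal(modification_profile(clean)$modified_fraction, 0)
})

test_that("per-miRNA aggregation conserves counts and flags the top isoform", {
  rec <- classify_fixture(c(16L, 16L), c(21L, 20L), c(10L, 5L))
  agg <- aggregate_mirna(rec)
  expect_equal(agg$count, 15)
  expect_true(agg$ref_most_abundant)

  rec2 <- classify_fixture(c(16L, 17L), c(21L, 21L), c(3L, 9L))
  expect_false(aggregate_mirna(rec2)$ref_most_abundant)

  expect_equal(nrow(aggregate_mirna(rec2[0, ])), 0L)
  # conservation
  expect_equal(sum(aggregate_mirna(rec)$count), sum(rec$count))
})

test_that("reads of one paralog family are counted once per mature name", {
  hp <- fixture_hairpin()
  hp2 <- rbind(hp, transform(hp, id = "mir-fix-1-p2"))
  ann <- rbind(fixture_annotation(hp),
               transform(fixture_annotation(hp), hairpin_id = "mir-fix-1-p2"))
  ann$mature_name <- "miR-fix-1-5p"  # same product from both copies
  idx <- build_hairpin_index(hp2)
  reads <- data.frame(seq = substr(hp$seq, 16, 36), count = 6L,
                      library = "normal", stringsAsFactors = FALSE)
  mp <- map_library(reads, idx)
  expect_equal(nrow(mp$alignments), 2L)
  rec <- classify_isomirs(mp$alignments, ann, hp2)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$count, 6)  # full count once, not double
})

test_that("unmutated mature reads return the identity isomiR", {
  cfg <- tiny_config(seed = 5)
  refs <- generate_references(cfg)
  idx <- build_hairpin_index(refs$hairpins)
  ann <- refs$annotations
  for (i in seq_len(nrow(ann))) {
    h <- refs$hairpins$seq[refs$hairpins$id == ann$hairpin_id[i]]
    read <- substr(h, ann$start[i], ann$end[i])
    aln <- map_read(read, idx)
    aln$read_seq <- read
    aln$count <- 2L
    aln$library <- "normal"
    rec <- classify_isomirs(aln, ann, refs$hairpins)
    expect_equal(rec$mature_name, ann$mature_name[i])
    expect_equal(rec$shift5, 0L)
    expect_equal(rec$shift3, 0L)
    expect_equal(rec$mod_category, "none")
  }
})

test_that("the hairpin stack report renders matched bases and lowercase tails", {
  rec <- classify_fixture(c(16L, 16L), c(21L, 21L), c(9L, 3L),
                          suffixes = c("", "AU"))
  hp <- fixture_hairpin()
  lines <- format_hairpin_stack(rec, hp$id, hp)
  expect_equal(lines[1], paste0(">", hp$id))
  expect_equal(lines[2], hp$seq)
  expect_match(lines[4], "au", fixed = TRUE)
  expect_match(lines[3], "\\(\\+0,\\+0\\)")
})
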