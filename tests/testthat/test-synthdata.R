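test_that("reference generation satisfies its structural invariants", {
  cfg <- tiny_config(seed = 3)
  refs <- generate_references(cfg)
  hp <- refs$hairpins
  expect_equal(nrow(hp), cfg$n_hairpins)
  expect_true(all(hp$length >= cfg$hairpin_len_range[1] &
                    hp$length <= cfg$hairpin_len_range[2]))
  # no repeated 18-mer across the hairpin set
  kmers <- unlist(lapply(hp$seq, function(s) {
    starts <- seq_len(nchar(s) - 17L)
    substring(s, starts, starts + 17L)
  }))
  expect_false(anyDuplicated(kmers) > 0)
  # one single-arm hairpin: 2n - 1 annotations, both-arm loci in truth
  expect_equal(nrow(refs$annotations), 2L * cfg$n_hairpins - 1L)
  expect_equal(nrow(refs$loci), 2L * cfg$n_hairpins)
  expect_equal(sum(!refs$loci$annotated), 1L)
  # mature spans are valid annotations with the configured length
  expect_true(all(refs$annotations$end - refs$annotations$start + 1L ==
                    cfg$mature_len))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 11, n_reads = 1500)
  s1 <- generate_paired_study(cfg)
  s2 <- generate_paired_study(cfg)
  expect_identical(s1$libraries$normal$reads, s2$libraries$normal$reads)
  expect_identical(s1$libraries$tumor$truth, s2$libraries$tumor$truth)
  expect_identical(s1$refs$hairpins, s2$refs$hairpins)

  d1 <- file.path(tempdir(), "study1")
  d2 <- file.path(tempdir(), "study2")
  write_study(s1, d1)
  write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every emitted read has exactly one truth row that reconstructs it", {
  cfg <- tiny_config(seed = 21, n_reads = 2000)
  lib <- generate_library(generate_references(cfg), "normal")
  expect_equal(length(lib$reads), 2000L)
  expect_equal(nrow(lib$truth), 2000L)
  expect_false(anyDuplicated(lib$truth$read_id) > 0)
  expect_identical(names(lib$reads), lib$truth$read_id)
  expect_identical(unname(lib$reads), paste0(lib$truth$insert, cfg$adapter))
  # adapter trimming recovers every insert exactly
  trimmed <- trim_adapter(lib$reads, cfg$adapter)
  expect_identical(unname(trimmed), lib$truth$insert)
})

test_that("miRNA truth rows reconstruct from hairpin coordinates and tails", {
  cfg <- tiny_config(seed = 33, n_reads = 2000)
  refs <- generate_references(cfg)
  lib <- generate_library(refs, "normal")
  tr <- lib$truth[lib$truth$class == "miRNA", ]
  hseq <- setNames(refs$hairpins$seq, refs$hairpins$id)
  loci <- refs$loci
  key <- match(tr$mature_name, loci$mature_name)
  windows <- substr(hseq[tr$hairpin_id], loci$start[key] + tr$shift5,
                    loci$end[key] + tr$shift3)
  expect_identical(unname(paste0(windows, tr$tail)), tr$insert)
  # first tail base never equals the next templated base
  tailed <- tr$tail != ""
  nxt <- substr(hseq[tr$hairpin_id[tailed]],
                loci$end[key][tailed] + tr$shift3[tailed] + 1L,
                loci$end[key][tailed] + tr$shift3[tailed] + 1L)
  expect_true(all(substr(tr$tail[tailed], 1, 1) != nxt))
})

test_that("degenerate laws produce degenerate libraries", {
  cfg0 <- tiny_config(seed = 41, n_reads = 800,
                      tailing_prob = c(normal = 0, tumor = 0),
                      shift5_law = c("0" = 1), shift3_law = c("0" = 1))
  refs <- generate_references(cfg0)
  lib <- generate_library(refs, "normal")
  tr <- lib$truth[lib$truth$class == "miRNA", ]
  expect_true(all(tr$tail == ""))
  expect_true(all(tr$shift5 == 0L & tr$shift3 == 0L))
  # every miRNA read is exactly an annotated-locus mature sequence
  hseq <- setNames(refs$hairpins$seq, refs$hairpins$id)
  key <- match(tr$mature_name, refs$loci$mature_name)
  expect_identical(unname(substr(hseq[tr$hairpin_id], refs$loci$start[key],
                                 refs$loci$end[key])), tr$insert)
})

test_that("sampled class proportions track the configured law", {
  cfg <- tiny_config(seed = 55, n_reads = 20000)
  lib <- generate_library(generate_references(cfg), "normal")
  frac <- table(lib$truth$class) / nrow(lib$truth)
  want <- cfg$class_props["normal", ]
  for (cls in names(want)) {
    got <- if (cls %in% names(frac)) frac[[cls]] else 0
    expect_lt(abs(got - want[[cls]]), 0.02)
  }
})

test_that("paired studies encode the configured effects in expectation", {
  cfg <- tiny_config(seed = 61, n_reads = 1000)
  st <- generate_paired_study(cfg)
  expect_equal(unname(st$expected$fc["syn-miR-02-5p"]), 4)
  # non-designated matures are balanced
  others <- setdiff(names(st$expected$fc),
                    c("syn-miR-02-5p", "syn-miR-03-5p", "syn-miR-03-3p"))
  expect_true(all(abs(st$expected$fc[others] - 1) < 1e-9))
  # arm-switch hairpin flips its 5p share between libraries
  expect_equal(unname(st$expected$arm_shares$normal["syn-mir-03"]), 0.75)
  expect_equal(unname(st$expected$arm_shares$tumor["syn-mir-03"]), 0.25)
})
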