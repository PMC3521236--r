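test_that("exact reads map with no tail; tailed reads recover their suffix", {
  hp <- fixture_hairpin()
  idx <- build_hairpin_index(hp)

  r1 <- substr(hp$seq, 5, 26)  # 22-nt perfect window
  a1 <- map_read(r1, idx)
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$start, 5L)
  expect_equal(a1$match_len, 22L)
  expect_equal(a1$mod_suffix, "")

  # 20-nt perfect prefix plus a 2-nt nontemplate tail
  tail1 <- setdiff(rna_letters, substr(hp$seq, 25, 25))[1]
  r2 <- paste0(substr(hp$seq, 5, 24), tail1, tail1)
  a2 <- map_read(r2, idx)
  expect_equal(a2$match_len, 20L)
  expect_equal(a2$mod_suffix, paste0(tail1, tail1))
  # maximality: extending the match by one base would mismatch
  expect_false(substr(hp$seq, 25, 25) == tail1)

  # longest perfect prefix of 17 nt -> unmapped (18-nt floor)
  mismatch <- setdiff(rna_letters, substr(hp$seq, 22, 22))[1]
  r3 <- paste0(substr(hp$seq, 5, 21), mismatch, "ACGUA")
  expect_equal(nrow(map_read(r3, idx)), 0L)

  expect_error(map_read(substr(hp$seq, 1, 17), idx), "floor")
})

test_that("reads overhanging the hairpin 3' terminus put the overhang in the suffix", {
  hp <- fixture_hairpin()
  idx <- build_hairpin_index(hp)
  r <- paste0(substr(hp$seq, 68, 87), "ACG")
  a <- map_read(r, idx)
  expect_equal(a$start, 68L)
  expect_equal(a$match_len, 20L)
  expect_equal(a$mod_suffix, "ACG")
})

test_that("identical paralogs share the read with equal fractional weights", {
  hp <- fixture_hairpin()
  hp2 <- rbind(hp, transform(hp, id = "mir-fix-1-p2"))
  idx <- build_hairpin_index(hp2)
  a <- map_read(substr(hp$seq, 5, 26), idx)
  expect_equal(nrow(a), 2L)
  expect_equal(a$weight, c(0.5, 0.5))
  expect_equal(sum(a$weight), 1)
  expect_setequal(a$hairpin_id, hp2$id)
})

test_that("an empty hairpin set maps nothing", {
  idx <- build_hairpin_index(fixture_hairpin()[0, ])
  expect_equal(nrow(map_read(strrep("ACGU", 5), idx)), 0L)
})

test_that("map_read agrees with the literal trim-and-retry oracle", {
  set.seed(1234)
  n_agree <- 0L
  for (i in 1:300) {
    hp <- random_hairpin_set()
    idx <- build_hairpin_index(hp)
    mode <- i %% 3L
    if (mode == 0L) {
      read <- rand_rna(sample(18:26, 1))       # arbitrary sequence
    } else {
      j <- sample(nrow(hp), 1)
      L <- sample(18:24, 1)
      s <- sample(hp$length[j] - L + 1L, 1)
      read <- substr(hp$seq[j], s, s + L - 1L)
      if (mode == 2L) read <- paste0(read, rand_rna(sample(1:4, 1)))
    }
    got <- map_read(read, idx)
    want <- brute_force_map(read, hp)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unique(got$match_len), want$match_len)
      expect_equal(unique(got$mod_suffix), want$mod_suffix)
      expect_setequal(paste(got$hairpin_id, got$start),
                      paste(want$hairpin_id, want$start))
      expect_equal(sum(got$weight), 1)
      # no-mismatch guarantee on every reported alignment
      for (r in seq_len(nrow(got))) {
        h <- hp$seq[hp$id == got$hairpin_id[r]]
        expect_equal(substr(h, got$start[r],
                            got$start[r] + got$match_len[r] - 1L),
                     substr(read, 1, got$match_len[r]))
      }
      n_agree <- n_agree + 1L
    }
  }
  expect_gt(n_agree, 100L)  # plenty of mapped instances exercised
})

test_that("map_library partitions a library and conserves counts", {
  hp <- fixture_hairpin()
  idx <- build_hairpin_index(hp)
  reads <- data.frame(
    seq = c(substr(hp$seq, 5, 26), substr(hp$seq, 16, 36), strrep("ACGU", 6)),
    count = c(10L, 5L, 3L), library = "normal", stringsAsFactors = FALSE)
  mp <- map_library(reads, idx)
  expect_equal(nrow(mp$unmapped), 1L)
  mapped_counts <- sum(reads$count) - sum(mp$unmapped$count)
  expect_equal(mapped_counts, 15L)
  # per-read weighted counts sum back to the mapped total
  w <- tapply(mp$alignments$weight, mp$alignments$read_seq, sum)
  expect_true(all(abs(w - 1) < 1e-12))

  empty <- map_library(reads[0, ], idx)
  expect_equal(nrow(empty$alignments), 0L)
  expect_equal(nrow(empty$unmapped), 0L)
})
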