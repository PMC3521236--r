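make_sets <- function() {
  set.seed(77)
  list(mRNA = c(m1 = rand_rna(120)),
       tRNA = c(t1 = rand_rna(120)),
       rRNA = c(r1 = rand_rna(120)))
}

test_that("the cascade assigns first-match classes with 0 or 1 substitution", {
  sets <- make_sets()
  exact_t <- substr(sets$tRNA[[1]], 30, 51)
  one_off <- substitution_neighbors(substr(sets$rRNA[[1]], 10, 31))[1]
  nowhere <- strrep("ACGU", 6)
  reads <- data.frame(seq = c(exact_t, one_off, nowhere),
                      count = c(4L, 3L, 2L), library = "normal",
                      stringsAsFactors = FALSE)
  asg <- classify_reads(reads, sets)
  expect_equal(asg$class_label, c("tRNA", "rRNA", "unknown"))
  expect_equal(asg$mismatches, c(0L, 1L, NA_integer_))
})

test_that("an earlier class wins even with one mismatch over a later exact hit", {
  sets <- make_sets()
  q <- substr(sets$tRNA[[1]], 40, 61)
  # plant a 1-substitution copy of the tRNA window inside the mRNA reference
  sets$mRNA <- c(m1 = paste0(rand_rna(20), substitution_neighbors(q)[5],
                             rand_rna(20)))
  asg <- classify_reads(data.frame(seq = q, count = 1L, library = "x",
                                   stringsAsFactors = FALSE), sets)
  expect_equal(asg$class_label, "mRNA")
  expect_equal(asg$mismatches, 1L)
})

test_that("classification agrees with the substitution-neighborhood oracle", {
  set.seed(88)
  sets <- list(mRNA = c(a = rand_rna(150), b = rand_rna(150)),
               tRNA = c(a = rand_rna(150)),
               snoRNA = c(a = rand_rna(150)))
  reads <- character(60)
  for (i in seq_along(reads)) {
    mode <- i %% 4L
    if (mode == 0L) {
      reads[i] <- rand_rna(20)
    } else {
      ref <- sets[[sample(3, 1)]][[1]]
      s <- sample(130, 1)
      w <- substr(ref, s, s + 19L)
      reads[i] <- if (mode == 1L) w else
        sample(substitution_neighbors(w), 1)
    }
  }
  reads <- unique(reads)
  asg <- classify_reads(data.frame(seq = reads, count = 1L, library = "x",
                                   stringsAsFactors = FALSE), sets)
  for (i in seq_along(reads)) {
    want <- oracle_classify(reads[i], sets)
    expect_equal(asg$class_label[i], want$class)
    expect_equal(asg$mismatches[i], want$mismatches)
  }
})

test_that("category summaries form a complete partition summing to one", {
  sets <- make_sets()
  asg <- data.frame(seq = c("AAA", "CCC", "GGG"), count = c(10L, 5L, 5L),
                    class_label = c("tRNA", "rRNA", "unknown"),
                    mismatches = c(0L, 1L, NA), library = "x",
                    stringsAsFactors = FALSE)
  frac <- summarize_categories(asg, mirna_count = 80)
  expect_equal(sum(frac), 1, tolerance = 1e-9)
  expect_equal(unname(frac["miRNA"]), 0.8)
  expect_equal(unname(frac["tRNA"]), 0.1)
  expect_equal(length(frac), 10L)

  all_mirna <- summarize_categories(asg[0, ], mirna_count = 50)
  expect_equal(unname(all_mirna["miRNA"]), 1)

  expect_error(summarize_categories(asg[0, ], mirna_count = 0), "empty")
  dup <- rbind(asg, asg[1, ])
  expect_error(summarize_categories(dup, 10), "more than once")
})

test_that("permuting the cascade order moves reads but never loses them", {
  set.seed(99)
  sets <- list(mRNA = c(a = rand_rna(200)), tRNA = c(a = rand_rna(200)),
               rRNA = c(a = rand_rna(200)))
  reads <- data.frame(
    seq = unique(c(vapply(1:15, function(i) {
      ref <- sets[[sample(3, 1)]][[1]]
      s <- sample(180, 1)
      substr(ref, s, s + 19L)
    }, character(1)), replicate(5, rand_rna(20)))),
    count = 2L, library = "x", stringsAsFactors = FALSE)
  a1 <- classify_reads(reads, sets, order = c("mRNA", "tRNA", "rRNA"))
  a2 <- classify_reads(reads, sets, order = c("rRNA", "tRNA", "mRNA"))
  expect_equal(sum(a1$count), sum(a2$count))
  expect_equal(sort(a1$seq), sort(a2$seq))
  # known classes keep their reads under permutation (exact hits only move
  # between classes if a read matches several references)
  expect_equal(sum(a1$class_label == "unknown"),
               sum(a2$class_label == "unknown"))
})
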