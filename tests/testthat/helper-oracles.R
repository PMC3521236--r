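# Independent oracles, deliberately naive: they re-state the definitions
# rather than the implementations they check.

# Literal trim-one-3'-base-and-retry mapping: for decreasing prefix lengths
# down to the floor, search the prefix in every hairpin via gregexpr.
brute_force_map <- function(seq, hairpins, floor = 18L) {
  n <- nchar(seq)
  if (n < floor) stop("read below floor")
  for (L in seq(n, floor)) {
    prefix <- substr(seq, 1L, L)
    hits <- NULL
    for (j in seq_len(nrow(hairpins))) {
      p <- gregexpr(prefix, hairpins$seq[j], fixed = TRUE)[[1]]
      if (p[1] != -1L) {
        hits <- rbind(hits, cbind(j, as.integer(p)))
      }
    }
    if (!is.null(hits)) {
      return(list(match_len = L, mod_suffix = substr(seq, L + 1L, n),
                  hairpin_id = hairpins$id[hits[, 1]], start = hits[, 2]))
    }
  }
  NULL
}

# All single-substitution neighbors of a sequence.
substitution_neighbors <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(chars)) {
    for (b in setdiff(rna_letters, chars[i])) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Cascade oracle: exact substring search of the read and each of its
# single-substitution neighbors, class order respected.
oracle_classify <- function(seq, reference_sets, order = names(reference_sets)) {
  in_class <- function(q, refs) any(vapply(refs, function(r) {
    grepl(q, r, fixed = TRUE)
  }, logical(1)))
  for (cls in order) {
    refs <- reference_sets[[cls]]
    if (in_class(seq, refs)) return(list(class = cls, mismatches = 0L))
    for (nb in substitution_neighbors(seq)) {
      if (in_class(nb, refs)) return(list(class = cls, mismatches = 1L))
    }
  }
  list(class = "unknown", mismatches = NA_integer_)
}

# Closed-form hypergeometric upper tail by direct enumeration.
hypergeom_enum <- function(N, K, n, k) {
  if (k > min(K, n)) return(0)
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
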