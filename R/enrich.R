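# Hypergeometric pathway over-representation with Benjamini-Hochberg FDR.

#' Upper-tail hypergeometric test
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` pathway members when `n` targets are drawn from a universe of
#' `N` genes of which `K` are in the pathway. Computed on the survival
#' function for numerical stability.
#'
#' @param N universe size.
#' @param K pathway size within the universe.
#' @param n target-set size.
#' @param k observed overlap.
#' @return the p-value.
#' @export
hypergeom_test <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || any(c(N, K, n, k) < 0)) {
    stop("inconsistent hypergeometric sizes (need k <= min(K, n); K, n <= N)")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read pathway memberships from a GMT file
#'
#' @param path GMT path (tab-separated: id, description, genes...).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Read a newline-delimited gene list
#'
#' @param path text file with one gene symbol per line.
#' @return character vector (trimmed, empties dropped, unique).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Hypergeometric enrichment of a target-gene set over pathways
#'
#' The universe defaults to all genes appearing in at least one pathway,
#' optionally intersected with a user-supplied universe; targets and
#' pathways are intersected with the universe before testing. One upper-tail
#' test per pathway, Benjamini-Hochberg adjusted over all tested pathways.
#'
#' @param target_genes character vector (e.g. the union of per-miRNA target
#'   lists).
#' @param pathways named list of gene vectors (see [read_gmt()]).
#' @param universe optional gene universe.
#' @return data.frame `pathway_id`, `K`, `n`, `k`, `p`, `q`, sorted by `p`.
#' @export
enrich_targets <- function(target_genes, pathways, universe = NULL) {
  pool <- unique(unlist(pathways, use.names = FALSE))
  if (!is.null(universe)) pool <- intersect(pool, unique(universe))
  if (length(pool) == 0L) stop("empty gene universe")
  targets <- intersect(unique(target_genes), pool)
  N <- length(pool)
  n <- length(targets)
  K <- vapply(pathways, function(g) length(intersect(g, pool)), integer(1))
  k <- vapply(pathways, function(g) length(intersect(intersect(g, pool),
                                                     targets)), integer(1))
  p <- mapply(hypergeom_test, N = N, K = K, n = n, k = k)
  out <- data.frame(pathway_id = names(pathways), K = K, n = n, k = k, p = p,
                    q = p.adjust(p, method = "BH"), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$p, out$pathway_id), , drop = FALSE]
}
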