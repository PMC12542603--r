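#' Upper tail of the hypergeometric distribution
#'
#' `P[X >= k]` for X ~ hypergeometric: `k` query genes hit a term of size `K`
#' in a universe of size `N` from a query of size `n`. Evaluated in log space
#' for numerical stability. Vectorised over `k`/`K`/`n`.
#'
#' @param k Overlap count(s).
#' @param K Term size(s) within the universe.
#' @param n Query size(s) within the universe.
#' @param N Universe size.
#' @return Tail probability in (0, 1\].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(K < 0 | K > N) || any(n < 0 | n > N))
    abort("require 0 <= K, n <= N")
  if (any(k < 0 | k > pmin(K, n)))
    abort("require 0 <= k <= min(K, n)")
  p <- exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  pmin(1, p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values capped at 1, input order
#' preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene set collection
#'
#' Hypergeometric over-representation of a query gene list against each term
#' of a GMT-style collection, inside an explicit gene universe. All terms
#' with at least one universe gene are tested and Benjamini-Hochberg adjusted
#' together; records are emitted for terms overlapping the query (k >= 1) and
#' filtered by `p < p_cutoff` OR `adjusted p < padj_cutoff`. The enrichment
#' score is `-log10` of the adjusted p-value (sign flipped so larger means
#' more enriched).
#'
#' @param query Character vector of gene symbols (the marker list).
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of background symbols (typically the
#'   genes surviving [filter_rare_genes()]).
#' @param p_cutoff,padj_cutoff Result filters (defaults 0.01 and 0.05).
#' @param filter Apply the filters (default TRUE); `FALSE` returns all
#'   k >= 1 records.
#' @return Tibble: term, k, K, n, N, p_value, p_adjusted, enrichment_score,
#'   genes (overlap symbols, comma-separated), sorted by p.
#' @export
enrich <- function(query, sets, universe, p_cutoff = 0.01,
                   padj_cutoff = 0.05, filter = TRUE) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warn(sprintf("%d query gene(s) outside universe dropped", length(dropped)))
  }
  query <- intersect(query, universe)
  if (!length(query)) abort("no query genes inside the universe")
  N <- length(universe); n <- length(query)

  sets <- lapply(sets, function(g) intersect(unique(toupper(g)), universe))
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) abort("no gene set overlaps the universe")

  K <- lengths(sets)
  hits <- lapply(sets, intersect, query)
  k <- lengths(hits)
  p <- hypergeometric_tail(k, K, n, N)
  padj <- bh_adjust(p)

  out <- tibble(
    term = names(sets), k = unname(k), K = unname(K), n = n, N = N,
    p_value = unname(p), p_adjusted = unname(padj),
    enrichment_score = -log10(unname(padj)),
    genes = vapply(hits, paste, character(1), collapse = ",")
  )
  out <- dplyr::filter(out, .data$k >= 1L)
  if (filter) {
    out <- dplyr::filter(out, .data$p_value < p_cutoff |
                           .data$p_adjusted < padj_cutoff)
  }
  dplyr::arrange(out, .data$p_value)
}
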