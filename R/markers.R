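#' Marker selection criteria
#'
#' The three-criterion rule for calling a gene an upregulated marker of a
#' cluster: Wilcoxon rank-sum p below `p_threshold`, expressed (count > 0)
#' in at least `min_fraction` of in-cluster cells, and in-cluster mean at
#' least `min_fold` times the mean over all other clusters.
#'
#' @param p_threshold Rank-sum p cutoff (default 1e-6).
#' @param min_fraction Minimum in-cluster expressing fraction (default 0.20).
#' @param min_fold Minimum linear-scale fold change (default 2).
#' @return A `marker_criteria` list.
#' @export
marker_criteria <- function(p_threshold = 1e-6, min_fraction = 0.20,
                            min_fold = 2.0) {
  stopifnot(p_threshold > 0, min_fold > 0,
            min_fraction > 0, min_fraction <= 1)
  structure(list(p_threshold = p_threshold, min_fraction = min_fraction,
                 min_fold = min_fold), class = "marker_criteria")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of two samples. `exact` mode evaluates the exact
#' permutation null of the rank-sum statistic with mid-ranks for ties (via a
#' generating-function convolution, identical to full enumeration of all
#' `choose(n1+n2, n1)` splits); `normal` mode uses the tie-corrected normal
#' approximation with continuity correction. `auto` picks exact for small
#' samples.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List: `statistic` (rank sum of `x`), `p_value` (two-sided, in
#'   (0, 1\]), `mode` used.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])

  if (mode == "auto") {
    mode <- if (choose(n, n1) <= 1e7 && n <= 60) "exact" else "normal"
  }
  if (mode == "exact") {
    if (choose(n, n1) > 1e7) {
      abort("exact enumeration too large (choose(n1+n2, n1) > 1e7); use normal",
            class = "chromastrat_use_normal")
    }
    p <- rank_sum_exact_p(r, n1)
  } else {
    p <- rank_sum_normal_p(W, r, n1)
  }
  list(statistic = W, p_value = p, mode = mode)
}

# exact two-sided p from the permutation distribution of the rank sum.
# doubled mid-ranks are integers, so the subset-sum distribution is built by
# integer convolution: f[j, s] = number of size-j subsets with doubled-rank
# sum s. The null is symmetric about n1*(n+1), so two-sided tail mass is
# counted as |sum - centre| >= |observed - centre|.
rank_sum_exact_p <- function(r, n1) {
  n <- length(r)
  r2 <- as.integer(round(2 * r))
  W2 <- sum(r2[seq_len(n1)])
  maxsum <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[[j]] indexed by sum s = 0..maxsum (offset 1)
  f <- vector("list", n1 + 1L)
  f[[1L]] <- c(1, numeric(maxsum))
  for (j in seq_len(n1)) f[[j + 1L]] <- numeric(maxsum + 1L)
  for (v in r2) {
    for (j in rev(seq_len(n1))) {
      shifted <- c(numeric(v), f[[j]][seq_len(maxsum + 1L - v)])
      f[[j + 1L]] <- f[[j + 1L]] + shifted
    }
  }
  dist <- f[[n1 + 1L]]
  total <- sum(dist)                      # = choose(n, n1)
  centre <- n1 * (n + 1)                  # E[W2]
  dev <- abs(W2 - centre)
  s <- seq(0L, maxsum)
  p <- sum(dist[abs(s - centre) >= dev - 1e-9]) / total
  min(1, p)
}

# tie-corrected normal approximation with 0.5 continuity correction
rank_sum_normal_p <- function(W, r, n1) {
  n <- length(r); n2 <- n - n1
  E <- n1 * (n + 1) / 2
  ties <- rle(sort(r))$lengths
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(1)
  z <- (W - E - sign(W - E) * min(0.5, abs(W - E))) / sqrt(v)
  min(1, 2 * pnorm(-abs(z)))
}

#' Full one-vs-rest marker statistics for every gene and cluster
#'
#' For each (gene, cluster) pair, tests in-cluster cells against all cells of
#' the other non-noise clusters with the tie-corrected normal rank-sum test,
#' and reports the expressing fraction, linear-scale means, fold change
#' (with pseudocount 1e-9) and log2 fold change. [select_markers()] filters
#' this table by the three criteria.
#'
#' @param norm Normalised genes-by-cells matrix.
#' @param labels Integer cluster labels over cells; noise (-1 or `NA`)
#'   excluded from both sides of every test.
#' @param min_cluster_size Clusters smaller than this are skipped with a
#'   warning (default 3).
#' @return Tibble: gene, cluster, p_value, fraction_in, mean_in, mean_out,
#'   fold, log2fc.
#' @export
marker_stats <- function(norm, labels, min_cluster_size = 3L) {
  stopifnot(ncol(norm) == length(labels))
  labels <- as.integer(labels)
  valid <- !is.na(labels) & labels > 0L
  cl <- sort(unique(labels[valid]))
  if (length(cl) < 2L) abort("need at least 2 non-noise clusters for marker testing")
  sizes <- table(factor(labels[valid], levels = cl))
  small <- cl[sizes < min_cluster_size]
  if (length(small)) {
    warn(paste0("cluster(s) smaller than ", min_cluster_size, " skipped: ",
                paste(small, collapse = ", ")))
    cl <- setdiff(cl, small)
    if (length(cl) < 2L) abort("fewer than 2 testable clusters remain")
  }

  X <- as.matrix(norm[, valid, drop = FALSE])
  lab <- labels[valid]
  n <- ncol(X); G <- nrow(X)
  # per-gene ranks and tie corrections, computed once
  R <- matrix(t(apply(X, 1L, rank)), nrow = G, dimnames = dimnames(X))
  tie_term <- apply(R, 1L, function(rr) {
    t <- rle(sort(rr))$lengths
    sum(t^3 - t)
  })
  expressed <- X > 0
  eps <- 1e-9

  out <- purrr::map_dfr(cl, function(c1) {
    ind <- lab == c1
    n1 <- sum(ind); n2 <- n - n1
    W <- rowSums(R[, ind, drop = FALSE])
    E <- n1 * (n + 1) / 2
    v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    d <- W - E
    z <- (d - sign(d) * pmin(0.5, abs(d))) / sqrt(pmax(v, .Machine$double.xmin))
    p <- pmin(1, 2 * pnorm(-abs(z)))
    p[v <= 0] <- 1
    mean_in <- unname(rowMeans(X[, ind, drop = FALSE]))
    mean_out <- unname(rowMeans(X[, !ind, drop = FALSE]))
    fold <- (mean_in + eps) / (mean_out + eps)
    tibble(gene = rownames(X), cluster = c1, p_value = unname(p),
           fraction_in = unname(rowMeans(expressed[, ind, drop = FALSE])),
           mean_in = mean_in, mean_out = mean_out,
           fold = fold, log2fc = log2(fold))
  })
  out
}

#' Select upregulated cluster markers by the three-criterion rule
#'
#' Keeps (gene, cluster) pairs passing all of: rank-sum p below the
#' threshold, expressing fraction at least `min_fraction`, and fold change at
#' least `min_fold` (upregulated only). Sorted by cluster then p.
#'
#' @param norm Normalised genes-by-cells matrix.
#' @param labels Integer cluster labels (noise = -1 / `NA` excluded).
#' @param criteria A [marker_criteria()] object.
#' @return Tibble of marker records (see [marker_stats()] for columns).
#' @export
select_markers <- function(norm, labels, criteria = marker_criteria()) {
  stats <- marker_stats(norm, labels)
  out <- dplyr::filter(stats,
                       .data$p_value < criteria$p_threshold,
                       .data$fraction_in >= criteria$min_fraction,
                       .data$fold >= criteria$min_fold)
  dplyr::arrange(out, .data$cluster, .data$p_value)
}

#' Gene-by-cluster log2 fold-change matrix
#'
#' Entry (g, c) is `log2((mean_in + eps) / (mean_out + eps))` of gene g for
#' cluster c against all other non-noise clusters — the quantity behind
#' marker heat-map panels. Rows are ordered by descending max |log2FC|.
#'
#' @param norm Normalised genes-by-cells matrix.
#' @param labels Integer cluster labels.
#' @param genes Genes to include (default: all rows of `norm`).
#' @param sort_rows Order rows by max |log2FC| (default TRUE).
#' @return Numeric genes-by-clusters matrix.
#' @export
log2fc_matrix <- function(norm, labels, genes = rownames(norm),
                          sort_rows = TRUE) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing)) abort(paste0("genes absent from matrix: ",
                                    paste(head(missing, 5L), collapse = ", ")))
  stats <- marker_stats(norm[genes, , drop = FALSE], labels,
                        min_cluster_size = 1L)
  wide <- tidyr::pivot_wider(stats[, c("gene", "cluster", "log2fc")],
                             names_from = "cluster", values_from = "log2fc")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$gene
  m <- m[match(genes, rownames(m)), , drop = FALSE]
  if (sort_rows && nrow(m) > 1L) {
    m <- m[order(apply(abs(m), 1L, max), decreasing = TRUE), , drop = FALSE]
  }
  m
}
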