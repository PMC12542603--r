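#' Per-condition subcluster composition
#'
#' Counts cells per (cell type, subcluster, condition) and expresses each
#' subcluster as a percentage of that condition's non-noise cells of that
#' type — the stratification readout behind per-type composition bar graphs.
#' Noise cells (subcluster -1) are reported with their counts but excluded
#' from the percentage denominators (`pct = NA`).
#'
#' @param labels Tibble with `cell_id`, `cell_type`, `subcluster` (and
#'   optionally `subcluster_label`), as from [subcluster_by_type()]'s
#'   `$cells`; a `subclustering` object is also accepted.
#' @param annotation Tibble with `cell_id` and `condition` for every cell in
#'   `labels`.
#' @return A `composition_table` tibble: cell_type, subcluster,
#'   subcluster_label, condition, n, pct.
#' @export
composition <- function(labels, annotation) {
  if (inherits(labels, "subclustering")) labels <- labels$cells
  stopifnot(all(c("cell_id", "cell_type", "subcluster") %in% names(labels)))
  if (!"subcluster_label" %in% names(labels)) {
    labels$subcluster_label <- ifelse(labels$subcluster > 0L,
                                      as.character(labels$subcluster),
                                      NA_character_)
  }
  joined <- dplyr::left_join(labels,
                             annotation[, c("cell_id", "condition")],
                             by = "cell_id")
  if (anyNA(joined$condition)) {
    abort("condition missing for one or more cells in the annotation")
  }
  counts <- joined |>
    dplyr::count(.data$cell_type, .data$subcluster, .data$subcluster_label,
                 .data$condition, name = "n")
  out <- counts |>
    dplyr::group_by(.data$cell_type, .data$condition) |>
    dplyr::mutate(pct = ifelse(.data$subcluster > 0L,
                               100 * .data$n / sum(.data$n[.data$subcluster > 0L]),
                               NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cell_type, .data$condition, .data$subcluster)
  # warn about (type, condition) blocks that never occur
  grid <- tidyr::expand_grid(cell_type = unique(labels$cell_type),
                             condition = unique(annotation$condition))
  seen <- dplyr::distinct(out, .data$cell_type, .data$condition)
  missing <- dplyr::anti_join(grid, seen, by = c("cell_type", "condition"))
  if (nrow(missing)) {
    warn(paste0("no cells for: ",
                paste(missing$cell_type, missing$condition,
                      sep = "/", collapse = ", ")))
  }
  structure(out, class = c("composition_table", class(out)))
}

#' Locate the disease-enriched subcluster of a cell type
#'
#' Operational definition: among a type's non-noise subclusters, the one
#' maximising (disease percentage - healthy percentage). Returns its label
#' and both percentages.
#'
#' @param comp A [composition()] table.
#' @param cell_type Cell type to inspect.
#' @param disease,healthy Condition names (defaults "disease", "healthy").
#' @return One-row tibble: cell_type, subcluster, subcluster_label,
#'   pct_disease, pct_healthy, delta.
#' @export
disease_enriched_subcluster <- function(comp, cell_type = "cardiomyocyte",
                                        disease = "disease",
                                        healthy = "healthy") {
  sub <- comp[comp$cell_type == cell_type & comp$subcluster > 0L, ]
  if (!nrow(sub)) abort(paste0("no non-noise subclusters for ", cell_type))
  wide <- tidyr::pivot_wider(
    sub[, c("subcluster", "subcluster_label", "condition", "pct")],
    names_from = "condition", values_from = "pct", values_fill = 0)
  for (cond in c(disease, healthy)) {
    if (!cond %in% names(wide)) wide[[cond]] <- 0
  }
  wide$delta <- wide[[disease]] - wide[[healthy]]
  best <- wide[which.max(wide$delta), ]
  tibble(cell_type = cell_type, subcluster = best$subcluster,
         subcluster_label = best$subcluster_label,
         pct_disease = best[[disease]], pct_healthy = best[[healthy]],
         delta = best$delta)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings via the closed-form
#' contingency formula under the permutation model. Positions where either
#' labeling is noise (-1 or `NA`) are excluded pairwise.
#'
#' @param a,b Label vectors of equal length (integer, character or factor).
#' @param noise Values treated as noise (default -1).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b, noise = -1L) {
  if (length(a) != length(b)) abort("labelings must have equal length")
  keep <- !is.na(a) & !is.na(b) & !(a %in% noise) & !(b %in% noise)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) abort("fewer than 2 non-noise items")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both labelings trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Marker recovery against planted truth
#'
#' Scores a cluster's selected markers against the generator's planted
#' positive-direction panel effects: sensitivity = recovered planted
#' positives / planted positives; precision = recovered / selected.
#'
#' @param selected Marker tibble (from [select_markers()]), or a character
#'   vector of gene symbols.
#' @param truth_genes Truth tibble with `gene` and `true_log2fc`
#'   (from `generate_cohort()$truth$genes`).
#' @param cluster Cluster id to score (ignored when `selected` is a
#'   character vector; default: all rows).
#' @return One-row tibble: n_planted, n_selected, n_hit, sensitivity,
#'   precision (`NA` when no gene was selected).
#' @export
marker_recovery <- function(selected, truth_genes, cluster = NULL) {
  if (is.data.frame(selected)) {
    if (!is.null(cluster)) selected <- selected[selected$cluster %in% cluster, ]
    genes <- unique(selected$gene)
  } else {
    genes <- unique(as.character(selected))
  }
  planted <- truth_genes$gene[truth_genes$true_log2fc > 0]
  if (!length(planted)) {
    warn("no planted positive effects; sensitivity undefined")
    return(tibble(n_planted = 0L, n_selected = length(genes),
                  n_hit = NA_integer_, sensitivity = NA_real_,
                  precision = NA_real_))
  }
  hit <- length(intersect(genes, planted))
  tibble(
    n_planted = length(planted), n_selected = length(genes), n_hit = hit,
    sensitivity = hit / length(planted),
    precision = if (length(genes)) hit / length(genes) else NA_real_
  )
}

#' Prevalence estimate with exact binomial confidence interval
#'
#' @param x Successes; @param n Trials; @param conf Level (default 0.95).
#' @return Tibble: estimate, lower, upper.
#' @export
prevalence_ci <- function(x, n, conf = 0.95) {
  ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
  tibble(estimate = x / n, lower = ci[1L], upper = ci[2L])
}
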