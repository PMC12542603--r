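#' Project an embedding to two dimensions with UMAP
#'
#' Thin, seeded wrapper over uwot's UMAP. Single-threaded optimisation so the
#' layout is reproducible from the seed.
#'
#' @param embedding Cells-by-dimensions numeric matrix.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 30; capped at
#'   `n_cells - 1`).
#' @param min_dist UMAP minimum embedding distance (default 0.3).
#' @return Cells-by-2 coordinate matrix with the parameters as attributes.
#' @export
project_umap <- function(embedding, seed = 1L, n_neighbors = 30L, min_dist = 0.3) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 3L) abort("need at least 3 cells for UMAP")
  n_neighbors <- min(n_neighbors, n - 1L)
  set.seed(derive_seed(seed, "umap"))
  xy <- uwot::umap(embedding, n_neighbors = n_neighbors, min_dist = min_dist,
                   n_threads = 1, n_sgd_threads = 0, batch = FALSE,
                   verbose = FALSE)
  dimnames(xy) <- list(rownames(embedding), c("umap1", "umap2"))
  attr(xy, "seed") <- as.integer(seed)
  attr(xy, "n_neighbors") <- as.integer(n_neighbors)
  attr(xy, "min_dist") <- min_dist
  xy
}

# neighbourhood query within radius eps. 2-D inputs use a uniform grid of
# side eps (9-cell stencil); higher dimensions fall back to a vectorised
# full-distance scan per query.
make_region_query <- function(points, eps) {
  n <- nrow(points)
  if (ncol(points) == 2L) {
    gx <- floor(points[, 1L] / eps)
    gy <- floor(points[, 2L] / eps)
    key <- paste(gx, gy)
    bins <- split(seq_len(n), key)
    function(i) {
      cand <- unlist(bins[paste(rep(gx[i] + -1:1, each = 3), gy[i] + -1:1)],
                     use.names = FALSE)
      d2 <- (points[cand, 1L] - points[i, 1L])^2 +
            (points[cand, 2L] - points[i, 2L])^2
      cand[d2 <= eps^2]
    }
  } else {
    tp <- t(points)
    function(i) {
      d2 <- colSums((tp - points[i, ])^2)
      which(d2 <= eps^2)
    }
  }
}

#' Default DBSCAN radius from the k-nearest-neighbour distance profile
#'
#' The 90th percentile of each point's distance to its `min_samples`-th
#' nearest neighbour (self excluded) — a knee-style heuristic for `eps` when
#' none is supplied.
#'
#' @param points Numeric matrix of coordinates.
#' @param min_samples DBSCAN core-point threshold.
#' @param probs Quantile to take (default 0.9).
#' @return A positive scalar radius.
#' @export
eps_heuristic <- function(points, min_samples = 10L, probs = 0.9) {
  points <- as.matrix(points)
  k <- min(min_samples, nrow(points) - 1L)
  dk <- FNN::knn.dist(points, k = k)[, k]
  e <- stats::quantile(dk, probs, names = FALSE)
  if (e <= 0) e <- max(dk, .Machine$double.eps)
  e
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN with core/border/noise semantics: a point is a core point
#' when at least `min_samples` points (itself included) lie within `eps`;
#' clusters are the connected components of core points, border points join
#' the first cluster that reaches them, and everything else is noise
#' (label -1). Cluster ids are renumbered by descending size.
#'
#' @param points Cells-by-dims coordinate matrix (2-D UMAP by default
#'   upstream; any dimensionality accepted).
#' @param eps Neighbourhood radius; `NULL` uses [eps_heuristic()].
#' @param min_samples Core-point density threshold (default 10).
#' @return Integer label vector (named by rownames), noise = -1, with
#'   `eps` / `min_samples` attributes.
#' @export
cluster_density <- function(points, eps = NULL, min_samples = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(min_samples >= 1L)
  if (is.null(eps)) eps <- eps_heuristic(points, min_samples)
  stopifnot(eps > 0)

  query <- make_region_query(points, eps)
  labels <- integer(n)            # 0 = unclassified
  NOISE <- -1L
  cid <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- query(i)
    if (length(nb) < min_samples) {
      labels[i] <- NOISE
      next
    }
    cid <- cid + 1L
    labels[i] <- cid
    seeds <- setdiff(nb, i)
    head_ptr <- 1L
    while (head_ptr <= length(seeds)) {
      q <- seeds[head_ptr]; head_ptr <- head_ptr + 1L
      if (labels[q] == NOISE) labels[q] <- cid       # border point
      if (labels[q] != 0L) next
      labels[q] <- cid
      nb_q <- query(q)
      if (length(nb_q) >= min_samples) {
        new <- nb_q[labels[nb_q] == 0L | labels[nb_q] == NOISE]
        new <- setdiff(new, seeds[head_ptr:length(seeds)])
        if (length(new)) seeds <- c(seeds, new)
      }
    }
  }

  labels <- renumber_by_size(labels)
  names(labels) <- rownames(points)
  attr(labels, "eps") <- eps
  attr(labels, "min_samples") <- as.integer(min_samples)
  labels
}

# relabel clusters 1..k by descending size; noise (-1) untouched
renumber_by_size <- function(labels) {
  keep <- labels > 0L
  if (!any(keep)) return(labels)
  sizes <- sort(table(labels[keep]), decreasing = TRUE)
  map <- setNames(seq_along(sizes), names(sizes))
  labels[keep] <- as.integer(map[as.character(labels[keep])])
  labels
}

#' Assign cell types to clusters from lineage markers
#'
#' For each non-noise cluster, each candidate type is scored as the mean over
#' its marker genes of the cluster-mean expression z-scored across clusters;
#' the argmax type is assigned. Ties break lexicographically on type name
#' with a warning. With a single cluster, raw cluster-mean marker expression
#' is used (z-scores degenerate).
#'
#' @param norm Normalised genes-by-cells matrix.
#' @param labels Integer cluster labels over cells (noise = -1 excluded).
#' @param marker_map Named list, cell type -> marker symbols
#'   ([default_marker_map()]).
#' @return Tibble: cluster, cell_type, score, margin (gap to runner-up).
#' @export
assign_cell_types <- function(norm, labels, marker_map = default_marker_map()) {
  clusters <- sort(unique(labels[labels > 0L]))
  if (!length(clusters)) abort("no non-noise clusters to type")
  marker_map <- lapply(marker_map, function(m) toupper(m))
  all_markers <- unique(unlist(marker_map))
  present <- intersect(all_markers, rownames(norm))
  missing <- setdiff(all_markers, present)
  if (length(missing)) {
    warn(paste0("marker gene(s) absent from matrix, dropped: ",
                paste(missing, collapse = ", ")))
  }
  marker_map <- lapply(marker_map, intersect, present)
  marker_map <- marker_map[lengths(marker_map) > 0L]
  if (!length(marker_map)) abort("no marker genes present in matrix")

  # cluster-mean expression of each marker gene
  cm <- vapply(clusters, function(cl)
    Matrix::rowMeans(norm[present, labels == cl, drop = FALSE]),
    numeric(length(present)))
  cm <- matrix(cm, nrow = length(present),
               dimnames = list(present, as.character(clusters)))
  if (length(clusters) > 1L) {
    mu <- rowMeans(cm)
    s <- apply(cm, 1L, sd)
    z <- (cm - mu) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- 0
  } else {
    z <- cm
  }

  scores <- t(vapply(marker_map, function(m)
    colMeans(z[m, , drop = FALSE]), numeric(length(clusters))))
  # types x clusters; assign per cluster
  out <- purrr::map_dfr(seq_along(clusters), function(j) {
    sc <- sort(scores[, j], decreasing = TRUE)
    top <- names(scores[, j])[scores[, j] == sc[1L]]
    if (length(top) > 1L) {
      warn(sprintf("cluster %d: tied type scores (%s); lexicographic tie-break",
                   clusters[j], paste(top, collapse = ", ")))
      top <- sort(top)
    }
    tibble(cluster = clusters[j], cell_type = top[1L], score = sc[1L],
           margin = if (length(sc) > 1L) sc[1L] - sc[2L] else NA_real_)
  })
  out
}

#' Stage-1 global clustering and cell typing
#'
#' Runs the full first stage on a raw count matrix: sex-gene exclusion,
#' rare-gene filtering, median-library normalisation, autoencoder embedding,
#' UMAP projection, DBSCAN clustering, and lineage-marker type assignment.
#'
#' @param counts Genes-by-cells count matrix.
#' @param marker_map Cell type -> marker symbols.
#' @param exclusion Symbols removed before embedding
#'   ([default_exclusion_list()]).
#' @param min_fraction Rare-gene threshold (default 0.01).
#' @param latent_dim,epochs,learning_rate,activation Autoencoder settings.
#' @param n_neighbors,min_dist UMAP settings.
#' @param eps,min_samples DBSCAN settings (`eps = NULL` -> heuristic).
#' @param cluster_on `"umap"` (default) or `"embedding"`: the space DBSCAN
#'   runs in.
#' @param seed Global stage seed.
#' @return A `stage1_result` list: `cells` tibble (cell_id, cluster,
#'   cell_type), `type_map`, `embedding`, `projection`, `labels`, `model`,
#'   `norm`.
#' @export
stage1_cluster <- function(counts, marker_map = default_marker_map(),
                           exclusion = default_exclusion_list(),
                           min_fraction = 0.01, latent_dim = 10L,
                           epochs = 500L, learning_rate = 1e-2,
                           activation = "tanh", n_neighbors = 30L,
                           min_dist = 0.3, eps = NULL, min_samples = 10L,
                           cluster_on = c("umap", "embedding"), seed = 1L) {
  cluster_on <- match.arg(cluster_on)
  m <- exclude_genes(counts, exclusion)
  m <- filter_rare_genes(m, min_fraction)
  norm <- normalize_counts(m)
  model <- train_autoencoder(norm, latent_dim = latent_dim, epochs = epochs,
                             learning_rate = learning_rate,
                             activation = activation,
                             seed = derive_seed(seed, "stage1_ae"))
  emb <- encode(model, norm)
  proj <- project_umap(emb, seed = derive_seed(seed, "stage1_umap"),
                       n_neighbors = n_neighbors, min_dist = min_dist)
  labels <- cluster_density(if (cluster_on == "umap") proj else emb,
                            eps = eps, min_samples = min_samples)
  # type calling uses the full normalised matrix so all markers are available
  norm_full <- normalize_counts(exclude_genes(counts, exclusion))
  type_map <- assign_cell_types(norm_full, labels, marker_map)
  cells <- tibble(cell_id = colnames(counts), cluster = as.integer(labels)) |>
    dplyr::left_join(type_map[, c("cluster", "cell_type")], by = "cluster")
  structure(list(cells = cells, type_map = type_map, embedding = emb,
                 projection = proj, labels = labels, model = model,
                 norm = norm), class = "stage1_result")
}

#' Panel-restricted subclustering within each cell type
#'
#' The second stage: for every cell type, the matrix is restricted to that
#' type's cells and to the chromatin panel genes, then re-run through
#' filter -> normalise -> autoencoder -> UMAP -> DBSCAN. Subcluster ids are
#' namespaced per type (CM1, CM2, ... largest first); DBSCAN noise keeps
#' id -1 and an `NA` label.
#'
#' @param counts Full genes-by-cells count matrix.
#' @param annotation Tibble with `cell_id` and `cell_type` (from stage 1 or
#'   external).
#' @param panel Gene panel gating the stage-2 embedding
#'   (default [chromatin_panel()]).
#' @param exclusion Sex-biased symbols to drop first.
#' @param types Cell types to process (default all in `annotation`).
#' @param min_fraction,latent_dim,epochs,learning_rate,activation,n_neighbors,min_dist,eps,min_samples,cluster_on
#'   Per-type stage parameters, as in [stage1_cluster()]. Stage 2 defaults to
#'   a tighter layout (`min_dist = 0.05`) and a stricter core threshold
#'   (`min_samples = 20`) than the global stage: subcluster structure within
#'   a type is subtler than between types, and density clustering benefits
#'   from compact blobs and suppression of micro-fragments.
#' @param seed Global stage seed; each type derives its own sub-seed.
#' @return A `subclustering` object: `$cells` tibble (cell_id, cell_type,
#'   subcluster, subcluster_label) and `$detail` per-type list (projection,
#'   labels, eps, model glance).
#' @export
subcluster_by_type <- function(counts, annotation, panel = chromatin_panel(),
                               exclusion = default_exclusion_list(),
                               types = NULL, min_fraction = 0.01,
                               latent_dim = 10L, epochs = 500L,
                               learning_rate = 1e-2, activation = "tanh",
                               n_neighbors = 30L, min_dist = 0.05, eps = NULL,
                               min_samples = 20L,
                               cluster_on = c("umap", "embedding"),
                               seed = 1L) {
  cluster_on <- match.arg(cluster_on)
  stopifnot(all(c("cell_id", "cell_type") %in% names(annotation)))
  types <- types %||% sort(unique(annotation$cell_type))
  rows <- list(); detail <- list()
  for (ty in types) {
    ids <- annotation$cell_id[annotation$cell_type %in% ty]
    ids <- intersect(colnames(counts), ids)
    if (length(ids) < max(min_samples, 3L)) {
      warn(sprintf("cell type '%s': only %d cells, skipped", ty, length(ids)))
      next
    }
    sub <- counts[, ids, drop = FALSE]
    sub <- exclude_genes(sub, exclusion)
    sub <- suppressMessages(restrict_to_panel(sub, panel))
    sub <- filter_rare_genes(sub, min_fraction)
    norm <- normalize_counts(sub)
    ty_seed <- derive_seed(seed, paste0("stage2_", ty))
    model <- train_autoencoder(norm, latent_dim = latent_dim, epochs = epochs,
                               learning_rate = learning_rate,
                               activation = activation, seed = ty_seed)
    emb <- encode(model, norm)
    proj <- project_umap(emb, seed = ty_seed, n_neighbors = n_neighbors,
                         min_dist = min_dist)
    labels <- cluster_density(if (cluster_on == "umap") proj else emb,
                              eps = eps, min_samples = min_samples)
    ab <- type_abbrev(ty)
    rows[[ty]] <- tibble(
      cell_id = ids, cell_type = ty, subcluster = as.integer(labels),
      subcluster_label = ifelse(labels > 0L, paste0(ab, labels), NA_character_)
    )
    detail[[ty]] <- list(projection = proj, labels = labels,
                         eps = attr(labels, "eps"),
                         model_summary = glance(model),
                         genes_used = rownames(sub))
  }
  if (!length(rows)) abort("no cell type had enough cells to subcluster")
  structure(list(cells = dplyr::bind_rows(rows), detail = detail),
            class = "subclustering")
}

#' @export
print.subclustering <- function(x, ...) {
  cat("<subclustering>\n")
  print(dplyr::count(x$cells, .data$cell_type, .data$subcluster_label))
  invisible(x)
}
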