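test_that("UMAP projection is seeded, 2-D and separates blobs", {
  set.seed(10)
  blobs <- rbind(matrix(rnorm(200 * 5, 0), 200, 5),
                 matrix(rnorm(200 * 5, 8), 200, 5))
  a <- project_umap(blobs, seed = 1L)
  b <- project_umap(blobs, seed = 1L)
  expect_identical(a[], b[])
  expect_identical(ncol(a), 2L)
  g <- rep(1:2, each = 200)
  cents <- rbind(colMeans(a[g == 1, ]), colMeans(a[g == 2, ]))
  between <- sqrt(sum((cents[1, ] - cents[2, ])^2))
  within <- vapply(1:2, function(k)
    mean(stats::dist(a[g == k, ])), numeric(1))
  expect_true(all(between > within))
  expect_error(project_umap(blobs[1:2, ]), "at least 3")
})

test_that("DBSCAN handles the degenerate regimes", {
  pts <- matrix(1, 20, 2)
  lab <- cluster_density(pts, eps = 0.5, min_samples = 10L)
  expect_identical(unique(as.integer(lab)), 1L)

  set.seed(11)
  spread <- matrix(runif(20, 0, 100), 10, 2)
  lab2 <- cluster_density(spread, eps = 1e-9, min_samples = 2L)
  expect_true(all(lab2 == -1L))
})

test_that("DBSCAN separates two well-spaced blobs exactly", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(400, 0, 0.1), 200, 2),
               matrix(rnorm(400, 10, 0.1), 200, 2))
  lab <- cluster_density(pts, eps = 0.5, min_samples = 10L)
  expect_identical(max(lab), 2L)
  expect_identical(sum(lab == -1L), 0L)
  expect_dbscan_matches(lab, pts, 0.5, 10L)
})

test_that("DBSCAN equals the quadratic reference on random instances", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(c(60L, 200L, 500L), 1)
    dim <- sample(c(2L, 2L, 10L), 1)   # mostly 2-D, sometimes high-dim
    k <- sample(2:4, 1)
    cent <- matrix(rnorm(k * dim, sd = 4), k, dim)
    pts <- cent[sample(k, n, replace = TRUE), ] +
      matrix(rnorm(n * dim, sd = 0.6), n, dim)
    ms <- sample(3:10, 1)
    eps <- eps_heuristic(pts, ms)
    lab <- cluster_density(pts, eps = eps, min_samples = ms)
    expect_dbscan_matches(lab, pts, eps, ms)
  }
})

test_that("cluster ids are renumbered by descending size", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
               matrix(rnorm(300, 5, 0.05), 150, 2))
  lab <- cluster_density(pts, eps = 0.3, min_samples = 5L)
  expect_gt(sum(lab == 1L), sum(lab == 2L))
})

test_that("cell types are assigned from lineage markers", {
  co <- small_cohort()
  norm <- normalize_counts(co$counts)
  truth_types <- co$annotation$cell_type
  lab <- as.integer(factor(truth_types))     # clusters = planted types
  map <- assign_cell_types(norm, lab)
  joined <- merge(data.frame(cluster = lab, truth = truth_types),
                  as.data.frame(map), by = "cluster")
  expect_true(all(joined$cell_type == joined$truth))
})

test_that("single cluster with a single marked type is assigned directly", {
  m <- matrix(c(5, 0, 4, 1, 6, 0), 2, 3,
              dimnames = list(c("ACTC1", "OTHER"), c("a", "b", "c")))
  out <- assign_cell_types(Matrix::Matrix(m, sparse = TRUE), rep(1L, 3),
                           marker_map = list(cardiomyocyte = "ACTC1"))
  expect_identical(out$cell_type, "cardiomyocyte")
})

test_that("tied type scores break lexicographically with a warning", {
  m <- matrix(c(3, 3, 1, 1), 2, 2,
              dimnames = list(c("MK1", "MK2"), c("a", "b")))
  # both clusters tie, so two warnings fire
  expect_warning(expect_warning(
    out <- assign_cell_types(Matrix::Matrix(m, sparse = TRUE), c(1L, 2L),
                             marker_map = list(beta = "MK1", alpha = "MK2")),
    "tie"), "tie")
  # MK1 and MK2 have identical profiles -> identical z-scores -> tie
  expect_identical(out$cell_type[out$cluster == 1L], "alpha")
})

test_that("subclustering is gated by the gene panel and skips tiny types", {
  co <- small_cohort()
  expect_warning(
    sub <- suppressMessages(subcluster_by_type(
      co$counts, co$annotation, epochs = 150L, min_samples = 80L,
      types = c("cardiomyocyte", "lymphocyte"), seed = 1L)),
    "skipped")
  expect_true(inherits(sub, "subclustering"))
  # gene restriction equals restrict_to_panel on the same inputs
  used <- sub$detail$cardiomyocyte$genes_used
  cm_ids <- co$annotation$cell_id[co$annotation$cell_type == "cardiomyocyte"]
  ref <- filter_rare_genes(suppressMessages(restrict_to_panel(
    exclude_genes(co$counts[, cm_ids], default_exclusion_list()),
    chromatin_panel())))
  expect_setequal(used, rownames(ref))
  # namespaced labels
  labs <- sub$cells$subcluster_label[sub$cells$subcluster > 0]
  expect_true(all(grepl("^CM[0-9]+$", labs)))
})

test_that("a type without substructure yields one dominant subcluster", {
  co <- small_cohort()
  sub <- suppressWarnings(suppressMessages(subcluster_by_type(
    co$counts, co$annotation, epochs = 150L,
    types = "fibroblast", seed = 1L)))
  tab <- table(sub$cells$subcluster[sub$cells$subcluster > 0])
  expect_gt(max(tab) / sum(tab), 0.9)
})
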