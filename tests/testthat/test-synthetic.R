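test_that("default configuration encodes the study conditions", {
  cfg <- default_config()
  expect_equal(unname(cfg$subpop_prevalence["healthy"]), 0.03)
  expect_equal(unname(cfg$subpop_prevalence["disease"]), 0.18)
  expect_identical(sort(names(cfg$cell_type_proportions)),
                   sort(c("cardiomyocyte", "fibroblast", "endothelial",
                          "smooth muscle", "macrophage", "lymphocyte")))
  expect_silent(validate_cohort_config(cfg))
  expect_length(cfg$genes, 1000L)
  expect_length(cfg$affected_effects, 40L)
  # planted effects live on panel genes only, half up / half down
  expect_true(all(names(cfg$affected_effects) %in%
                  as.character(chromatin_panel())))
  expect_equal(sum(cfg$affected_effects > 0), 20L)
  expect_equal(unique(abs(cfg$affected_effects)), 1.5)
  # enough cardiomyocyte nuclei per condition for subcluster analysis
  expect_gte(min(cfg$n_cells) * cfg$cell_type_proportions[["cardiomyocyte"]],
             5000)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(cohort_config(cell_type_proportions = c(cardiomyocyte = 0.5,
                                                       fibroblast = 0.4)),
               "sum to 1")
  expect_error(cohort_config(subpop_prevalence = c(healthy = -0.1, disease = 0.2)),
               "prevalence")
  expect_error(cohort_config(dispersion = 0), "dispersion")
  expect_error(cohort_config(n_cells = c(healthy = 0L, disease = 10L)),
               "n_cells")
})

test_that("generation is bitwise reproducible from the seed", {
  cfg <- cohort_config(n_cells = c(healthy = 150L, disease = 150L), seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cfg, seed = 8L)
  expect_false(identical(as.matrix(a$counts), as.matrix(c2$counts)))
})

test_that("null-effect cohort matches closed-form negative binomial moments", {
  # one cell type, no markers, no subpopulation: counts are NB with mean
  # s_c * mu_g, s_c lognormal. E[count_g] = E[s] * mu_g with
  # E[s] = exp(meanlog + sdlog^2/2).
  cfg <- cohort_config(
    n_cells = c(healthy = 1000L, disease = 1000L),
    cell_type_proportions = c(cardiomyocyte = 1),
    marker_map = list(cardiomyocyte = "ACTC1"), marker_fold = 1,
    subpop_prevalence = c(healthy = 0, disease = 0),
    n_affected = 2L, effect_log2fc = 0,
    libsize_meanlog = 0, libsize_sdlog = 0.3, seed = 11L)
  co <- generate_cohort(cfg)
  n <- ncol(co$counts)
  es <- exp(0 + 0.3^2 / 2)
  mu <- cfg$baseline_mean
  phi <- cfg$dispersion
  emp <- Matrix::rowMeans(co$counts)
  # per-gene MC standard error of the mean: Var = E[V(X|s)] + V(E[X|s])
  vs <- (exp(0.3^2) - 1) * exp(0.3^2)      # variance of lognormal s
  v <- es * mu + (es * mu)^2 / phi * (vs / es^2 + 1) + mu^2 * vs
  se <- sqrt(v / n)
  z <- abs(emp - es * mu) / se
  # jointly over ~1000 genes a few 3-sigma excursions are expected
  expect_gte(mean(z <= 3), 0.99)
  expect_lt(max(z), 6)
})

test_that("planted subpopulation prevalence sits inside its binomial interval", {
  co <- small_cohort()
  cfg <- co$config
  for (cond in c("healthy", "disease")) {
    cm <- co$truth$cells[co$truth$cells$condition == cond &
                         co$truth$cells$cell_type == "cardiomyocyte", ]
    ci <- stats::binom.test(sum(cm$subpop), nrow(cm),
                            p = cfg$subpop_prevalence[[cond]],
                            conf.level = 0.99)$conf.int
    expect_true(cfg$subpop_prevalence[[cond]] >= ci[1] &&
                cfg$subpop_prevalence[[cond]] <= ci[2])
  }
})

test_that("large dispersion approaches the Poisson limit", {
  cfg <- cohort_config(
    n_cells = c(healthy = 1500L, disease = 1500L),
    cell_type_proportions = c(cardiomyocyte = 1),
    marker_map = list(cardiomyocyte = "ACTC1"), marker_fold = 1,
    subpop_prevalence = c(healthy = 0, disease = 0),
    dispersion = 1e8, libsize_sdlog = 0, seed = 5L)
  co <- generate_cohort(cfg)
  x <- as.matrix(co$counts)
  vm <- apply(x, 1L, var) / pmax(rowMeans(x), 1e-12)
  # variance/mean ratio concentrates at 1 for expressed genes
  expressed <- rowMeans(x) > 0.5
  expect_gt(sum(expressed), 100)
  expect_equal(mean(vm[expressed]), 1, tolerance = 0.05)
})

test_that("unaffected genes are null across subpopulation flags", {
  co <- small_cohort()
  cm <- co$truth$cells$cell_type == "cardiomyocyte"
  flag <- co$truth$cells$subpop[cm]
  skip_if(sum(flag) < 5)
  x <- as.matrix(co$counts[, cm])
  unaffected <- sample(co$truth$genes$gene[!co$truth$genes$affected], 200)
  p <- vapply(unaffected, function(g) {
    suppressWarnings(stats::wilcox.test(x[g, flag], x[g, !flag])$p.value)
  }, numeric(1))
  p <- p[is.finite(p)]
  # calibration: uniform-ish null, no excess of small p
  expect_lt(mean(p < 0.05), 0.12)
  expect_gt(mean(p > 0.5), 0.3)
})

test_that("cohorts write and read back through the standard formats", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "matrix/matrix.mtx", "annotation.tsv", "truth_cells.tsv",
    "truth_genes.tsv")))))
  back <- read_matrix_market(file.path(dir, "matrix"))
  expect_equal(as.matrix(back), as.matrix(co$counts))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann$cell_id, co$annotation$cell_id)
})
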