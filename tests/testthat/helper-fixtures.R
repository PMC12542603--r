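# shared small fixtures, built in code and cached per test run

toy_counts <- function() {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3, 3, 3),
    j = c(1, 2, 2, 1, 3, 4),
    x = c(5, 1, 2, 3, 4, 1),
    dims = c(3, 4)
  )
  dimnames(m) <- list(c("HMGN3", "XIST", "CTCF"),
                      paste0("cell", 1:4))
  methods::as(m, "generalMatrix")
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort (600 cells/condition) for fast structural tests
small_cohort <- function() {
  cached("small_cohort", {
    cfg <- cohort_config(n_cells = c(healthy = 600L, disease = 600L), seed = 42L)
    suppressMessages(generate_cohort(cfg))
  })
}

# write a tiny GMT collection to a temp file
write_toy_gmt <- function(path, sets) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# small file-based pipeline run shared by the smoke and determinism tests
pipeline_run_dirs <- function() {
  cached("pipeline_runs", {
    root <- file.path(tempdir(), "chromastrat-pipeline")
    dir.create(root, showWarnings = FALSE, recursive = TRUE)
    data_dir <- file.path(root, "cohort")
    cfg <- cohort_config(n_cells = c(healthy = 500L, disease = 500L),
                         seed = 3L)
    suppressMessages(simulate_cohort_files(data_dir, cfg))
    fast <- list(epochs = 120L)
    rc <- function(out) run_config(
      matrix = file.path(data_dir, "matrix"),
      annotation = file.path(data_dir, "annotation.tsv"),
      truth_genes = file.path(data_dir, "truth_genes.tsv"),
      outdir = out, seed = 5L, stage1 = fast, stage2 = fast)
    out1 <- file.path(root, "run1")
    res <- suppressWarnings(suppressMessages(run_pipeline(rc(out1))))
    out2 <- file.path(root, "run2")
    cfg2 <- run_config_from_manifest(file.path(out1, "manifest.json"), out2)
    suppressWarnings(suppressMessages(run_pipeline(cfg2)))
    list(run1 = out1, run2 = out2, results = res, data = data_dir)
  })
}


# cohort with 10 markers per type: validates the stage-1 clustering machinery
# itself; the default lineage lists (1-4 genes/type) under-determine fully
# unsupervised typing by construction
rich_cohort <- function() {
  cached("rich_cohort", {
    mm <- default_marker_map()
    mm_rich <- lapply(setNames(names(mm), names(mm)), function(ty) {
      c(mm[[ty]], sprintf("%s_MK%02d", toupper(substr(ty, 1, 3)), 1:8))
    })
    cfg <- cohort_config(n_cells = c(healthy = 800L, disease = 800L),
                         marker_map = mm_rich, seed = 42L)
    list(cohort = suppressMessages(generate_cohort(cfg)), marker_map = mm_rich)
  })
}
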