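#' Build a validated pipeline run configuration
#'
#' Collects every path, hyperparameter and seed of a full run into one
#' structure; [run_pipeline()] executes it and records it verbatim in the
#' run manifest, which alone reproduces the run.
#'
#' @param matrix Path to a Matrix-Market directory or dense TSV, or an
#'   in-memory genes-by-cells matrix.
#' @param annotation Path to the annotation TSV, or a tibble.
#' @param panel Path to a panel file, or a `gene_panel` (default: packaged
#'   chromatin panel).
#' @param gmt Optional path to a GMT collection for enrichment.
#' @param truth_genes Optional truth tibble (or TSV path) enabling marker
#'   recovery scoring.
#' @param outdir Output directory.
#' @param seed Global seed; every stage derives its own sub-seed from it.
#' @param use_annotation_types Use `cell_type` from the annotation for
#'   stage 2 instead of stage-1 assignments (default FALSE; stage 1 is then
#'   skipped).
#' @param stage1,stage2 Named lists of stage hyperparameter overrides
#'   (latent_dim, epochs, learning_rate, activation, n_neighbors, min_dist,
#'   eps, min_samples, min_fraction, cluster_on).
#' @param criteria [marker_criteria()] for marker selection.
#' @param p_cutoff,padj_cutoff Enrichment result filters.
#' @param exclusion Sex-biased gene exclusion list.
#' @return A `run_config` list.
#' @export
run_config <- function(matrix, annotation, panel = NULL, gmt = NULL,
                       truth_genes = NULL, outdir = "chromastrat_run",
                       seed = 1L, use_annotation_types = FALSE,
                       stage1 = list(), stage2 = list(),
                       criteria = marker_criteria(),
                       p_cutoff = 0.01, padj_cutoff = 0.05,
                       exclusion = default_exclusion_list()) {
  for (nm in c("matrix", "annotation", "panel", "gmt", "truth_genes")) {
    v <- get(nm)
    if (is.character(v) && length(v) == 1L && !file.exists(v)) {
      abort(sprintf("config field '%s': path does not exist: %s", nm, v))
    }
  }
  if (is.null(seed)) abort("config field 'seed' must be set")
  structure(list(
    matrix = matrix, annotation = annotation, panel = panel, gmt = gmt,
    truth_genes = truth_genes, outdir = outdir, seed = as.integer(seed),
    use_annotation_types = isTRUE(use_annotation_types),
    stage1 = stage1, stage2 = stage2, criteria = criteria,
    p_cutoff = p_cutoff, padj_cutoff = padj_cutoff, exclusion = exclusion
  ), class = "run_config")
}

load_matrix_input <- function(x) {
  if (is.character(x)) {
    if (dir.exists(x)) read_matrix_market(x) else read_dense_tsv(x)
  } else {
    x
  }
}

load_panel_input <- function(x) {
  if (is.null(x)) chromatin_panel()
  else if (is.character(x) && length(x) == 1L) suppressMessages(load_panel(x))
  else x
}

stage_args <- function(overrides, stage = c("stage1", "stage2")) {
  stage <- match.arg(stage)
  defaults <- list(latent_dim = 10L, epochs = 500L, learning_rate = 1e-2,
                   activation = "tanh", n_neighbors = 30L,
                   min_dist = if (stage == "stage1") 0.3 else 0.05,
                   eps = NULL,
                   min_samples = if (stage == "stage1") 10L else 20L,
                   min_fraction = 0.01, cluster_on = "umap")
  out <- utils::modifyList(defaults, as.list(overrides), keep.null = TRUE)
  # JSON round-trips can turn a NULL eps into an empty list
  if (!is.null(out$eps) && !(is.numeric(out$eps) && length(out$eps) == 1L)) {
    out$eps <- NULL
  }
  out
}

#' Execute the full stratification pipeline
#'
#' Runs, in order: stage-1 global clustering and cell typing (unless the
#' annotation's own `cell_type` is trusted), stage-2 panel-restricted
#' subclustering per cell type, three-criterion marker selection per type,
#' optional over-representation analysis of the disease-enriched
#' cardiomyocyte subcluster's markers, per-condition composition, and (when
#' truth is supplied) recovery metrics. All tables are written as TSV into
#' `config$outdir` along with a deterministic JSON run manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every result object plus `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    inform(sprintf("[%s +%.1fs] %s", stage,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   sprintf(...)))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  counts <- load_matrix_input(config$matrix)
  annotation <- if (is.character(config$annotation)) {
    read_annotation(config$annotation)
  } else as_tibble(config$annotation)
  panel <- load_panel_input(config$panel)
  s1 <- stage_args(config$stage1, "stage1")
  s2 <- stage_args(config$stage2, "stage2")
  log_stage("load", "%d genes x %d cells", nrow(counts), ncol(counts))

  results <- list(outdir = outdir)

  # ---- stage 1: global clustering & typing --------------------------------
  if (config$use_annotation_types) {
    if (!"cell_type" %in% names(annotation)) {
      abort("use_annotation_types = TRUE but annotation has no cell_type column")
    }
    typed <- annotation[, c("cell_id", "cell_type")]
    log_stage("stage1", "using annotation cell types (%d types)",
              dplyr::n_distinct(typed$cell_type))
  } else {
    st1 <- do.call(stage1_cluster, c(list(
      counts = counts, exclusion = config$exclusion,
      seed = derive_seed(config$seed, "stage1")), s1))
    results$stage1 <- st1
    typed <- st1$cells[, c("cell_id", "cell_type")]
    write_result_tsv(st1$cells, file.path(outdir, "stage1_labels.tsv"))
    write_result_tsv(st1$type_map, file.path(outdir, "stage1_types.tsv"))
    log_stage("stage1", "%d clusters, %d noise cells",
              max(st1$labels), sum(st1$labels == -1L))
  }

  # ---- stage 2: panel-restricted subclustering ----------------------------
  sub <- do.call(subcluster_by_type, c(list(
    counts = counts, annotation = typed, panel = panel,
    exclusion = config$exclusion,
    seed = derive_seed(config$seed, "stage2")), s2))
  results$subclustering <- sub
  write_result_tsv(sub$cells, file.path(outdir, "stage2_labels.tsv"))
  log_stage("stage2", "%d subclusters across %d types",
            dplyr::n_distinct(sub$cells$subcluster_label, na.rm = TRUE),
            length(sub$detail))

  # ---- markers: full-matrix values, per-type one-vs-rest ------------------
  norm_full <- normalize_counts(exclude_genes(counts, config$exclusion))
  markers <- list()
  for (ty in names(sub$detail)) {
    cells_ty <- sub$cells[sub$cells$cell_type == ty, ]
    labs <- cells_ty$subcluster
    if (dplyr::n_distinct(labs[labs > 0L]) < 2L) next
    mk <- suppressWarnings(select_markers(
      norm_full[, cells_ty$cell_id, drop = FALSE], labs, config$criteria))
    if (nrow(mk)) {
      ab <- type_abbrev(ty)
      mk$cell_type <- ty
      mk$subcluster_label <- paste0(ab, mk$cluster)
      markers[[ty]] <- mk
    }
  }
  markers <- dplyr::bind_rows(markers)
  results$markers <- markers
  write_result_tsv(markers, file.path(outdir, "markers.tsv"))
  log_stage("markers", "%d marker records", nrow(markers))

  # ---- composition --------------------------------------------------------
  comp <- composition(sub, annotation)
  results$composition <- comp
  write_result_tsv(comp, file.path(outdir, "composition.tsv"))
  conds <- unique(annotation$condition)
  if (all(c("healthy", "disease") %in% conds) &&
      "cardiomyocyte" %in% comp$cell_type) {
    results$disease_subcluster <-
      disease_enriched_subcluster(comp, "cardiomyocyte")
    write_result_tsv(results$disease_subcluster,
                     file.path(outdir, "disease_subcluster.tsv"))
  }
  log_stage("composition", "%d rows", nrow(comp))

  # ---- enrichment of the disease-enriched cardiomyocyte markers -----------
  if (!is.null(config$gmt) && !is.null(results$disease_subcluster) &&
      nrow(markers)) {
    sets <- read_gmt(config$gmt)
    lab <- results$disease_subcluster$subcluster_label
    query <- markers$gene[markers$subcluster_label == lab]
    filt <- filter_rare_genes(exclude_genes(counts, config$exclusion),
                              s1$min_fraction)
    if (length(query)) {
      enr <- enrich(query, sets, rownames(filt),
                    p_cutoff = config$p_cutoff,
                    padj_cutoff = config$padj_cutoff)
      results$enrichment <- enr
      write_result_tsv(enr, file.path(outdir, "enrichment.tsv"))
      log_stage("enrich", "%d enriched terms for %s", nrow(enr), lab)
    }
  }

  # ---- recovery against planted truth -------------------------------------
  if (!is.null(config$truth_genes)) {
    tg <- if (is.character(config$truth_genes)) {
      readr::read_tsv(config$truth_genes, show_col_types = FALSE)
    } else config$truth_genes
    if (!is.null(results$disease_subcluster) && nrow(markers)) {
      lab <- results$disease_subcluster$subcluster_label
      rec <- marker_recovery(markers$gene[markers$subcluster_label == lab], tg)
      results$recovery <- rec
      write_result_tsv(rec, file.path(outdir, "recovery.tsv"))
      log_stage("recovery", "sensitivity %.3f precision %.3f",
                rec$sensitivity, rec$precision)
    }
  }

  # ---- manifest (deterministic: no timestamps) ----------------------------
  manifest <- list(
    package = "chromastrat",
    version = as.character(utils::packageVersion("chromastrat")),
    seed = config$seed,
    use_annotation_types = config$use_annotation_types,
    stage1 = s1, stage2 = s2,
    criteria = unclass(config$criteria),
    enrichment = list(p_cutoff = config$p_cutoff,
                      padj_cutoff = config$padj_cutoff),
    exclusion = config$exclusion,
    inputs = list(
      matrix = if (is.character(config$matrix)) config$matrix else "<in-memory>",
      annotation = if (is.character(config$annotation)) config$annotation else "<in-memory>",
      panel = if (is.character(config$panel)) config$panel else "<packaged>",
      gmt = config$gmt %||% NA,
      truth_genes = if (is.character(config$truth_genes %||% NA)) config$truth_genes else NA
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  log_stage("done", "results in %s", outdir)
  invisible(results)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: [generate_cohort()] then [write_cohort()].
#'
#' @param outdir Output directory.
#' @param config A `cohort_config` (default [default_config()]).
#' @param seed Optional seed override.
#' @return `outdir`, invisibly.
#' @export
simulate_cohort_files <- function(outdir, config = default_config(),
                                  seed = config$seed) {
  cohort <- generate_cohort(config, seed = seed)
  write_cohort(cohort, outdir)
}

#' Rebuild a run configuration from a written manifest
#'
#' Reads the `manifest.json` emitted by [run_pipeline()] and reconstructs the
#' [run_config()] it records, so a run can be reproduced bit-for-bit from the
#' manifest alone (for file-based inputs).
#'
#' @param path Path to a `manifest.json`.
#' @param outdir Output directory for the reproduced run.
#' @return A `run_config`.
#' @export
run_config_from_manifest <- function(path, outdir) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NULL else x
  inp <- m$inputs
  if (identical(inp$matrix, "<in-memory>") ||
      identical(inp$annotation, "<in-memory>")) {
    abort("manifest records in-memory inputs; only file-based runs can be rebuilt")
  }
  run_config(
    matrix = inp$matrix, annotation = inp$annotation,
    panel = if (identical(inp$panel, "<packaged>")) NULL else inp$panel,
    gmt = pick(inp$gmt), truth_genes = pick(inp$truth_genes),
    outdir = outdir, seed = m$seed,
    use_annotation_types = isTRUE(m$use_annotation_types),
    stage1 = m$stage1, stage2 = m$stage2,
    criteria = do.call(marker_criteria, m$criteria),
    p_cutoff = m$enrichment$p_cutoff, padj_cutoff = m$enrichment$padj_cutoff,
    exclusion = m$exclusion
  )
}
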