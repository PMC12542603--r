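#' Read a Matrix-Market expression matrix with feature/barcode sidecars
#'
#' Reads a sparse count matrix in Matrix-Market coordinate format together
#' with its `features.tsv` (gene symbols, first column) and `barcodes.tsv`
#' (cell ids) sidecars, as written by common single-cell pipelines. Plain or
#' gzip-compressed files are accepted. If the matrix dimensions match the
#' sidecars only after transposition (cells on rows), it is transposed so
#' genes are rows.
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv` (or
#'   `genes.tsv`), and `barcodes.tsv`, optionally `.gz`; alternatively give
#'   the three paths explicitly.
#' @param matrix_file,features_file,barcodes_file Explicit file paths,
#'   overriding `dir`.
#' @return A `Matrix::dgCMatrix`, genes as rows, with symbol/barcode dimnames.
#' @export
read_matrix_market <- function(dir = NULL, matrix_file = NULL,
                               features_file = NULL, barcodes_file = NULL) {
  find1 <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    abort(paste0("none of ", paste(cands, collapse = "/"), " found in ", dir))
  }
  if (is.null(matrix_file))   matrix_file   <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(features_file)) features_file <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  if (is.null(barcodes_file)) barcodes_file <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))

  m <- Matrix::readMM(matrix_file)
  feats <- readr::read_tsv(features_file, col_names = FALSE, show_col_types = FALSE)
  genes <- toupper(trimws(as.character(feats[[1L]])))
  barcodes <- trimws(readLines(barcodes_file))
  barcodes <- barcodes[nzchar(barcodes)]

  if (nrow(m) == length(barcodes) && ncol(m) == length(genes) &&
      nrow(m) != length(genes)) {
    m <- Matrix::t(m)  # cells-on-rows dialect
  }
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    abort(sprintf("matrix is %d x %d but sidecars give %d features and %d barcodes",
                  nrow(m), ncol(m), length(genes), length(barcodes)))
  }
  vals <- m@x
  if (any(vals < 0)) abort("negative counts in matrix file")
  if (any(vals != round(vals))) abort("non-integer values in matrix file")
  if (anyDuplicated(genes)) abort("duplicate gene symbols in features file")
  if (anyDuplicated(barcodes)) abort("duplicate cell barcodes in barcodes file")
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write an expression matrix as Matrix-Market plus sidecars
#'
#' Inverse of [read_matrix_market()]: writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` into `dir`.
#'
#' @param matrix Genes-by-cells sparse matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_matrix_market <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(matrix, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix), file.path(dir, "features.tsv"))
  writeLines(colnames(matrix), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense TSV expression matrix
#'
#' First column gene symbols, header row of cell ids, integer counts.
#'
#' @param path TSV path.
#' @return Sparse genes-by-cells `dgCMatrix` (zeros not stored).
#' @export
read_dense_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) abort("dense TSV has no expression body")
  genes <- toupper(trimws(as.character(tab[[1L]])))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric entries in dense TSV")
  if (any(vals < 0)) abort("negative counts in dense TSV")
  if (any(vals != round(vals))) abort("non-integer counts in dense TSV")
  if (anyDuplicated(genes)) abort("duplicate gene symbols in dense TSV")
  m <- as(as(Matrix::Matrix(vals, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(genes, colnames(tab)[-1L])
  m
}

#' Read a per-cell annotation table
#'
#' TSV with at least `cell_id` and `condition` columns; `donor_id`, `sex`,
#' `cell_type`, `subcluster` are carried through when present.
#'
#' @param path TSV path.
#' @return A tibble, one row per cell.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("cell_id", "condition")
  miss <- setdiff(req, names(ann))
  if (length(miss)) abort(paste0("annotation missing column(s): ", paste(miss, collapse = ", ")))
  if (anyNA(ann$condition)) abort("annotation has cells with missing condition")
  as_tibble(ann)
}

#' Write a result table as TSV
#'
#' Fixed column order as given; doubles rendered at 6 significant digits.
#'
#' @param x Data frame (labels, markers, composition, ...).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- signif(x[[j]], 6L)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: term, description, member genes. Symbols are uppercased;
#' empty sets are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (term -> gene symbols).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
  }
  sets <- lapply(sets, function(g) unique(toupper(trimws(g[nzchar(g)]))))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn(sprintf("dropped %d empty gene set(s)", sum(empty)))
    sets <- sets[!empty]
  }
  sets
}
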