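#' Load a curated gene panel from a one-column text file
#'
#' Reads gene symbols from the first column of a TSV/CSV file (one symbol per
#' row, optional header), uppercases and deduplicates them, and returns a
#' `gene_panel` object. The packaged chromatin-structure panel can be loaded
#' with [chromatin_panel()].
#'
#' @param path Path to a single-column (or first-column) TSV/CSV file.
#' @param source_label Free-text provenance recorded on the panel.
#' @return A `gene_panel`: a character vector of unique uppercase symbols with
#'   a `source_label` attribute.
#' @export
#' @examples
#' p <- chromatin_panel()
#' length(p)
load_panel <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(paste0("panel file is empty: ", path))
  }
  # first column of comma- or tab-separated rows
  sym <- vapply(strsplit(lines, "[\t,]"), function(x) trimws(x[[1L]]), character(1))
  # drop a header row: common column-name tokens, never a gene symbol
  if (tolower(sym[1L]) %in% c("gene", "symbol", "gene_symbol", "genes", "gene.symbol")) {
    sym <- sym[-1L]
  }
  sym <- toupper(sym)
  sym <- sym[nzchar(sym)]
  if (length(sym) == 0L) {
    abort(paste0("no valid gene symbols in panel file: ", path))
  }
  n_dup <- sum(duplicated(sym))
  if (n_dup > 0L) {
    warn(sprintf("panel file contains %d duplicate symbol(s) after uppercasing; deduplicated", n_dup))
  }
  sym <- unique(sym)
  inform(sprintf("loaded gene panel '%s': %d symbols", source_label, length(sym)))
  new_gene_panel(sym, source_label)
}

new_gene_panel <- function(symbols, source_label) {
  structure(symbols, class = "gene_panel", source_label = source_label)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d symbols (source: %s)\n",
              length(x), attr(x, "source_label") %||% "unknown"))
  cat(" ", paste(head(unclass(x), 8L), collapse = ", "),
      if (length(x) > 8L) "..." else "", "\n")
  invisible(x)
}

#' The packaged chromatin-structure gene panel
#'
#' Loads the chromatin structural gene panel shipped with the package:
#' a synthetic stand-in for the curated 892-gene table of chromatin
#' remodellers and genome-topology regulators. Its core is a set of canonical
#' human chromatin-regulator symbols (SWI/SNF, ISWI/CHD/INO80/NuRD
#' remodellers, histone writers/erasers/readers, DNA-methylation machinery,
#' cohesin/condensin/CTCF, nuclear lamina), padded with placeholder symbols
#' (`CSR0001`...) to the reference size of 892.
#'
#' @return A `gene_panel` of 892 symbols.
#' @export
chromatin_panel <- function() {
  path <- system.file("extdata", "chromatin_panel_synthetic.tsv",
                      package = "chromastrat", mustWork = TRUE)
  suppressMessages(load_panel(path, source_label = "chromatin_panel_synthetic"))
}

#' Default sex-biased gene exclusion list
#'
#' Genes with strong donor-sex bias that are routinely removed before
#' embedding and marker testing, so clusters do not form along donor sex.
#'
#' @param extra Additional symbols to exclude.
#' @return Character vector of uppercase symbols.
#' @export
default_exclusion_list <- function(extra = character()) {
  unique(toupper(c("XIST", "UTY", "KDM5D", extra)))
}

#' Restrict an expression matrix to a gene panel
#'
#' Keeps only the rows (genes) whose symbols appear in `panel`, preserving the
#' matrix's row order. Counts of retained genes are untouched.
#'
#' @param matrix Sparse genes-by-cells count matrix with gene symbols as
#'   rownames.
#' @param panel A `gene_panel` or character vector of symbols.
#' @return The row-subset matrix.
#' @export
restrict_to_panel <- function(matrix, panel) {
  stopifnot(!is.null(rownames(matrix)))
  panel <- toupper(as.character(panel))
  keep <- toupper(rownames(matrix)) %in% panel
  if (!any(keep)) {
    abort("no overlap between panel and matrix gene symbols; check symbol namespaces")
  }
  n_absent <- length(setdiff(panel, toupper(rownames(matrix))))
  inform(sprintf("panel restriction: kept %d/%d genes; %d panel symbols absent from matrix",
                 sum(keep), nrow(matrix), n_absent))
  matrix[keep, , drop = FALSE]
}

#' Remove excluded genes from an expression matrix
#'
#' Drops rows named in the exclusion list (case-insensitive). Idempotent;
#' symbols absent from the matrix are ignored.
#'
#' @param matrix Genes-by-cells matrix with rownames.
#' @param excl Character vector of symbols to remove
#'   (default [default_exclusion_list()]).
#' @return The matrix without the excluded rows.
#' @export
exclude_genes <- function(matrix, excl = default_exclusion_list()) {
  stopifnot(!is.null(rownames(matrix)))
  excl <- toupper(as.character(excl))
  drop <- toupper(rownames(matrix)) %in% excl
  if (any(drop)) {
    inform(sprintf("excluded %d gene(s): %s", sum(drop),
                   paste(rownames(matrix)[drop], collapse = ", ")))
  }
  matrix[!drop, , drop = FALSE]
}
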