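#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's pipeline functions.
#
#   Rscript scripts/run_pipeline.R simulate --outdir cohort [--seed 1]
#   Rscript scripts/run_pipeline.R run-all --matrix cohort/matrix \
#       --annotation cohort/annotation.tsv [--panel panel.tsv] [--gmt sets.gmt] \
#       [--truth cohort/truth_genes.tsv] --outdir results [--seed 1]

suppressPackageStartupMessages(library(chromastrat))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("subcommand required: simulate | run-all")
cmd <- args[[1L]]
kv <- list()
i <- 2L
while (i < length(args) + 1L) {
  key <- sub("^--", "", args[[i]])
  kv[[key]] <- if (i + 1L <= length(args)) args[[i + 1L]] else NA
  i <- i + 2L
}
`%||%` <- function(a, b) if (is.null(a)) b else a
seed <- as.integer(kv$seed %||% 1L)

if (cmd == "simulate") {
  outdir <- kv$outdir %||% "cohort"
  simulate_cohort_files(outdir, default_config(seed = seed))
  message("cohort written to ", outdir)
} else if (cmd == "run-all") {
  cfg <- run_config(
    matrix = kv$matrix, annotation = kv$annotation,
    panel = kv$panel, gmt = kv$gmt, truth_genes = kv$truth,
    outdir = kv$outdir %||% "chromastrat_run", seed = seed)
  run_pipeline(cfg)
} else {
  stop("unknown subcommand: ", cmd)
}
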