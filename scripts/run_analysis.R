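#!/usr/bin/env Rscript
# Thin command-line wrapper around nucdeg::run_full_analysis().
#
# Usage:
#   Rscript scripts/run_analysis.R --input cells.csv [--dialect csv|tsv]
#       [--seed 1] [--profile fast|full] [--outdir results/analysis]
#       [--normalize-by-size]
#
# With --simulate N, a synthetic study is generated (seed-controlled)
# instead of reading --input, and its ground truth is written alongside.

suppressPackageStartupMessages(library(nucdeg))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
has_flag <- function(flag) flag %in% args

seed <- as.integer(get_arg("--seed", "1"))
profile <- match.arg(get_arg("--profile", "fast"), c("fast", "full"))
outdir <- get_arg("--outdir", "results/analysis")
dialect <- match.arg(get_arg("--dialect", "csv"), c("csv", "tsv"))

input <- get_arg("--input")
if (has_flag("--simulate")) {
  n <- as.integer(get_arg("--simulate", "200"))
  study <- generate_study(study_design(n_per_passage = rep(n, 6L),
                                       seed = seed))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_study(study, file.path(outdir, "simulated_cells.csv"), "csv",
              truth_path = file.path(outdir, "simulated_truth.json"))
  input <- study$records
} else if (is.null(input)) {
  stop("either --input <file> or --simulate <n-per-passage> is required")
}

report <- run_full_analysis(input, dialect = dialect, seed = seed,
                            profile = profile, outdir = outdir)
print(report)
message("report written to ", outdir)
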