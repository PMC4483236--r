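#' Read single-cell fluorescence records
#'
#' Reads a table of single-cell measurements with one row per cell and the
#' four columns `nucleus_size` (nuclear area, arbitrary units),
#' `fluorescence` (raw integrated nuclear signal), `passage` (replicative
#' passage, >= 1) and `experiment` (biological replicate identifier).
#' Malformed rows (non-numeric or non-positive fluorescence or nucleus size,
#' passage < 1) are dropped with a warning naming their 1-based data row
#' numbers.
#'
#' @param source Path to a delimited text file with a header row.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A `data.frame` of class `cell_records` with the four columns in
#'   canonical order.
#' @export
read_records <- function(source, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(source))
    stop_nucdeg(sprintf("input file not found: %s", source), "nucdeg_io_error")
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "")
  required <- c("nucleus_size", "fluorescence", "passage", "experiment")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop_nucdeg(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "nucdeg_schema_error")
  if (nrow(raw) == 0L)
    stop_nucdeg("input file contains no data rows", "nucdeg_schema_error")
  raw <- raw[required]

  ns <- suppressWarnings(as.numeric(raw$nucleus_size))
  fl <- suppressWarnings(as.numeric(raw$fluorescence))
  ps <- suppressWarnings(as.numeric(raw$passage))
  bad <- !is.finite(ns) | !is.finite(fl) | !is.finite(ps) |
    ns <= 0 | fl <= 0 | ps < 1 | ps != floor(ps)
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s): %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
  }
  if (all(bad))
    stop_nucdeg("no valid rows after validation", "nucdeg_schema_error")
  out <- data.frame(nucleus_size = ns[!bad], fluorescence = fl[!bad],
                    passage = as.integer(ps[!bad]),
                    experiment = as.character(raw$experiment)[!bad],
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_records", "data.frame")
  out
}

as_cell_records <- function(x) {
  required <- c("nucleus_size", "fluorescence", "passage", "experiment")
  if (!is.data.frame(x) || !all(required %in% names(x)))
    stop_nucdeg("expected a data.frame with columns nucleus_size, fluorescence, passage, experiment",
                "nucdeg_schema_error")
  if (!inherits(x, "cell_records")) class(x) <- c("cell_records", class(x))
  x
}

#' Rescale fluorescence to integer counts on a common support
#'
#' Maps raw integrated fluorescence linearly onto integer counts in
#' `[0, max_count]`, assigning `max_count` to the highest observed value
#' across ALL experiments and passages and scaling every other value
#' accordingly; values are then rounded to the nearest integer (half away
#' from zero), reflecting the integer state space of the count model.
#' The default support `[0, 1000]` is the range on which the numerical
#' stationary solution is computed.
#'
#' By default the raw integrated signal is analyzed (the model describes
#' total nuclear protein amount); set `normalize_by_size = TRUE` to analyze
#' fluorescence density per unit nuclear area instead.
#'
#' @param records A `cell_records` data.frame (see [read_records()]).
#' @param max_count Upper end of the count support; default 1000.
#' @param normalize_by_size Divide fluorescence by `nucleus_size` before
#'   scaling; default `FALSE`.
#' @return An object of class `scaled_dataset`: list with integer vector
#'   `counts`, aligned `passage` and `experiment` labels, `scale_factor`
#'   (raw units per count) and `max_count`.
#' @export
scale_to_counts <- function(records, max_count = 1000L,
                            normalize_by_size = FALSE) {
  records <- as_cell_records(records)
  if (nrow(records) == 0L)
    stop_nucdeg("no records to scale", "nucdeg_schema_error")
  if (max_count < 1)
    stop_nucdeg("'max_count' must be >= 1", "nucdeg_invalid_params")
  signal <- records$fluorescence
  if (normalize_by_size) signal <- signal / records$nucleus_size
  if (any(signal <= 0))
    stop_nucdeg("all fluorescence signals must be positive", "nucdeg_schema_error")
  smax <- max(signal)
  counts <- as.integer(round_half_up(signal * max_count / smax))
  structure(list(counts = counts,
                 passage = as.integer(records$passage),
                 experiment = as.character(records$experiment),
                 scale_factor = smax / max_count,
                 max_count = as.integer(max_count)),
            class = "scaled_dataset")
}

#' @export
print.scaled_dataset <- function(x, ...) {
  cat(sprintf("Scaled single-cell dataset: %d cells on [0, %d] (%.4g raw units/count)\n",
              length(x$counts), x$max_count, x$scale_factor))
  tab <- table(x$passage)
  cat("  cells per passage:",
      paste(sprintf("p%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Select the counts of one passage
#'
#' @param dataset A [scale_to_counts()] result.
#' @param passage Passage number to select.
#' @param experiment Experiment identifier, or `"all"` (default) for the
#'   pooled union of all experiments at that passage.
#' @return Integer count vector.
#' @export
select_passage <- function(dataset, passage, experiment = "all") {
  stopifnot(inherits(dataset, "scaled_dataset"))
  keep <- dataset$passage == passage
  if (!identical(experiment, "all"))
    keep <- keep & dataset$experiment == as.character(experiment)
  if (!any(keep))
    stop_nucdeg(sprintf("no cells for passage %s (experiment %s)",
                        passage, experiment), "nucdeg_empty_selection")
  dataset$counts[keep]
}

#' Write a scaled dataset back to CSV
#'
#' @param dataset A `scaled_dataset`.
#' @param path Output CSV path (columns count, passage, experiment).
#' @return `path`, invisibly.
#' @export
write_scaled_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "scaled_dataset"))
  utils::write.csv(
    data.frame(count = dataset$counts, passage = dataset$passage,
               experiment = dataset$experiment),
    path, row.names = FALSE)
  invisible(path)
}
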