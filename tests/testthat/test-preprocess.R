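# Reading the single-cell table and rescaling fluorescence to counts.

make_table <- function(path, rows, sep = ",") {
  header <- paste(c("nucleus_size", "fluorescence", "passage", "experiment"),
                  collapse = sep)
  writeLines(c(header, vapply(rows, paste, "", collapse = sep)), path)
}

test_that("well-formed tables are read; malformed rows are dropped with diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  make_table(path, list(c(100, 5000, 3, "exp1"),
                        c(120, 6000, 3, "exp1"),
                        c(90, 4500, 9, "exp2")), sep = "\t")
  rec <- read_records(path, "tsv")
  expect_s3_class(rec, "cell_records")
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$passage, c(3L, 3L, 9L))

  path2 <- withr::local_tempfile(fileext = ".csv")
  make_table(path2, list(c(100, 5000, 3, "exp1"),
                         c(120, -1, 3, "exp1"),       # negative fluorescence
                         c(90, "abc", 9, "exp2"),     # non-numeric
                         c(80, 4000, 9, "exp2")))
  expect_warning(rec2 <- read_records(path2, "csv"), "2, 3")
  expect_identical(nrow(rec2), 2L)

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("nucleus_size,fluorescence,passage", path3)
  expect_error(read_records(path3, "csv"), class = "nucdeg_schema_error")
  expect_error(read_records(file.path(tempdir(), "nope.csv"), "csv"),
               class = "nucdeg_io_error")
})

test_that("scaling assigns max_count to the global maximum and is linear", {
  rec <- data.frame(nucleus_size = rep(100, 4),
                    fluorescence = c(2500, 5000, 10000, 1),
                    passage = c(3L, 3L, 9L, 9L),
                    experiment = c("a", "a", "b", "b"))
  ds <- scale_to_counts(rec, max_count = 1000)
  expect_identical(ds$counts, c(250L, 500L, 1000L, 0L))
  expect_equal(ds$scale_factor, 10)

  # units invariance: multiplying all signals by a constant changes nothing
  rec2 <- rec; rec2$fluorescence <- rec2$fluorescence * 37.3
  expect_identical(scale_to_counts(rec2, 1000)$counts, ds$counts)

  # rank order preserved under random inputs
  set.seed(5)
  recr <- data.frame(nucleus_size = rep(1, 200),
                     fluorescence = rlnorm(200, 8, 1),
                     passage = 1L, experiment = "a")
  cr <- scale_to_counts(recr, 1000)$counts
  expect_true(all(diff(cr[order(recr$fluorescence)]) >= 0))

  # idempotence on already-scaled data sharing the same maximum
  rec3 <- data.frame(nucleus_size = 1, fluorescence = as.numeric(ds$counts + 1e-9),
                     passage = 1L, experiment = "a")[ds$counts > 0, ]
  expect_identical(scale_to_counts(rec3, 1000)$counts,
                   ds$counts[ds$counts > 0])
})

test_that("rounding is half away from zero and density mode divides by area", {
  rec <- data.frame(nucleus_size = c(2, 1), fluorescence = c(15, 40),
                    passage = 1L, experiment = "a")
  # 15 * 1000/40 = 375; with density normalization 7.5 vs 40 -> ratio 0.1875
  expect_identical(scale_to_counts(rec, 1000)$counts, c(375L, 1000L))
  dens <- scale_to_counts(rec, 1000, normalize_by_size = TRUE)
  expect_identical(dens$counts, c(188L, 1000L))  # 187.5 rounds up, not to even
})

test_that("passage selection filters and pools experiments", {
  study <- generate_study(small_design(seed = 3))
  ds <- scale_to_counts(study$records)
  p3 <- select_passage(ds, 3)
  expect_length(p3, 120L)
  per_exp <- vapply(paste0("exp", 1:3),
                    function(e) length(select_passage(ds, 3, e)), 0L)
  expect_identical(sum(per_exp), length(p3))
  expect_error(select_passage(ds, 99), class = "nucdeg_empty_selection")
  expect_error(select_passage(ds, 3, "exp9"), class = "nucdeg_empty_selection")
})

test_that("a generated study round-trips through write and read", {
  study <- generate_study(small_design(seed = 8, n = 40))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_study(study, path, "tsv")
  rec <- read_records(path, "tsv")
  expect_identical(nrow(rec), nrow(study$records))
  expect_equal(rec$fluorescence, study$records$fluorescence, tolerance = 1e-6)
  expect_identical(rec$passage, study$records$passage)
})
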