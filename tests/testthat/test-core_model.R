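test_that("taxon table reader parses counts and enforces the contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_toy_taxon_tsv(f)
  mat <- read_taxon_table(f)
  expect_equal(dim(mat), c(3L, 4L))
  expect_equal(unname(colSums(mat)), rep(100, 4))
  expect_equal(rownames(mat), c("taxA", "taxB", "taxC"))

  # duplicated sample header names the duplicate
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_toy_taxon_tsv(f2, header = c("taxon_id", "s1", "s2", "s2", "s4"))
  expect_error(read_taxon_table(f2), "duplicate sample.*s2")

  # transposed orientation is recognized through the header
  f3 <- withr::local_tempfile(fileext = ".tsv")
  tmat <- t(mat)
  df <- data.frame(sample_id = rownames(tmat), tmat, check.names = FALSE)
  write.table(df, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_taxon_table(f3), mat)

  # unrecognizable orientation is an error, not a guess
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu\ts1\ts2", "a\t1\t2", "b\t3\t4"), f4)
  expect_error(read_taxon_table(f4), "taxon_id")
})

test_that("all-zero and negative columns are rejected at load", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\t0", "b\t2\t0"), f)
  expect_error(read_taxon_table(f), "all-zero sample.*s2")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\t-3", "b\t2\t5"), f2)
  expect_error(read_taxon_table(f2), "negative")
})

test_that("taxon table round-trips bit-exactly for integer counts", {
  mat <- matrix(c(10, 0, 5, 5, 0, 0, 0, 1, 90, 100, 95, 94),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxon_table(mat, f)
  expect_identical(read_taxon_table(f), mat)
})

test_that("metadata reader groups by patient, sorts by date, and flags issues", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_toy_metadata_csv(f)
  md <- read_sample_metadata(f)
  expect_equal(unique(md$patient_id), c("P1", "P2"))
  expect_true(all(tapply(md$date, md$patient_id,
                         function(d) all(diff(d) > 0))))
  expect_s3_class(md$date, "Date")

  # unknown disease state cites the offending row
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_metadata_csv(f2, rows = c("P1,s1,2014-01-01,55,B0,,",
                                      "P1,s2,2014-02-01,54,X,,",
                                      "P1,s3,2014-03-01,53,B0,,"))
  expect_error(read_sample_metadata(f2), "disease_state.*'X'.*2")

  # unparsable date cites the row number
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_toy_metadata_csv(f3, rows = c("P1,s1,2014-01-01,55,B0,,",
                                      "P1,s2,01/02/2014,54,B0,,"))
  expect_error(read_sample_metadata(f3), "date.*2")

  # out-of-order rows come back sorted, with a warning
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_toy_metadata_csv(f4, rows = c("P1,s2,2014-02-01,54,B0,,",
                                      "P1,s1,2014-01-01,55,B0,,",
                                      "P1,s3,2014-03-01,53,B0,,"))
  expect_warning(md4 <- read_sample_metadata(f4), "not sorted")
  expect_equal(md4$sample_id, c("s1", "s2", "s3"))

  # missing %FEV1 is allowed and flagged
  f5 <- withr::local_tempfile(fileext = ".csv")
  write_toy_metadata_csv(f5, rows = c("P1,s1,2014-01-01,,B0,,",
                                      "P1,s2,2014-02-01,54,B0,,"))
  expect_message(md5 <- read_sample_metadata(f5), "missing %FEV1")
  expect_true(is.na(md5$fev1_percent[1]))
})

test_that("assembly normalizes columns and enforces alignment invariants", {
  mat <- matrix(c(10, 0, 90, 20, 20, 60), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  md <- data.frame(patient_id = "P1", sample_id = c("s1", "s2"),
                   date = as.Date(c("2014-01-01", "2014-02-01")),
                   fev1_percent = c(50, 51), disease_state = c("B0", "B0"),
                   treatment_start = as.Date(NA), treatment_end = as.Date(NA),
                   stringsAsFactors = FALSE)
  series <- assemble_patient_series(mat, md)
  expect_named(series, "P1")
  expect_equal(unname(series$P1$abundance[, "s1"]), c(0.1, 0.0, 0.9))
  expect_equal(unname(colSums(series$P1$abundance)), c(1, 1))

  # orphan samples on either side are listed
  expect_error(assemble_patient_series(mat[, 1, drop = FALSE], md),
               "s2")
  expect_error(assemble_patient_series(mat, md[1, , drop = FALSE]),
               "s2")
})

test_that("T-labelled samples outside the treatment window are rejected", {
  mat <- matrix(c(1, 1, 1), nrow = 1,
                dimnames = list("a", c("s1", "s2", "s3")))
  origin <- as.Date("2014-01-01")
  md <- data.frame(patient_id = "P1", sample_id = c("s1", "s2", "s3"),
                   date = origin + c(0, 30, 60),
                   fev1_percent = NA_real_,
                   disease_state = c("B0", "E", "T"),
                   treatment_start = origin + 40,
                   treatment_end = origin + 55,
                   stringsAsFactors = FALSE)
  expect_error(assemble_patient_series(mat, md),
               "labelled T fall outside")
  md$treatment_end <- origin + 65
  expect_silent(assemble_patient_series(mat, md))
})

test_that("a full synthetic cohort round-trips through write/read/assemble", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_params(), seed = 7, output_dir = dir)
  mats <- lapply(names(coh$series), function(pid) {
    read_taxon_table(file.path(dir, paste0("taxon_table_", pid, ".tsv")))
  })
  names(mats) <- names(coh$series)
  md <- suppressMessages(read_sample_metadata(file.path(dir, "metadata.csv")))
  for (pid in names(coh$series)) {
    rebuilt <- assemble_patient_series(
      mats[[pid]], md[md$patient_id == pid, , drop = FALSE])[[pid]]
    expect_equal(rebuilt$abundance, coh$series[[pid]]$abundance,
                 tolerance = 1e-12)
    expect_identical(rebuilt$sample_dates, coh$series[[pid]]$sample_dates)
    expect_identical(rebuilt$disease_state, coh$series[[pid]]$disease_state)
  }
})

test_that("normalization conserves presence/absence at threshold zero", {
  set.seed(11)
  for (rep in 1:20) {
    raw <- matrix(rpois(60, 2) * runif(60), nrow = 6)
    raw[, colSums(raw) == 0] <- 1  # keep columns valid
    rownames(raw) <- paste0("t", 1:6)
    s <- make_series(raw)
    expect_identical(unname(presence_matrix(s, 0)), unname(raw > 0))
  }
})
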