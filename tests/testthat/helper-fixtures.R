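# In-code fixture builders shared across the suite.

# A patient series built directly from an abundance matrix and day offsets.
make_series <- function(abundance, days = NULL, patient_id = "PX",
                        fev1 = NULL, states = NULL,
                        treatment_start = as.Date(NA),
                        treatment_end = as.Date(NA)) {
  abundance <- as.matrix(abundance)
  n <- ncol(abundance)
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- sprintf("T%02d", seq_len(nrow(abundance)))
  }
  if (is.null(days)) days <- seq_len(n) * 14 - 14
  origin <- as.Date("2014-01-01")
  patient_series(
    patient_id = patient_id,
    sample_ids = sprintf("%s_S%02d", patient_id, seq_len(n)),
    sample_dates = origin + days,
    abundance = abundance,
    fev1_percent = if (is.null(fev1)) rep(NA_real_, n) else fev1,
    disease_state = if (is.null(states)) rep("B0", n) else states,
    treatment_start = treatment_start,
    treatment_end = treatment_end)
}

# Independent oracle for the moving-window STR: exhaustive window
# enumeration with set unions, no shared code with the implementation.
oracle_moving_window <- function(presence) {
  n <- ncol(presence)
  sapply(seq_len(n), function(L) {
    mean(sapply(seq_len(n - L + 1), function(s) {
      length(Reduce(union, lapply(s:(s + L - 1),
                                  function(j) which(presence[, j]))))
    }))
  })
}

# Independent OLS oracle via the normal equations (no lm).
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  f <- (ss_tot - ss_res) / (ss_res / (n - 2))
  list(slope = slope, intercept = intercept, r_squared = r2,
       f_statistic = f, p_value = pf(f, 1, n - 2, lower.tail = FALSE))
}

# Direct rank-formula oracle for tie-corrected Kruskal-Wallis H.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, 1L)
  gid <- rep(seq_along(groups), sizes)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, gid, sum)^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Direct rank-formula oracle for Dunn z of one pair.
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, 1L)
  gid <- rep(seq_along(groups), sizes)
  ties <- table(x)
  v <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  unname((mean(r[gid == i]) - mean(r[gid == j])) /
           sqrt(v * (1 / sizes[i] + 1 / sizes[j])))
}

# A small on-disk cohort for reader tests: 3 taxa x 4 samples, counts.
write_toy_taxon_tsv <- function(path,
                                header = c("taxon_id", "s1", "s2", "s3", "s4")) {
  lines <- c(paste(header, collapse = "\t"),
             "taxA\t10\t0\t5\t5",
             "taxB\t0\t0\t0\t1",
             "taxC\t90\t100\t95\t94")
  writeLines(lines, path)
  path
}

write_toy_metadata_csv <- function(path, rows = NULL) {
  hdr <- "patient_id,sample_id,date,fev1_percent,disease_state,treatment_start,treatment_end"
  if (is.null(rows)) {
    rows <- c(
      "P1,s1,2014-01-01,55.0,B0,,",
      "P1,s2,2014-02-01,54.0,B0,,",
      "P2,s3,2014-01-05,40.0,B0,,",
      "P2,s4,2014-03-05,41.0,B0,,")
  }
  writeLines(c(hdr, rows), path)
  path
}

small_params <- function(...) {
  generator_params(n_patients = 4L, no_pex_patients = 3L, ...)
}
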