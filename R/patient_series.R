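#' Construct a patient series
#'
#' A `patient_series` holds one patient's time-ordered samples: a taxon-by-
#' sample relative-abundance matrix, the sample dates, per-sample %FEV1
#' (possibly missing) and BETR disease states, and optional treatment dates.
#' Columns of `abundance` are normalized to sum to one. This constructor
#' validates all invariants; most users will build series via
#' [assemble_patient_series()] or [generate_patient()].
#'
#' @param patient_id Patient identifier (scalar character).
#' @param sample_ids Character vector of sample identifiers, one per column.
#' @param sample_dates `Date` vector, strictly increasing.
#' @param abundance Numeric taxa-by-samples matrix of non-negative values;
#'   columns are normalized to relative abundance.
#' @param fev1_percent Numeric vector of %FEV1 predicted per sample (`NA`
#'   allowed).
#' @param disease_state Character vector of BETR labels (B0, E, T, R, B1).
#' @param treatment_start,treatment_end Optional `Date` scalars (or `NA`).
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, sample_ids, sample_dates, abundance,
                           fev1_percent = rep(NA_real_, length(sample_ids)),
                           disease_state = rep("B0", length(sample_ids)),
                           treatment_start = as.Date(NA),
                           treatment_end = as.Date(NA)) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  colnames(abundance) <- sample_ids
  sums <- colSums(abundance)
  if (any(sums == 0)) {
    stop("patient ", patient_id, ": all-zero sample column(s) ",
         paste(sample_ids[sums == 0], collapse = ", "), call. = FALSE)
  }
  abundance <- sweep(abundance, 2, sums, "/")
  x <- structure(
    list(patient_id = as.character(patient_id),
         sample_ids = as.character(sample_ids),
         sample_dates = as.Date(sample_dates),
         abundance = abundance,
         taxon_ids = rownames(abundance),
         fev1_percent = as.numeric(fev1_percent),
         disease_state = as.character(disease_state),
         treatment_start = as.Date(treatment_start),
         treatment_end = as.Date(treatment_end)),
    class = "patient_series")
  validate_patient_series(x)
}

#' Validate a patient series
#'
#' Checks the structural invariants: strictly increasing dates, 1:1 alignment
#' of matrix columns with samples, non-negative abundances with unit column
#' sums, known BETR labels, and consistency of T-labelled samples with the
#' treatment window when treatment dates are present.
#'
#' @param x A `patient_series`.
#' @return `x`, invisibly, or an error.
#' @export
validate_patient_series <- function(x) {
  stopifnot(inherits(x, "patient_series"))
  n <- length(x$sample_ids)
  pid <- x$patient_id
  if (n < 1) stop("patient ", pid, ": no samples", call. = FALSE)
  if (ncol(x$abundance) != n ||
      !identical(colnames(x$abundance), x$sample_ids)) {
    stop("patient ", pid, ": abundance columns do not align with sample_ids",
         call. = FALSE)
  }
  if (length(x$sample_dates) != n || anyNA(x$sample_dates)) {
    stop("patient ", pid, ": bad sample_dates", call. = FALSE)
  }
  if (n > 1 && any(diff(as.numeric(x$sample_dates)) <= 0)) {
    stop("patient ", pid, ": sample_dates must be strictly increasing",
         call. = FALSE)
  }
  if (any(x$abundance < 0)) {
    stop("patient ", pid, ": negative abundances", call. = FALSE)
  }
  if (any(abs(colSums(x$abundance) - 1) > 1e-9)) {
    stop("patient ", pid, ": columns not normalized to 1", call. = FALSE)
  }
  if (length(x$fev1_percent) != n || length(x$disease_state) != n) {
    stop("patient ", pid, ": clinical vectors do not align with samples",
         call. = FALSE)
  }
  if (any(!(x$disease_state %in% .betr_states))) {
    stop("patient ", pid, ": unknown disease_state label(s)", call. = FALSE)
  }
  if (!is.na(x$treatment_start) && !is.na(x$treatment_end)) {
    if (x$treatment_end < x$treatment_start) {
      stop("patient ", pid, ": treatment_end precedes treatment_start",
           call. = FALSE)
    }
    t_idx <- which(x$disease_state == "T")
    bad <- t_idx[x$sample_dates[t_idx] < x$treatment_start |
                 x$sample_dates[t_idx] > x$treatment_end]
    if (length(bad) > 0) {
      stop("patient ", pid, ": sample(s) ",
           paste(x$sample_ids[bad], collapse = ", "),
           " labelled T fall outside [treatment_start, treatment_end]",
           call. = FALSE)
    }
  } else if (any(x$disease_state == "T")) {
    stop("patient ", pid, ": T-labelled samples but no treatment dates",
         call. = FALSE)
  }
  invisible(x)
}

#' Elapsed days since a patient's first sample
#'
#' Day 0 is the patient's first sample date; dates, not sample indices, are
#' authoritative for elapsed-time computations.
#'
#' @param series A `patient_series`.
#' @return Numeric vector of elapsed days, starting at 0.
#' @export
elapsed_days <- function(series) {
  as.numeric(series$sample_dates - series$sample_dates[1])
}

#' Presence/absence matrix of a patient series
#'
#' Presence means relative abundance strictly greater than
#' `presence_threshold` (default 0).
#'
#' @param series A `patient_series`.
#' @param presence_threshold Detection floor on relative abundance.
#' @return Logical taxa-by-samples matrix.
#' @export
presence_matrix <- function(series, presence_threshold = 0) {
  series$abundance > presence_threshold
}

#' @export
print.patient_series <- function(x, ...) {
  n <- length(x$sample_ids)
  cat(sprintf("<patient_series> %s: %d taxa x %d samples over %d days\n",
              x$patient_id, nrow(x$abundance), n,
              as.integer(diff(range(x$sample_dates)))))
  cat(sprintf("  states: %s; treated: %s\n",
              paste(rle(x$disease_state)$values, collapse = "-"),
              if (is.na(x$treatment_start)) "no" else
                format(x$treatment_start)))
  invisible(x)
}

#' Assemble per-patient series from a taxon table and metadata
#'
#' Joins a taxon-by-sample matrix (typically from [read_taxon_table()]) with
#' per-sample clinical metadata ([read_sample_metadata()]), normalizes each
#' sample to relative abundance, and returns one validated
#' [patient_series()] per patient. Every metadata sample must appear in the
#' matrix and vice versa; orphans on either side are an error.
#'
#' @param mat Numeric taxa-by-samples matrix (counts or proportions).
#' @param metadata Data.frame from [read_sample_metadata()].
#' @param config A [cohort_config()] (currently unused beyond validation,
#'   kept for interface stability).
#' @return Named list of `patient_series`, one per patient.
#' @export
assemble_patient_series <- function(mat, metadata, config = cohort_config()) {
  validate_cohort_config(config)
  mat <- validate_taxon_matrix(mat)
  orphan_meta <- setdiff(metadata$sample_id, colnames(mat))
  orphan_mat <- setdiff(colnames(mat), metadata$sample_id)
  if (length(orphan_meta) > 0 || length(orphan_mat) > 0) {
    stop("sample mismatch between matrix and metadata; in metadata only: [",
         paste(orphan_meta, collapse = ", "), "]; in matrix only: [",
         paste(orphan_mat, collapse = ", "), "]", call. = FALSE)
  }
  patients <- unique(metadata$patient_id)
  out <- lapply(patients, function(pid) {
    rows <- metadata[metadata$patient_id == pid, , drop = FALSE]
    rows <- rows[order(rows$date), , drop = FALSE]
    ts <- stats::na.omit(unique(rows$treatment_start))
    te <- stats::na.omit(unique(rows$treatment_end))
    if (length(ts) > 1 || length(te) > 1) {
      stop("patient ", pid, ": inconsistent treatment dates across samples",
           call. = FALSE)
    }
    sub <- mat[, rows$sample_id, drop = FALSE]
    patient_series(
      patient_id = pid,
      sample_ids = rows$sample_id,
      sample_dates = rows$date,
      abundance = sub,
      fev1_percent = rows$fev1_percent,
      disease_state = rows$disease_state,
      treatment_start = if (length(ts) == 1) ts else as.Date(NA),
      treatment_end = if (length(te) == 1) te else as.Date(NA))
  })
  names(out) <- patients
  out
}
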