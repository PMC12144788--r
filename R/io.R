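#' Read a taxon-by-sample abundance table
#'
#' Accepts either a TSV file whose first column is `taxon_id` and whose
#' remaining columns are sample IDs, or a BIOM-format JSON file (read through
#' the biomformat package). Values may be counts or proportions; they must be
#' numeric and non-negative. A file whose first header cell is `sample_id`
#' is taken to be transposed (samples in rows) and is flipped to the canonical
#' taxa-by-samples orientation; any other first header cell is an error.
#'
#' @param path Path to the table.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return A numeric matrix, taxa in rows, samples in columns, with unique
#'   dimnames.
#' @export
read_taxon_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
    storage.mode(mat) <- "double"
    return(validate_taxon_matrix(mat, path))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    stop("taxon table must have at least one sample column: ", path,
         call. = FALSE)
  }
  transposed <- FALSE
  if (identical(header[1], "sample_id")) {
    transposed <- TRUE
  } else if (!identical(header[1], "taxon_id")) {
    stop("first header cell must be 'taxon_id' (or 'sample_id' for a ",
         "transposed table), got '", header[1], "': ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character",
                                         rep("numeric", length(header) - 1L)))
  row_ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  colnames(mat) <- header[-1]  # read.delim may mangle duplicates; restore
  rownames(mat) <- row_ids
  if (transposed) mat <- t(mat)
  validate_taxon_matrix(mat, path)
}

validate_taxon_matrix <- function(mat, path = "<matrix>") {
  dup_taxa <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup_taxa) > 0) {
    stop("duplicate taxon labels in ", path, ": ",
         paste(dup_taxa, collapse = ", "), call. = FALSE)
  }
  dup_samples <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(dup_samples) > 0) {
    stop("duplicate sample labels in ", path, ": ",
         paste(dup_samples, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(mat) || anyNA(mat)) {
    stop("non-numeric or missing abundance values in ", path, call. = FALSE)
  }
  if (any(mat < 0)) stop("negative abundance values in ", path, call. = FALSE)
  zero_cols <- colnames(mat)[colSums(mat) == 0]
  if (length(zero_cols) > 0) {
    stop("all-zero sample column(s) in ", path, ": ",
         paste(zero_cols, collapse = ", "), call. = FALSE)
  }
  mat
}

#' Write a taxon-by-sample table as TSV
#'
#' Inverse of [read_taxon_table()] for the TSV format: integer counts
#' round-trip bit-exactly and doubles round-trip to full precision.
#'
#' @param mat Numeric matrix, taxa in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(taxon_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("taxon_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.betr_states <- c("B0", "E", "T", "R", "B1")

#' Read per-sample clinical metadata
#'
#' Expects a CSV with columns `patient_id, sample_id, date, fev1_percent,
#' disease_state, treatment_start, treatment_end`. Dates are ISO 8601
#' (`YYYY-MM-DD`); empty strings mean missing. `fev1_percent` may be missing
#' per sample (flagged with a message); `disease_state` must be one of the
#' BETR labels B0, E, T, R, B1. Records are returned grouped by patient and
#' sorted by date within patient; out-of-order input is reordered with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with parsed columns (`date`, `treatment_start`,
#'   `treatment_end` as `Date`, `fev1_percent` numeric).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  required <- c("patient_id", "sample_id", "date", "fev1_percent",
                "disease_state", "treatment_start", "treatment_end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_date_col <- function(x, col) {
    x[!nzchar(x)] <- NA_character_
    out <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop("unparsable ", col, " in metadata row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out
  }
  df$date <- parse_date_col(df$date, "date")
  if (anyNA(df$date)) {
    stop("missing sample date in metadata row(s) ",
         paste(which(is.na(df$date)), collapse = ", "), call. = FALSE)
  }
  df$treatment_start <- parse_date_col(df$treatment_start, "treatment_start")
  df$treatment_end <- parse_date_col(df$treatment_end, "treatment_end")
  bad_state <- which(!(df$disease_state %in% .betr_states))
  if (length(bad_state) > 0) {
    stop("unknown disease_state label(s) '",
         paste(unique(df$disease_state[bad_state]), collapse = "', '"),
         "' in metadata row(s) ", paste(bad_state, collapse = ", "),
         call. = FALSE)
  }
  fev <- df$fev1_percent
  fev[!nzchar(fev)] <- NA_character_
  fev_num <- suppressWarnings(as.numeric(fev))
  bad_fev <- which(!is.na(fev) & is.na(fev_num))
  if (length(bad_fev) > 0) {
    stop("non-numeric fev1_percent in metadata row(s) ",
         paste(bad_fev, collapse = ", "), call. = FALSE)
  }
  df$fev1_percent <- fev_num
  if (anyNA(fev_num)) {
    message(sum(is.na(fev_num)), " sample(s) have missing %FEV1; they are ",
            "kept for microbiota analyses and skipped in lung-function fits")
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id(s) in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(match(df$patient_id, unique(df$patient_id)), df$date)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("metadata rows were not sorted by date within patient; reordering",
            call. = FALSE)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write per-sample clinical metadata as CSV
#'
#' Inverse of [read_sample_metadata()]; `NA` dates and %FEV1 are written as
#' empty strings.
#'
#' @param metadata Data.frame as returned by [read_sample_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  out <- metadata
  for (col in c("date", "treatment_start", "treatment_end")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], "%Y-%m-%d"))
  }
  out$fev1_percent <- ifelse(is.na(out$fev1_percent), "",
                             format(out$fev1_percent, digits = 10,
                                    trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
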