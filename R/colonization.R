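#' Temporal persistence and colonization status of every detected taxon
#'
#' For each taxon detected at least once in the series, computes its temporal
#' persistence (fraction of samples in which it is present) and its mean
#' relative abundance across the samples where it is detected, and labels it
#' chronic or intermittent by a modified Leeds criterion: chronic if its
#' persistence strictly exceeds `chronic_persistence_cutoff` (default 0.5),
#' intermittent otherwise. Ties at exactly the cutoff are intermittent.
#' Persistence is always computed over the whole series; fine-scale analyses
#' reuse these whole-series labels.
#'
#' @param series A [patient_series()] with at least 2 samples.
#' @param config A [cohort_config()]; uses `presence_threshold` and
#'   `chronic_persistence_cutoff`.
#' @return A data.frame of class `colonization_profile` with columns
#'   `taxon_id`, `n_detected`, `n_samples`, `persistence`, `mean_abundance`
#'   (mean relative abundance when present), and `label`
#'   (`"chronic"`/`"intermittent"`). Taxa never detected are excluded.
#' @export
compute_persistence <- function(series, config = cohort_config()) {
  validate_patient_series(series)
  validate_cohort_config(config)
  n <- length(series$sample_ids)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  pres <- presence_matrix(series, config$presence_threshold)
  n_det <- rowSums(pres)
  keep <- n_det > 0
  ab <- series$abundance[keep, , drop = FALSE]
  pres <- pres[keep, , drop = FALSE]
  n_det <- n_det[keep]
  mean_ab <- rowSums(ab * pres) / n_det
  persistence <- n_det / n
  out <- data.frame(
    taxon_id = rownames(ab),
    n_detected = as.integer(n_det),
    n_samples = n,
    persistence = persistence,
    mean_abundance = mean_ab,
    label = ifelse(persistence > config$chronic_persistence_cutoff,
                   "chronic", "intermittent"),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("colonization_profile", "data.frame")
  out
}

#' Fit the persistence-abundance relationship (PAR)
#'
#' Ordinary least squares of log10 mean relative abundance (when present) on
#' temporal persistence. Abundance spans orders of magnitude while persistence
#' is a bounded fraction, hence the one-sided log transform; set
#' `log_persistence = TRUE` to regress on log10(persistence) instead.
#' The slope's sign is reported, not assumed.
#'
#' @param profiles A `colonization_profile` data.frame with >= 3 taxa.
#' @param log_persistence Regress on log10(persistence)? Default `FALSE`.
#' @return A [fit_linear()] result (`linear_fit`).
#' @export
fit_par <- function(profiles, log_persistence = FALSE) {
  if (nrow(profiles) < 3) {
    stop("need at least 3 taxon profiles to fit a PAR", call. = FALSE)
  }
  x <- if (log_persistence) log10(profiles$persistence) else
    profiles$persistence
  if (stats::var(x) == 0) {
    stop("zero variance in persistence: PAR slope undefined", call. = FALSE)
  }
  fit_linear(x, log10(profiles$mean_abundance))
}

#' Count chronic and intermittent taxa
#'
#' @param profiles A `colonization_profile` data.frame.
#' @return Named integer vector `c(n_chronic, n_intermittent)`; the two counts
#'   partition the detected taxa.
#' @export
count_by_label <- function(profiles) {
  c(n_chronic = sum(profiles$label == "chronic"),
    n_intermittent = sum(profiles$label == "intermittent"))
}

#' Write per-patient colonization profiles as TSV
#'
#' @param profiles A `colonization_profile` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colonization_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
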