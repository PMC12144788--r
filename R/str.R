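#' Moving-window species accumulation
#'
#' Builds the species-time relationship (STR) curve by the moving-window
#' method: for every window length L in 1..N, the mean over all N - L + 1
#' contiguous sample windows of the number of distinct taxa present at least
#' once within the window. Unlike one-direction accumulation, this captures
#' immigration of new taxa, local extinction, and recolonization of the same
#' taxa through time.
#'
#' @param presence Logical (or 0/1) taxa-by-samples matrix with N >= 2 columns
#'   and at least one `TRUE` cell.
#' @return An object of class `str_curve`: a list with `window_lengths`
#'   (1..N), `mean_richness` (non-decreasing), and `n_windows` (N - L + 1).
#' @examples
#' pres <- matrix(TRUE, nrow = 7, ncol = 5)  # static community
#' accumulate_moving_window(pres)$mean_richness
#' @export
accumulate_moving_window <- function(presence) {
  presence <- as.matrix(presence)
  if (length(presence) == 0) stop("empty presence matrix", call. = FALSE)
  mode(presence) <- "logical"
  n <- ncol(presence)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (!any(presence)) {
    stop("no taxon is present in any sample", call. = FALSE)
  }
  mean_richness <- numeric(n)
  # running per-window union maintained as a count-per-taxon matrix would be
  # overkill at these sizes; cumulative sums keep it O(taxa * N^2)
  cum <- cbind(0L, t(apply(presence, 1L, cumsum)))
  for (L in seq_len(n)) {
    starts <- seq_len(n - L + 1L)
    tot <- 0
    for (s in starts) {
      tot <- tot + sum(cum[, s + L] - cum[, s] > 0L)
    }
    mean_richness[L] <- tot / length(starts)
  }
  out <- list(window_lengths = seq_len(n),
              mean_richness = mean_richness,
              n_windows = n - seq_len(n) + 1L)
  class(out) <- "str_curve"
  out
}

#' @export
print.str_curve <- function(x, ...) {
  cat(sprintf("<str_curve> N = %d; mean richness %.2f -> %.2f\n",
              length(x$window_lengths), x$mean_richness[1],
              x$mean_richness[length(x$mean_richness)]))
  invisible(x)
}

#' Time axis for an STR fit
#'
#' Converts window lengths to the fitting time variable T. In
#' `"sample_count"` mode T is the ordinal window length L (default for whole
#' series fits: one curve per patient despite uneven sampling, and a
#' dimensionless w insensitive to sampling jitter). In `"days"` mode T(L) is
#' the mean duration spanned by the windows of length L plus one mean
#' inter-sample interval, so that T(1) equals one mean interval rather than
#' zero.
#'
#' @param curve An `str_curve`.
#' @param dates Sample dates (`Date` or numeric days), required for
#'   `"days"` mode.
#' @param unit `"sample_count"` or `"days"`.
#' @return Numeric vector of T values, one per window length.
#' @export
str_time_axis <- function(curve, dates = NULL,
                          unit = c("sample_count", "days")) {
  unit <- match.arg(unit)
  n <- length(curve$window_lengths)
  if (unit == "sample_count") return(as.numeric(seq_len(n)))
  if (is.null(dates)) stop("dates required for days mode", call. = FALSE)
  d <- as.numeric(dates)
  if (length(d) != n) stop("dates do not match curve length", call. = FALSE)
  mean_interval <- (d[n] - d[1]) / (n - 1)
  vapply(seq_len(n), function(L) {
    starts <- seq_len(n - L + 1L)
    mean(d[starts + L - 1L] - d[starts]) + mean_interval
  }, numeric(1))
}

#' Whole-series species-time relationship for a patient
#'
#' Restricts the presence matrix to the requested taxon subset (whole
#' microbiota, chronic colonizers, or intermittent colonizers, with membership
#' taken from whole-series colonization labels), accumulates richness by the
#' moving-window method, and fits the power model S = c * T^w. An empty subset
#' (e.g. a patient with no chronic taxa) yields an explicit
#' `status = "empty_subset"` result rather than an error.
#'
#' @param series A [patient_series()].
#' @param subset `"whole"`, `"chronic"`, or `"intermittent"`.
#' @param profiles Colonization profiles from [compute_persistence()];
#'   computed on the fly when `NULL`.
#' @param config A [cohort_config()]; `str_time_unit` selects the time axis.
#' @return An object of class `str_result`: list with `patient_id`, `subset`,
#'   `status` (`"ok"` or `"empty_subset"`), `curve` (`str_curve`), `time`
#'   (fitting T values), and `fit` ([fit_power()] result; `w` is
#'   `fit$exponent`).
#' @export
compute_str <- function(series, subset = c("whole", "chronic", "intermittent"),
                        profiles = NULL, config = cohort_config()) {
  subset <- match.arg(subset)
  validate_patient_series(series)
  validate_cohort_config(config)
  if (is.null(profiles)) profiles <- compute_persistence(series, config)
  taxa <- if (subset == "whole") profiles$taxon_id else
    profiles$taxon_id[profiles$label == subset]
  if (length(taxa) == 0) {
    out <- list(patient_id = series$patient_id, subset = subset,
                status = "empty_subset", curve = NULL, time = NULL, fit = NULL)
    class(out) <- "str_result"
    return(out)
  }
  pres <- presence_matrix(series, config$presence_threshold)[taxa, ,
                                                             drop = FALSE]
  curve <- accumulate_moving_window(pres)
  tt <- str_time_axis(curve, series$sample_dates, config$str_time_unit)
  fit <- fit_power(tt, curve$mean_richness)
  out <- list(patient_id = series$patient_id, subset = subset, status = "ok",
              curve = curve, time = tt, fit = fit)
  class(out) <- "str_result"
  out
}

#' @export
print.str_result <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<str_result> %s/%s: %s\n", x$patient_id, x$subset, x$status))
  } else {
    cat(sprintf("<str_result> %s/%s: w = %.3f, c = %.3f (R2 = %.3f)\n",
                x$patient_id, x$subset, x$fit$exponent, x$fit$c,
                x$fit$r_squared))
  }
  invisible(x)
}

#' Tabulate STR fits across patients and subsets
#'
#' @param results List of `str_result` objects.
#' @return Data.frame with one row per fit: `patient_id, subset, c, w, R2, F,
#'   df_num, df_den, p, n_points` (NA-filled for empty subsets).
#' @export
str_fit_table <- function(results) {
  rows <- lapply(results, function(r) {
    if (r$status != "ok") {
      data.frame(patient_id = r$patient_id, subset = r$subset,
                 c = NA_real_, w = NA_real_, R2 = NA_real_, F = NA_real_,
                 df_num = NA_integer_, df_den = NA_integer_, p = NA_real_,
                 n_points = NA_integer_, stringsAsFactors = FALSE)
    } else {
      f <- r$fit
      data.frame(patient_id = r$patient_id, subset = r$subset,
                 c = f$c, w = f$exponent, R2 = f$r_squared,
                 F = f$f_statistic, df_num = f$df_num, df_den = f$df_den,
                 p = f$p_value, n_points = f$n_points,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
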