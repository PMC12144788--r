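#' Cumulative absolute change in lung function
#'
#' Running sum of |change in %FEV1| between consecutive non-missing
#' timepoints, paired with elapsed days. Day 0 is the first sample with a
#' non-missing %FEV1; missing values are skipped, not imputed, with
#' differences bridged across the gap.
#'
#' @param fev1 Numeric vector of per-sample %FEV1 (NA = missing).
#' @param dates `Date` (or numeric day) vector aligned with `fev1`.
#' @return An object of class `lf_curve` with `status = "ok"` and elements
#'   `days` (elapsed days from the first usable timepoint) and
#'   `cumulative_change` (non-decreasing, starting at 0), or
#'   `status = "insufficient"` when fewer than 3 non-missing values exist.
#' @examples
#' cumulative_abs_change(c(50, 55, 52), as.Date("2014-01-01") + c(0, 30, 60))
#' @export
cumulative_abs_change <- function(fev1, dates) {
  if (length(fev1) != length(dates)) {
    stop("fev1 and dates lengths differ", call. = FALSE)
  }
  ok <- !is.na(fev1)
  if (sum(ok) < 3) {
    out <- list(status = "insufficient", n_available = sum(ok))
    class(out) <- "lf_curve"
    return(out)
  }
  v <- fev1[ok]
  d <- as.numeric(dates)[ok]
  out <- list(status = "ok",
              days = d - d[1],
              cumulative_change = cumsum(c(0, abs(diff(v)))),
              n_available = sum(ok))
  class(out) <- "lf_curve"
  out
}

#' @export
print.lf_curve <- function(x, ...) {
  if (x$status != "ok") {
    cat("<lf_curve> insufficient lung-function data (",
        x$n_available, " values)\n", sep = "")
  } else {
    cat(sprintf("<lf_curve> %d points over %g days; total |d%%FEV1| = %.1f\n",
                length(x$days), max(x$days),
                max(x$cumulative_change)))
  }
  invisible(x)
}

#' Power-law rate of lung-function change
#'
#' Fits the power model dFEV1 = a * T^b to a cumulative absolute change curve,
#' with T in days. Points with zero elapsed days or zero cumulative change are
#' excluded (the log is undefined there; the fit runs through the strictly
#' positive part of the curve). A constant-%FEV1 series (all cumulative
#' changes zero) bypasses the fit with the convention b = 0.
#'
#' @param curve An `lf_curve` from [cumulative_abs_change()].
#' @return An object of class `lf_fit`: `status` (`"ok"`, `"insufficient"`,
#'   or `"constant"`) plus, when ok, a [fit_power()] result in `fit` with
#'   `a = fit$c` and `b = fit$exponent`; when constant, `b = 0`.
#' @export
fit_lft <- function(curve) {
  stopifnot(inherits(curve, "lf_curve"))
  if (curve$status != "ok") {
    out <- list(status = "insufficient", fit = NULL, b = NA_real_,
                a = NA_real_)
    class(out) <- "lf_fit"
    return(out)
  }
  if (all(curve$cumulative_change == 0)) {
    out <- list(status = "constant", fit = NULL, b = 0, a = 0)
    class(out) <- "lf_fit"
    return(out)
  }
  keep <- curve$days > 0 & curve$cumulative_change > 0
  if (sum(keep) < 3) {
    out <- list(status = "insufficient", fit = NULL, b = NA_real_,
                a = NA_real_)
    class(out) <- "lf_fit"
    return(out)
  }
  fit <- fit_power(curve$days[keep], curve$cumulative_change[keep])
  out <- list(status = "ok", fit = fit, b = fit$exponent, a = fit$c)
  class(out) <- "lf_fit"
  out
}

#' @export
print.lf_fit <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<lf_fit> dFEV1 = %.3g * T^%.3g (R2 = %.3f)\n",
                x$a, x$b, x$fit$r_squared))
  } else {
    cat("<lf_fit> ", x$status, "\n", sep = "")
  }
  invisible(x)
}

#' Lung-function power fit for a patient series
#'
#' Convenience wrapper: [cumulative_abs_change()] then [fit_lft()].
#'
#' @param series A [patient_series()].
#' @return An `lf_fit`.
#' @export
compute_lft <- function(series) {
  fit_lft(cumulative_abs_change(series$fev1_percent, series$sample_dates))
}

#' Tabulate lung-function fits across patients
#'
#' @param fits Named list of `lf_fit` objects (names are patient IDs).
#' @return Data.frame `patient_id, status, a, b, R2, F, df_num, df_den, p,
#'   n_points`.
#' @export
lft_fit_table <- function(fits) {
  rows <- lapply(names(fits), function(pid) {
    x <- fits[[pid]]
    if (x$status == "ok") {
      f <- x$fit
      data.frame(patient_id = pid, status = x$status, a = x$a, b = x$b,
                 R2 = f$r_squared, F = f$f_statistic, df_num = f$df_num,
                 df_den = f$df_den, p = f$p_value, n_points = f$n_points,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = pid, status = x$status, a = x$a, b = x$b,
                 R2 = NA_real_, F = NA_real_, df_num = NA_integer_,
                 df_den = NA_integer_, p = NA_real_, n_points = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
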