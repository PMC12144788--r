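#' Fit the power model y = c * x^w by log-log least squares
#'
#' Ordinary least squares of `log(y)` on `log(x)`; the exponent is the slope
#' (the temporal scaling exponent w for STRs, the lung-function rate b for
#' cumulative %FEV1 change) and `c` is the back-transformed intercept. The
#' slope is identical under any log base; natural logs are used. Diagnostics
#' are the standard regression F-test with (1, n - 2) degrees of freedom.
#'
#' Degenerate input where all `y` are identical is, ecologically, "no
#' turnover": the fit is bypassed and the exponent is 0 with `c = y`, R^2
#' reported as 1 by convention and the p-value as `NA`.
#'
#' @param x,y Strictly positive numeric vectors of equal length (>= 3).
#' @return An object of class `power_fit` with elements `c`, `exponent`,
#'   `r_squared`, `f_statistic`, `df_num`, `df_den`, `p_value`, `n_points`,
#'   and `degenerate`.
#' @examples
#' fit_power(1:6, 3 * (1:6)^0.5)
#' @export
fit_power <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0)) {
    stop("x and y must be strictly positive and finite", call. = FALSE)
  }
  n <- length(x)
  if (diff(range(y)) <= 1e-12 * max(y)) {
    fit <- list(c = y[1], exponent = 0, r_squared = 1,
                f_statistic = NA_real_, df_num = 1L, df_den = n - 2L,
                p_value = NA_real_, n_points = n, degenerate = TRUE)
    class(fit) <- "power_fit"
    return(fit)
  }
  m <- stats::lm(log(y) ~ log(x))
  s <- suppressWarnings(summary(m))  # exact power laws trip the perfect-fit warning
  fstat <- if (is.null(s$fstatistic)) NA_real_ else unname(s$fstatistic[1])
  pval <- if (is.na(fstat)) NA_real_ else
    stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  fit <- list(c = exp(unname(stats::coef(m)[1])),
              exponent = unname(stats::coef(m)[2]),
              r_squared = s$r.squared,
              f_statistic = fstat,
              df_num = 1L, df_den = n - 2L,
              p_value = pval, n_points = n, degenerate = FALSE)
  class(fit) <- "power_fit"
  fit
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf(
    "<power_fit> y = %.4g * x^%.4g  (R2 = %.3f, F[%d,%d] = %s, p = %s, n = %d%s)\n",
    x$c, x$exponent, x$r_squared, x$df_num, x$df_den,
    if (is.na(x$f_statistic)) "NA" else sprintf("%.3g", x$f_statistic),
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    x$n_points, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Simple linear regression with F-test diagnostics
#'
#' Thin wrapper around [stats::lm()] returning slope, intercept, R^2, F,
#' degrees of freedom and two-sided p-value; used for persistence-abundance
#' relationships and cohort-level b-on-w regressions.
#'
#' @param x,y Numeric vectors (>= 3 points); `x` must have non-zero variance.
#' @return An object of class `linear_fit`.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("zero variance in x: slope undefined", call. = FALSE)
  }
  n <- length(x)
  m <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(m))
  fstat <- if (is.null(s$fstatistic)) NA_real_ else unname(s$fstatistic[1])
  pval <- if (is.na(fstat)) NA_real_ else
    stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  fit <- list(slope = unname(stats::coef(m)[2]),
              intercept = unname(stats::coef(m)[1]),
              slope_se = s$coefficients[2, 2],
              r_squared = s$r.squared,
              f_statistic = fstat,
              df_num = 1L, df_den = n - 2L,
              p_value = pval, n_points = n)
  class(fit) <- "linear_fit"
  fit
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> y = %.4g + %.4g * x  (R2 = %.3f, F[%d,%d] = %.3g, p = %s, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$df_num, x$df_den, x$f_statistic,
    format.pval(x$p_value, digits = 3), x$n_points))
  invisible(x)
}
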