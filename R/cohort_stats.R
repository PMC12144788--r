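#' Kruskal-Wallis comparison of groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k - 1 degrees
#' of freedom, computed through [stats::kruskal.test()]. Used to compare
#' turnover exponents between the whole-microbiota, chronic, and intermittent
#' groups.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return An object of class `group_comparison`: list with `H`, `df`,
#'   `p_value`, `group_labels`, `group_sizes`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  kt <- stats::kruskal.test(x, g)
  out <- list(H = unname(kt$statistic),
              df = unname(kt$parameter),
              p_value = kt$p.value,
              group_labels = names(groups),
              group_sizes = vapply(groups, length, 1L))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis H = %.3f, df = %d, p = %s\n",
              x$H, x$df, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Standard Dunn z statistics from the pooled ranks with tie correction:
#' for groups i, j with mean pooled ranks Ri, Rj and sizes ni, nj,
#' z = (Ri - Rj) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/ni + 1/nj)),
#' where the tie sum runs over tied value groups of size t in the pooled
#' sample. Two-sided normal p-values, adjusted for the number of pairs
#' (Bonferroni by default).
#'
#' @param groups Named list of numeric vectors (>= 2 groups). The test is
#'   usually run after a significant Kruskal-Wallis result over >= 3 groups;
#'   with 2 groups it reduces to a single rank-sum z comparison.
#' @param adjust `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @return Data.frame with one row per unordered pair: `group1, group2, z,
#'   p_value, p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 1L)
  gid <- rep(seq_along(groups), sizes)
  r <- rank(x)
  n_total <- length(x)
  mean_ranks <- tapply(r, gid, mean)
  tie_counts <- table(x)
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (n_total - 1))
  var_base <- n_total * (n_total + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (mean_ranks[[i]] - mean_ranks[[j]]) /
      sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
  })
  # identical pooled values give var_base = 0; all mean-rank differences are 0
  z[!is.finite(z)] <- 0
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = as.numeric(z),
             p_value = p,
             p_adjusted = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regress lung-function rate b on turnover w across patients
#'
#' Ordinary least squares of per-patient b on per-patient w with standard
#' F-test diagnostics; a positive slope means greater lung-function change
#' accompanies greater microbiota turnover.
#'
#' @param w,b Numeric vectors of per-patient turnover exponents and
#'   lung-function rates (>= 3 complete pairs).
#' @return A [fit_linear()] result (`linear_fit`).
#' @export
regress_b_on_w <- function(w, b) {
  ok <- !is.na(w) & !is.na(b)
  fit_linear(w[ok], b[ok])
}

#' Cohort summary table
#'
#' Means, sample SDs (n - 1 denominator), minima and maxima of the headline
#' per-patient statistics: turnover w by subset, chronic/intermittent taxon
#' counts, lung-function rate b, peak fine-scale w, and onset lead days per
#' threshold. Subsets with no values are flagged absent rather than dropped.
#'
#' @param str_fits Data.frame from [str_fit_table()].
#' @param counts Data.frame with columns `patient_id, n_chronic,
#'   n_intermittent` (one row per patient), or `NULL`.
#' @param lft_fits Data.frame from [lft_fit_table()], or `NULL`.
#' @param peaks Named numeric vector of per-patient peak w, or `NULL`.
#' @param onset_summary Data.frame from [cohort_onset_summary()], or `NULL`.
#' @return Data.frame `statistic, n, mean, sd, min, max, absent`.
#' @export
summarize_cohort <- function(str_fits, counts = NULL, lft_fits = NULL,
                             peaks = NULL, onset_summary = NULL) {
  row_of <- function(stat, v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(data.frame(statistic = stat, n = 0L, mean = NA_real_,
                        sd = NA_real_, min = NA_real_, max = NA_real_,
                        absent = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(statistic = stat, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), absent = FALSE,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (sub in c("whole", "chronic", "intermittent")) {
    rows[[paste0("w_", sub)]] <-
      row_of(paste0("w_", sub), str_fits$w[str_fits$subset == sub])
  }
  if (!is.null(counts)) {
    rows$n_chronic <- row_of("n_chronic_taxa", counts$n_chronic)
    rows$n_intermittent <- row_of("n_intermittent_taxa",
                                  counts$n_intermittent)
  }
  if (!is.null(lft_fits)) {
    rows$b <- row_of("b_lung_function",
                     lft_fits$b[lft_fits$status == "ok"])
  }
  if (!is.null(peaks)) rows$peak_w <- row_of("peak_w", as.numeric(peaks))
  if (!is.null(onset_summary)) {
    for (k in seq_len(nrow(onset_summary))) {
      s <- onset_summary[k, ]
      rows[[paste0("lead_", s$threshold)]] <- data.frame(
        statistic = sprintf("lead_days_threshold_%g", s$threshold),
        n = s$n_leads, mean = s$mean_lead_days, sd = s$sd_lead_days,
        min = NA_real_, max = NA_real_, absent = s$n_leads == 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
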