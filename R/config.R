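#' Analysis configuration for a patient cohort
#'
#' Bundles the tunable constants of the turnover analysis. The defaults encode
#' the study conventions: presence is any non-zero relative abundance, chronic
#' colonization requires strictly more than 50% temporal persistence, whole
#' series species-time relationships (STRs) use ordinal time (window length in
#' samples), fine-scale quadrats hold five timepoints and use elapsed days, and
#' onset detection is run at turnover thresholds w > 0.5 and w > 1.0.
#'
#' @param presence_threshold Minimal relative abundance for a taxon to count
#'   as present in a sample. Default 0 (strictly greater than zero counts as
#'   present; upstream denoising is assumed).
#' @param chronic_persistence_cutoff Persistence fraction above which (strictly)
#'   a taxon is labelled chronic. Default 0.5; ties at exactly 0.5 are
#'   intermittent.
#' @param str_time_unit Time axis for whole-series STR fits: `"sample_count"`
#'   (ordinal window length, default) or `"days"` (mean spanned duration of the
#'   windows of each length plus one mean inter-sample interval).
#' @param quadrat_size Number of timepoints per sliding quadrat (>= 3,
#'   default 5).
#' @param quadrat_time_unit Time axis used for the STR fit inside each quadrat:
#'   `"days"` (default) or `"sample_count"`. See the package vignette for why
#'   the quadrat default differs from `str_time_unit`.
#' @param onset_thresholds Numeric vector of turnover thresholds at which PEx
#'   onset is dated. Default `c(0.5, 1)`.
#' @param sustained_k Number of consecutive quadrat midpoints that must exceed
#'   the threshold before a crossing is declared (default 1, i.e. first
#'   exceedance).
#' @param par_log_persistence Logical; fit the persistence-abundance
#'   relationship against log10(persistence) instead of the untransformed
#'   fraction. Default `FALSE`.
#' @param dunn_adjust Multiplicity adjustment for Dunn's post-hoc test:
#'   `"bonferroni"` (default), `"holm"`, or `"none"`.
#' @param rng_seed Integer seed used by seeded pipeline steps.
#'
#' @return An object of class `cohort_config` (a named list).
#' @examples
#' cfg <- cohort_config(quadrat_size = 5)
#' cfg$onset_thresholds
#' @export
cohort_config <- function(presence_threshold = 0,
                          chronic_persistence_cutoff = 0.5,
                          str_time_unit = c("sample_count", "days"),
                          quadrat_size = 5L,
                          quadrat_time_unit = c("days", "sample_count"),
                          onset_thresholds = c(0.5, 1),
                          sustained_k = 1L,
                          par_log_persistence = FALSE,
                          dunn_adjust = c("bonferroni", "holm", "none"),
                          rng_seed = 1L) {
  str_time_unit <- match.arg(str_time_unit)
  quadrat_time_unit <- match.arg(quadrat_time_unit)
  dunn_adjust <- match.arg(dunn_adjust)
  cfg <- list(
    presence_threshold = as.numeric(presence_threshold),
    chronic_persistence_cutoff = as.numeric(chronic_persistence_cutoff),
    str_time_unit = str_time_unit,
    quadrat_size = as.integer(quadrat_size),
    quadrat_time_unit = quadrat_time_unit,
    onset_thresholds = as.numeric(onset_thresholds),
    sustained_k = as.integer(sustained_k),
    par_log_persistence = isTRUE(par_log_persistence),
    dunn_adjust = dunn_adjust,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!(cfg$presence_threshold >= 0 && cfg$presence_threshold < 1)) {
    stop("presence_threshold must lie in [0, 1)", call. = FALSE)
  }
  if (!(cfg$chronic_persistence_cutoff > 0 &&
        cfg$chronic_persistence_cutoff < 1)) {
    stop("chronic_persistence_cutoff must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$quadrat_size < 3L) stop("quadrat_size must be >= 3", call. = FALSE)
  if (any(!is.finite(cfg$onset_thresholds)) || any(cfg$onset_thresholds <= 0)) {
    stop("onset_thresholds must be positive", call. = FALSE)
  }
  if (cfg$sustained_k < 1L) stop("sustained_k must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read a cohort configuration from a key: value text file
#'
#' The file is YAML-formatted (plain `key: value` lines suffice). Unknown keys
#' are rejected so that typos fail loudly; missing keys take the
#' [cohort_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, raw)
}

#' Write a cohort configuration to a key: value text file
#'
#' @param config A `cohort_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
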