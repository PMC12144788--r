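#' Parameters of the synthetic cohort generator
#'
#' The generator emulates a processed longitudinal sputum-microbiota deposit:
#' a cohort of adults with CF sampled at clinic visits over roughly a year,
#' most of whom pass through a pulmonary exacerbation (PEx) with BETR disease
#' states (B0 baseline, E exacerbation within 30 days before treatment, T
#' treatment, R recovery within 30 days after, B1 post-PEx baseline). Each
#' patient carries a chronic core of high-persistence taxa dominated by a
#' single abundant pathogen, plus a large pool of rare intermittent taxa whose
#' detections arrive as Poisson immigration events; the immigration rate is
#' multiplied by `burst_multiplier` from the true onset day until treatment
#' end. Visits are denser around the exacerbation and treatment window
#' (routine plus emergency visits), and %FEV1 declines through E and recovers
#' through T, with per-visit change magnitude optionally coupled to the
#' realized number of intermittent detections.
#'
#' @param n_patients Number of patients (default 12).
#' @param no_pex_patients Indices of patients who never exacerbate
#'   (default `c(3, 7)`).
#' @param n_samples_range Inclusive range of per-patient sample counts for
#'   PEx patients (default 16..35).
#' @param n_samples_range_no_pex Sample-count range for no-PEx patients
#'   (default 6..9; sparse routine-only sampling).
#' @param series_days_range Inclusive range of series durations in days
#'   (default 221..368).
#' @param n_chronic_taxa Number of chronic-core taxa (default 12).
#' @param chronic_presence_prob Per-sample presence probability of each
#'   chronic taxon (default 0.9).
#' @param chronic_dominant_scale,chronic_scale,chronic_scale_decay Abundance
#'   scales: the first chronic taxon (the dominant pathogen) has lognormal
#'   median `chronic_dominant_scale`; chronic taxon k > 1 has median
#'   `chronic_scale * chronic_scale_decay^(k - 2)`.
#' @param intermittent_pool_size Size of the intermittent taxon pool
#'   (default 90).
#' @param resident_pool_size Number of pool taxa forming the patient's
#'   recurring resident subset (default 20).
#' @param lambda_baseline Expected intermittent detections per sample at
#'   baseline (default 1.2).
#' @param burst_multiplier Multiplier on `lambda_baseline` from the true
#'   onset day to treatment end (kappa, default 8; 1 disables the burst).
#' @param p_resident_baseline,p_resident_burst Probability that a detection
#'   recurs from the resident subset rather than immigrating from the full
#'   pool, at baseline (0.7) and during the burst (0.15).
#' @param intermittent_scale Lognormal median abundance of intermittent
#'   detections (default 0.3, on the same raw scale as the chronic core).
#' @param dense_factor Relative visit density inside
#'   `[treatment_start - exacerbation_days, treatment_end + 7]`
#'   (default 8).
#' @param exacerbation_days,recovery_days Lengths of the E and R periods in
#'   days (default 30 each).
#' @param treatment_duration_range Inclusive range of treatment lengths in
#'   days (default 12..16).
#' @param onset_lead_days True onset day is this many days before treatment
#'   start (default 21).
#' @param fev1_baseline_range Uniform range of patient baseline %FEV1
#'   (default 25..81).
#' @param fev1_noise_sd SD of per-visit %FEV1 observation noise (default 2.5).
#' @param fev1_decline,fev1_recovery %FEV1 lost linearly across E and regained
#'   linearly across T (default 10 each).
#' @param coupling Coefficient linking per-visit |change in %FEV1| to the
#'   number of taxa newly detected at that visit (default 0.5; 0 turns the
#'   coupling off).
#' @param rng_seed Default cohort seed for [generate_cohort()].
#' @return An object of class `generator_params` (named list).
#' @export
generator_params <- function(n_patients = 12L,
                             no_pex_patients = c(3L, 7L),
                             n_samples_range = c(16L, 35L),
                             n_samples_range_no_pex = c(6L, 9L),
                             series_days_range = c(221L, 368L),
                             n_chronic_taxa = 12L,
                             chronic_presence_prob = 0.9,
                             chronic_dominant_scale = 60,
                             chronic_scale = 10,
                             chronic_scale_decay = 0.75,
                             intermittent_pool_size = 90L,
                             resident_pool_size = 20L,
                             lambda_baseline = 1.2,
                             burst_multiplier = 8,
                             p_resident_baseline = 0.7,
                             p_resident_burst = 0.15,
                             intermittent_scale = 0.3,
                             dense_factor = 8,
                             exacerbation_days = 30L,
                             recovery_days = 30L,
                             treatment_duration_range = c(12L, 16L),
                             onset_lead_days = 21,
                             fev1_baseline_range = c(25, 81),
                             fev1_noise_sd = 2.5,
                             fev1_decline = 10,
                             fev1_recovery = 10,
                             coupling = 0.5,
                             rng_seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$chronic_presence_prob >= 0, p$chronic_presence_prob <= 1,
            p$p_resident_baseline >= 0, p$p_resident_baseline <= 1,
            p$p_resident_burst >= 0, p$p_resident_burst <= 1,
            p$lambda_baseline >= 0, p$burst_multiplier >= 1,
            p$coupling >= 0, p$dense_factor >= 1,
            p$resident_pool_size <= p$intermittent_pool_size)
  class(p) <- "generator_params"
  p
}

.origin_date <- as.Date("2014-01-01")

#' Generate one synthetic patient series with ground truth
#'
#' See [generator_params()] for the generative model. All randomness flows
#' from `seed`. The true onset day must precede treatment start
#' (`onset_lead_days > 0` guarantees it); an infeasible schedule is an error.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed for this patient.
#' @param patient_id Patient identifier.
#' @param pex Does this patient experience a PEx?
#' @return List with `series` (a [patient_series()]) and `truth` (one-row
#'   data.frame: onset/treatment days, pool composition sizes, rates).
#' @export
generate_patient <- function(params = generator_params(), seed = 1L,
                             patient_id = "P01", pex = TRUE) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(as.integer(seed))
  series_days <- sample(params$series_days_range[1]:params$series_days_range[2], 1)
  nr <- if (pex) params$n_samples_range else params$n_samples_range_no_pex
  n <- sample(nr[1]:nr[2], 1)

  if (pex) {
    treatment_start <- round(series_days * stats::runif(1, 0.45, 0.65))
    treatment_end <- treatment_start +
      sample(params$treatment_duration_range[1]:params$treatment_duration_range[2], 1)
    onset_day <- treatment_start - params$onset_lead_days
    if (onset_day >= treatment_start) {
      stop("infeasible schedule: onset at or after treatment start",
           call. = FALSE)
    }
    dense_lo <- treatment_start - params$exacerbation_days
    dense_hi <- treatment_end + 7
  } else {
    treatment_start <- treatment_end <- onset_day <- NA_real_
    dense_lo <- dense_hi <- -1
  }

  cand <- 1:series_days
  wts <- ifelse(cand >= dense_lo & cand <= dense_hi, params$dense_factor, 1)
  days <- sort(c(0, sample(cand, n - 1, prob = wts)))

  state_of <- function(day) {
    if (!pex) return("B0")
    if (day < treatment_start - params$exacerbation_days) "B0"
    else if (day < treatment_start) "E"
    else if (day <= treatment_end) "T"
    else if (day <= treatment_end + params$recovery_days) "R"
    else "B1"
  }
  states <- vapply(days, state_of, character(1))
  in_burst <- if (pex) days >= onset_day & days <= treatment_end else
    rep(FALSE, n)

  nc <- params$n_chronic_taxa
  np <- params$intermittent_pool_size
  chronic_ids <- sprintf("C%02d", seq_len(nc))
  pool_ids <- sprintf("I%02d", seq_len(np))
  resident <- sample.int(np, params$resident_pool_size)
  chronic_scales <- c(params$chronic_dominant_scale,
                      params$chronic_scale *
                        params$chronic_scale_decay^(seq_len(nc - 1) - 1))

  ab <- matrix(0, nrow = nc + np, ncol = n,
               dimnames = list(c(chronic_ids, pool_ids), NULL))
  n_int <- integer(n)
  for (j in seq_len(n)) {
    pres <- stats::rbinom(nc, 1, params$chronic_presence_prob) == 1
    if (!any(pres)) pres[1] <- TRUE  # keep the sample non-empty
    ab[which(pres), j] <- stats::rlnorm(sum(pres),
                                        log(chronic_scales[pres]), 0.5)
    rate <- params$lambda_baseline *
      if (in_burst[j]) params$burst_multiplier else 1
    k <- stats::rpois(1, rate)
    n_int[j] <- k
    if (k > 0) {
      p_res <- if (in_burst[j]) params$p_resident_burst else
        params$p_resident_baseline
      from_res <- stats::runif(k) < p_res
      ids <- integer(k)
      if (any(from_res)) {
        ids[from_res] <- resident[sample.int(length(resident),
                                             sum(from_res), replace = TRUE)]
      }
      if (any(!from_res)) {
        ids[!from_res] <- sample.int(np, sum(!from_res), replace = TRUE)
      }
      for (tax in unique(ids)) {
        ab[nc + tax, j] <- stats::rlnorm(1, log(params$intermittent_scale), 1)
      }
    }
  }

  fev_base <- stats::runif(1, params$fev1_baseline_range[1],
                           params$fev1_baseline_range[2])
  trend <- vapply(seq_len(n), function(j) {
    if (!pex) return(fev_base)
    day <- days[j]
    e_start <- treatment_start - params$exacerbation_days
    if (day < e_start) fev_base
    else if (day < treatment_start) {
      fev_base - params$fev1_decline * (day - e_start) /
        params$exacerbation_days
    } else if (day <= treatment_end) {
      fev_base - params$fev1_decline + params$fev1_recovery *
        (day - treatment_start) / (treatment_end - treatment_start)
    } else fev_base - params$fev1_decline + params$fev1_recovery
  }, numeric(1))
  fev1 <- trend + stats::rnorm(n, 0, params$fev1_noise_sd)
  if (params$coupling > 0) {
    # each visit-to-visit |change| is inflated by coupling x the number of
    # taxa newly detected at that visit: a signed random walk whose step
    # size follows realized immigration
    seen <- rep(FALSE, nc + np)
    n_new <- integer(n)
    for (j in seq_len(n)) {
      det <- ab[, j] > 0
      n_new[j] <- sum(det & !seen)
      seen <- seen | det
    }
    steps <- sample(c(-1, 1), n, replace = TRUE) * params$coupling * n_new
    fev1 <- fev1 + cumsum(steps)
  }
  fev1 <- pmax(fev1, 5)

  series <- patient_series(
    patient_id = patient_id,
    sample_ids = sprintf("%s_S%02d", patient_id, seq_len(n)),
    sample_dates = .origin_date + days,
    abundance = ab,
    fev1_percent = fev1,
    disease_state = states,
    treatment_start = if (pex) .origin_date + treatment_start else
      as.Date(NA),
    treatment_end = if (pex) .origin_date + treatment_end else as.Date(NA))

  truth <- data.frame(
    patient_id = patient_id, pex = pex, seed = as.integer(seed),
    series_days = series_days, n_samples = n,
    true_onset_day = onset_day, treatment_start_day = treatment_start,
    treatment_end_day = treatment_end,
    lambda_baseline = params$lambda_baseline,
    burst_multiplier = if (pex) params$burst_multiplier else 1,
    coupling = params$coupling, stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}

#' Generate a synthetic cohort (optionally written to disk)
#'
#' Generates `params$n_patients` patients, deriving one seed per patient from
#' the cohort seed and the patient's index (so a patient's series is invariant
#' to reordering of the cohort). With `output_dir` set, writes one
#' taxon-by-sample TSV per patient (`taxon_table_<id>.tsv`, relative
#' abundances), a combined `metadata.csv`, and `ground_truth.tsv`; the ground
#' truth is written alongside but is never consumed by any analysis function.
#' Fixed seeds reproduce byte-identical outputs.
#'
#' @param params A [generator_params()] object.
#' @param seed Cohort seed (default `params$rng_seed`).
#' @param output_dir Output directory, created if needed; `NULL` (default)
#'   keeps the cohort in memory only.
#' @return List with `series` (named list of [patient_series()]),
#'   `ground_truth` (data.frame), and `files` (character vector of written
#'   paths, empty when `output_dir` is `NULL`).
#' @export
generate_cohort <- function(params = generator_params(),
                            seed = params$rng_seed, output_dir = NULL) {
  stopifnot(inherits(params, "generator_params"))
  idx <- seq_len(params$n_patients)
  series <- list()
  truths <- list()
  for (i in idx) {
    pid <- sprintf("P%02d", i)
    res <- generate_patient(params,
                            seed = patient_seed(seed, i),
                            patient_id = pid,
                            pex = !(i %in% params$no_pex_patients))
    series[[pid]] <- res$series
    truths[[pid]] <- res$truth
  }
  ground_truth <- do.call(rbind, truths)
  rownames(ground_truth) <- NULL
  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(series)) {
      f <- file.path(output_dir, paste0("taxon_table_", pid, ".tsv"))
      write_taxon_table(series[[pid]]$abundance, f)
      files <- c(files, f)
    }
    meta <- do.call(rbind, lapply(series, function(s) {
      data.frame(patient_id = s$patient_id, sample_id = s$sample_ids,
                 date = s$sample_dates, fev1_percent = s$fev1_percent,
                 disease_state = s$disease_state,
                 treatment_start = s$treatment_start,
                 treatment_end = s$treatment_end, stringsAsFactors = FALSE)
    }))
    rownames(meta) <- NULL
    f_meta <- file.path(output_dir, "metadata.csv")
    write_sample_metadata(meta, f_meta)
    f_truth <- file.path(output_dir, "ground_truth.tsv")
    utils::write.table(ground_truth, f_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f_meta, f_truth)
  }
  list(series = series, ground_truth = ground_truth, files = files)
}

#' Derive a per-patient seed from a cohort seed
#'
#' Keeps derived seeds within 32-bit integer range and ties them to the
#' patient index, not the cohort position.
#'
#' @param cohort_seed Integer cohort seed.
#' @param patient_index Integer patient index.
#' @return Integer seed.
#' @export
patient_seed <- function(cohort_seed, patient_index) {
  as.integer((as.numeric(cohort_seed) %% 1000000) * 1000 +
               as.numeric(patient_index))
}
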