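#!/usr/bin/env Rscript
# Stage 2: chronic/intermittent colonization status.
#
# For every patient, classifies each detected taxon by temporal persistence
# (chronic if present in more than half of the samples) and fits the
# persistence-abundance relationship (PAR): log10 mean relative abundance
# when present against persistence.

source(file.path("analysis", "00_read_cohort.R"))

series <- read_cohort()
out_dir <- file.path("results", "colonization")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

profiles <- list()
par_rows <- list()
for (pid in names(series)) {
  prof <- compute_persistence(series[[pid]])
  profiles[[pid]] <- cbind(patient_id = pid, prof)
  par <- fit_par(prof)
  par_rows[[pid]] <- data.frame(
    patient_id = pid, slope = par$slope, intercept = par$intercept,
    R2 = par$r_squared, F = par$f_statistic, df_num = par$df_num,
    df_den = par$df_den, p = par$p_value, n_taxa = par$n_points)
}
prof_all <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))
par_all <- do.call(rbind, c(par_rows, list(make.row.names = FALSE)))
write_colonization_profiles(prof_all, file.path(out_dir, "profiles.tsv"))
write.table(par_all, file.path(out_dir, "par_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

counts <- t(sapply(profiles, count_by_label))
cat(sprintf("Chronic taxa per patient: %.1f +/- %.1f (min %d, max %d)\n",
            mean(counts[, 1]), sd(counts[, 1]), min(counts[, 1]),
            max(counts[, 1])))
cat(sprintf("Intermittent taxa per patient: %.1f +/- %.1f (min %d, max %d)\n",
            mean(counts[, 2]), sd(counts[, 2]), min(counts[, 2]),
            max(counts[, 2])))
cat(sprintf("PAR slopes all positive: %s (range %.2f to %.2f)\n",
            all(par_all$slope > 0), min(par_all$slope), max(par_all$slope)))
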