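#!/usr/bin/env Rscript
# Stage 4: cumulative lung-function change.
#
# Accumulates the absolute change in %FEV1 between consecutive visits for
# each patient and fits the power model dFEV1 = a*T^b with T in days; b is
# the patient's rate of lung-function change.

source(file.path("analysis", "00_read_cohort.R"))

series <- read_cohort()
out_dir <- file.path("results", "lung_function")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fits <- lapply(series, compute_lft)
tab <- lft_fit_table(fits)
write.table(tab, file.path(out_dir, "lft_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

treated <- sapply(series, function(s) !is.na(s$treatment_start))
b_pex <- tab$b[tab$status == "ok" & treated[tab$patient_id]]
b_base <- tab$b[tab$status == "ok" & !treated[tab$patient_id]]
cat(sprintf("b (PEx patients, n = %d): mean %.3f +/- %.3f\n",
            length(b_pex), mean(b_pex), sd(b_pex)))
cat(sprintf("b (stable patients, n = %d): %s\n", length(b_base),
            paste(sprintf("%.3f", b_base), collapse = ", ")))
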