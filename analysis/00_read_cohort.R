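# Shared loader for stages 2-6: reads the simulated cohort from
# results/synthetic_cohort back through the file readers, so every stage
# exercises the same ingestion path real deposited data would take.

library(cfturnover)

read_cohort <- function(input_dir = file.path("results", "synthetic_cohort"),
                        config = cohort_config()) {
  if (!dir.exists(input_dir)) {
    stop("run analysis/01_simulate.R first: missing ", input_dir,
         call. = FALSE)
  }
  metadata <- suppressMessages(
    read_sample_metadata(file.path(input_dir, "metadata.csv")))
  tables <- sort(list.files(input_dir, pattern = "^taxon_table_.*[.]tsv$",
                            full.names = TRUE))
  series <- list()
  for (f in tables) {
    pid <- sub("^taxon_table_(.*)[.]tsv$", "\\1", basename(f))
    mat <- read_taxon_table(f)
    meta_p <- metadata[metadata$patient_id == pid, , drop = FALSE]
    series[[pid]] <- assemble_patient_series(mat, meta_p, config)[[pid]]
  }
  series
}
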