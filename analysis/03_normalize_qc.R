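#!/usr/bin/env Rscript
# Stage 3: pooled-QC random-forest drift normalization, then the
# reproducibility filter (PQC CoV < 20%, highest mean not in blanks) and a
# projection QC of the run.

suppressPackageStartupMessages(library(lipidflux))
seed <- as.integer(Sys.getenv("LIPIDFLUX_SEED", "1"))

conc <- readr::read_csv("results/concentrations.csv", show_col_types = FALSE)
norm <- serrf_normalize(conc, seed = seed)
filt <- qc_filter(norm)
readr::write_csv(filt$conc, "results/concentrations_normalized.csv")
readr::write_csv(filt$metrics, "results/qc_metrics.csv")

proj <- pca_qc(filt$conc)
readr::write_csv(proj$scores, "results/pca_scores.csv")
jsonlite::write_json(
  list(dispersion = proj$dispersion,
       variance_explained = proj$variance_explained),
  "results/qc_report.json", auto_unbox = TRUE, pretty = TRUE,
  dataframe = "rows")

cov_pqc <- filt$metrics$cov_pqc
cat(sprintf("retained %d / %d species (median PQC CoV %.1f%%)\n",
            sum(filt$metrics$retained), nrow(filt$metrics),
            median(cov_pqc, na.rm = TRUE)))
print(proj$dispersion)
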