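#!/usr/bin/env Rscript
# Stage 4: temporal statistics over t0/t1/t2 on the STEMI subjects:
# per-species repeated-measures ANOVA (Greenhouse-Geisser) with Bonferroni
# pairwise comparisons, class totals with percent differences, within-class
# composition log-ratios for the major structural classes, and clustered
# heatmap ordering.

suppressPackageStartupMessages(library(lipidflux))

norm <- readr::read_csv("results/concentrations_normalized.csv",
                        show_col_types = FALSE)
stemi <- norm[norm$sample_type == "study" & grepl("^S", norm$subject_id), ]
core <- stemi[stemi$timepoint %in% c("t0", "t1", "t2"), ]

screen <- species_temporal_screen(core)
readr::write_csv(screen$anova, "results/anova_results.csv")
readr::write_csv(screen$pairwise, "results/pairwise_results.csv")

totals <- class_totals(core)
readr::write_csv(totals, "results/class_totals.csv")
class_pd <- purrr::map_dfr(unique(totals$lipid_class), function(cl) {
  w <- tidyr::pivot_wider(totals[totals$lipid_class == cl, ],
                          id_cols = "subject_id", names_from = "timepoint",
                          values_from = "total")
  purrr::map_dfr(list(c("t0", "t1"), c("t1", "t2"), c("t0", "t2")),
                 function(pr) {
    ok <- stats::complete.cases(w[pr])
    pd <- percent_difference(w[[pr[1]]][ok], w[[pr[2]]][ok], n_boot = 500)
    tibble::tibble(lipid_class = cl,
                   pair = paste(pr, collapse = "_vs_"),
                   percent_difference = pd$percent_difference,
                   sem = pd$sem)
  })
})
readr::write_csv(class_pd, "results/class_percent_differences.csv")

ratios <- purrr::map_dfr(c("PC", "PE", "PI", "SM"), function(cl) {
  dplyr::mutate(within_class_log_ratio(core, cl), lipid_class = cl)
})
readr::write_csv(ratios, "results/composition_logratios.csv")

wide <- tidyr::pivot_wider(core, id_cols = "species",
                           names_from = "sample_id",
                           values_from = "concentration")
mat <- as.matrix(wide[-1]); rownames(mat) <- wide$species
hm <- cluster_heatmap_data(mat)
jsonlite::write_json(list(row_order = hm$row_order, col_order = hm$col_order),
                     "results/heatmap_order.json", auto_unbox = TRUE)

frac <- tapply(screen$pairwise$significant, screen$pairwise$pair, mean)
cat("fraction of species significant (Bonferroni-corrected p < 0.05):\n")
print(round(frac, 3))
big <- class_pd[abs(class_pd$percent_difference) > 20, ]
cat("class totals changing by more than 20%:\n")
print(as.data.frame(big), digits = 3)
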