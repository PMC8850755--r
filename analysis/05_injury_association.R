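#!/usr/bin/env Rscript
# Stage 5: myocardial-injury associations: delta troponin per subject,
# covariate-adjusted per-species regressions at each timepoint, tertile and
# MACE stratification with fold changes, late-phase trajectories for the
# markers, and the STEMI-vs-control comparison.

suppressPackageStartupMessages(library(lipidflux))

norm <- readr::read_csv("results/concentrations_normalized.csv",
                        show_col_types = FALSE)
clinical <- readr::read_csv("results/clinical.csv", show_col_types = FALSE)
troponin <- readr::read_csv("results/troponin.csv", show_col_types = FALSE)

stemi <- norm[norm$sample_type == "study" & grepl("^S", norm$subject_id), ]
delta <- cohort_delta_troponin(troponin)

reg <- purrr::map_dfr(c("t0", "t1", "t2"), function(tp) {
  dplyr::mutate(regression_screen(stemi[stemi$timepoint == tp, ], delta,
                                  clinical),
                timepoint = tp, .before = 1L)
})
readr::write_csv(reg, "results/regression_results.csv")

split <- tertile_split(delta$delta_tnt)
lab <- tibble::tibble(subject_id = delta$subject_id, tertile = split$labels)
mace <- tibble::tibble(subject_id = clinical$subject_id,
                       mace = ifelse(clinical$mace, "mace", "none"))
sig <- unique(reg$species[reg$significant & reg$flag == "ok"])
cmp <- purrr::map_dfr(c("t0", "t1", "t2"), function(tp) {
  ct <- stemi[stemi$timepoint == tp & stemi$species %in% sig, ]
  purrr::map_dfr(unique(ct$species), function(s) {
    d <- ct[ct$species == s, ]
    d_t <- dplyr::inner_join(d, lab, by = "subject_id")
    d_m <- dplyr::inner_join(d, mace, by = "subject_id")
    dplyr::bind_rows(
      dplyr::mutate(group_fold_change(d_t$concentration, d_t$tertile,
                                      group_a = "top"),
                    grouping = "tertile_top_vs_rest"),
      dplyr::mutate(group_fold_change(d_m$concentration, d_m$mace,
                                      group_a = "mace"),
                    grouping = "mace_vs_none")) |>
      dplyr::mutate(species = s, timepoint = tp, .before = 1L)
  })
})
readr::write_csv(cmp, "results/group_comparisons.csv")

markers <- c("acylcarnitine 18:2", "TG 51:0", "LPC 17:1")
late_ids <- unique(stemi$subject_id[stemi$timepoint == "t3"])
late <- late_phase_trajectories(
  stemi[stemi$subject_id %in% late_ids, ], species = markers)
readr::write_csv(late$vs_baseline, "results/late_phase.csv")

ctrl <- norm[norm$sample_type == "study" & grepl("^C", norm$subject_id), ]
cc <- control_comparison(stemi[stemi$timepoint == "t0", ], ctrl, markers)
readr::write_csv(cc, "results/control_comparison.csv")

cat(sprintf("delta troponin: median %.0f ng/L, tertile split %d vs %d (thresholds %.0f / %.0f)\n",
            median(delta$delta_tnt), split$n_top, split$n_lower,
            split$thresholds[1], split$thresholds[2]))
cat(sprintf("%d species significantly associated with delta troponin across timepoints\n",
            length(sig)))
cat("markers vs controls:\n")
print(as.data.frame(cc), digits = 3)
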