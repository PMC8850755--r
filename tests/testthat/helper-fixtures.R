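# Shared fixtures. Everything is generated in code; the expensive
# default-scale study is built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# A small panel (subset of the packaged one) for fast unit tests.
small_panel <- function(n_per_class = 3,
                        classes = c("PC", "TG", "FA", "LPC",
                                    "acylcarnitine", "SM")) {
  full <- default_panel()
  keep <- full$species |>
    dplyr::filter(.data$lipid_class %in% classes) |>
    dplyr::group_by(.data$lipid_class) |>
    dplyr::slice_head(n = n_per_class) |>
    dplyr::ungroup()
  # keep the planted marker species when their class is included
  extra <- full$species[full$species$species %in%
                          c("TG 51:0", "LPC 17:1", "acylcarnitine 18:2") &
                          full$species$lipid_class %in% classes, ]
  keep <- dplyr::distinct(dplyr::bind_rows(keep, extra))
  istd <- full$istd_map[full$istd_map$lipid_class %in% classes, ]
  lipidflux:::build_panel(keep[c("species", "lipid_class")], istd)
}

# A small complete synthetic study (cohort + acquisition), memoized per key.
small_study <- function(seed = 11, n_stemi = 12, n_control = 6,
                        n_late = 4, drift_amplitude = 0.3, noise_cv = 0.15) {
  key <- paste("small", seed, n_stemi, n_control, n_late, drift_amplitude,
               noise_cv, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  panel <- default_panel()
  truth <- ground_truth(panel)
  design <- study_design(n_stemi = n_stemi, n_control = n_control,
                         n_late_subset = n_late)
  cohort <- generate_cohort(design, truth, seed = seed)
  acq <- generate_acquisition(cohort, design, truth, panel,
                              drift_amplitude = drift_amplitude,
                              noise_cv = noise_cv, seed = seed)
  out <- list(panel = panel, truth = truth, design = design,
              cohort = cohort, acq = acq)
  .fixture_cache[[key]] <- out
  out
}

# The default-scale study run through the full pipeline once (used by the
# acceptance checks and the end-to-end invariants).
default_study_run <- function(seed = 1) {
  key <- paste0("default_run_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  panel <- default_panel()
  truth <- ground_truth(panel)
  design <- study_design()
  cohort <- generate_cohort(design, truth, seed = seed)
  acq <- generate_acquisition(cohort, design, truth, panel, seed = seed)
  conc <- quantify(deisotope(acq, panel), panel)
  meta <- dplyr::distinct(acq[acq$sample_type == "study",
                              c("sample_id", "subject_id", "timepoint")])
  conc <- dplyr::left_join(conc, meta, by = "sample_id")
  norm <- serrf_normalize(conc, seed = seed)
  filt <- qc_filter(norm)
  out <- list(panel = panel, truth = truth, design = design,
              cohort = cohort, acq = acq, conc = conc, norm = norm,
              filt = filt)
  .fixture_cache[[key]] <- out
  out
}

# Hand-built drift-bearing concentration table: n_species species measured
# over study + PQC + blank injections with a known multiplicative trend.
drifted_conc_table <- function(seed = 5, n_species = 20, n_study = 40,
                               n_pqc = 10, n_blank = 4, n_batches = 1,
                               drift_fold = 1.5, noise_cv = 0.05,
                               batch_offsets = rep(1, n_batches)) {
  set.seed(seed)
  base <- exp(rnorm(n_species, log(50), 1))
  species <- sprintf("SP%02d", seq_len(n_species))
  per_batch <- ceiling((n_study + n_pqc + n_blank) / n_batches)
  rows <- list()
  inj_types <- rep(c("study", "pqc", "blank"),
                   c(n_study, n_pqc, n_blank))
  batch_of <- rep(seq_len(n_batches), length.out = length(inj_types))
  # interleave PQCs through the order within batch
  for (b in seq_len(n_batches)) {
    idx <- which(batch_of == b)
    types <- inj_types[idx][sample.int(length(idx))]
    n_b <- length(types)
    order_b <- seq_len(n_b)
    drift <- drift_fold^((order_b - 1) / max(1, n_b - 1))
    for (i in seq_len(n_b)) {
      conc <- if (types[i] == "blank") base * 0.002 else base
      conc <- conc * drift[i] * batch_offsets[b] *
        rlnorm(n_species, 0, sqrt(log(1 + noise_cv^2)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("B%d_%s_%02d", b, types[i], i),
        sample_type = types[i], batch = b, injection_order = i,
        species = species, lipid_class = "PC", concentration = conc,
        flags = "")
    }
  }
  dplyr::bind_rows(rows)
}

pqc_cov_by_species <- function(conc) {
  pqc <- conc[conc$sample_type == "pqc", ]
  vapply(split(pqc$concentration, pqc$species),
         function(x) 100 * sd(x) / mean(x), numeric(1))
}
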