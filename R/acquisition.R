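# Synthetic study generator, part 2: the raw MRM acquisition. Emits one row
# per (injection, transition) with injection-order drift, batch offsets,
# multiplicative noise, M+2 isotope interference between same-class species
# differing by one double bond, pooled-QC/technical-QC/reference/blank
# injections, and internal-standard areas.

#' Run order for one analytical batch
#'
#' Layout per batch: 6 opening blanks, 10 equilibration PQCs, six cycles of
#' ten study samples followed by one PQC and one TQC (a 10:1 study:PQC ratio
#' in the interleaved portion), 4 reference-material (SRM) injections,
#' 6 closing blanks, and 4 closing PQCs - 102 injections for a full batch
#' of 60 study samples.
#'
#' @param n_study Study samples in this batch (<= 60).
#' @param layout Named counts per sample type (see [study_design()]).
#' @return Tibble `injection_order, sample_type, slot` where `slot` indexes
#'   injections of the same type within the batch.
#' @export
batch_run_order <- function(n_study = 60,
                            layout = c(study = 60, pqc = 20, tqc = 6,
                                       srm = 4, blank = 12)) {
  stopifnot(n_study <= layout[["study"]])
  types <- c(rep("blank", 6), rep("pqc", 10))
  remaining <- n_study
  for (cycle in seq_len(6)) {
    take <- min(10, remaining)
    remaining <- remaining - take
    types <- c(types, rep("study", take), "pqc", "tqc")
  }
  types <- c(types, rep("srm", layout[["srm"]]), rep("blank", 6),
             rep("pqc", 4))
  tibble::tibble(
    injection_order = seq_along(types),
    sample_type = types
  ) |>
    dplyr::group_by(.data$sample_type) |>
    dplyr::mutate(slot = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$injection_order)
}

#' Generate a synthetic raw MRM acquisition
#'
#' Converts latent true concentrations into per-injection peak areas:
#' `area = conc / ISTD_conc * base_response * divisor * drift * noise`,
#' where `divisor` is the species' correction/response factor (so the
#' noise-free pipeline inverts exactly), `drift` is a per-batch smooth
#' logistic trend over injection order with class-correlated, per-species
#' amplitudes times a per-(batch, species) offset, and noise is
#' multiplicative log-normal. PQC areas derive from the pooled mean of all
#' study samples; TQCs are matrix-free (internal standards only); SRM
#' injections use a fixed reference profile; blanks carry only
#' carryover-level analyte signal. M+2 isotope interference is added onto
#' the quantifier of the same-class species with one fewer double bond, and
#' explicit M+2 isotope rows are emitted for the most abundant species.
#'
#' @param cohort Output of [generate_cohort()].
#' @param design A `study_design`.
#' @param truth The `ground_truth` used for the cohort.
#' @param panel A `lipid_panel`.
#' @param drift_amplitude Relative amplitude of the within-batch trend and
#'   batch offsets (default 0.3; 0 disables drift entirely).
#' @param noise_cv Multiplicative measurement CV (default 0.15; 0 disables).
#' @param seed Master seed (named stream `"acquisition"`).
#' @param istd_base_area Instrument response scale for internal standards.
#' @return A peak-area table: `sample_id, sample_type, batch,
#'   injection_order, transition_id, area` plus `subject_id, timepoint` for
#'   study rows.
#' @export
generate_acquisition <- function(cohort, design = study_design(),
                                 truth = ground_truth(),
                                 panel = default_panel(),
                                 drift_amplitude = 0.3, noise_cv = 0.15,
                                 seed = 1L, istd_base_area = 1e6) {
  lipid <- cohort$lipid_truth
  sp <- panel$species
  istd <- panel$istd_map

  # study samples in acquisition order (randomized), 60 per batch
  samples <- dplyr::distinct(lipid[c("subject_id", "timepoint")])
  samples$sample_id <- paste(samples$subject_id, samples$timepoint, sep = "_")
  samples <- with_stream(seed, "runorder",
                         samples[sample.int(nrow(samples)), ])
  n_batches <- ceiling(nrow(samples) / design$batch_layout[["study"]])
  samples$batch <- rep(seq_len(n_batches),
                       each = design$batch_layout[["study"]])[
                         seq_len(nrow(samples))]

  # species-level constants
  divisor <- species_divisors(sp$species)
  names(divisor) <- sp$species
  istd_conc <- setNames(istd$istd_conc, istd$lipid_class)

  # concentration matrices per sample group
  conc_wide <- tidyr::pivot_wider(
    dplyr::mutate(lipid,
                  sample_id = paste(.data$subject_id, .data$timepoint,
                                    sep = "_")),
    id_cols = "sample_id", names_from = "species", values_from = "true_conc")
  conc_mat <- as.matrix(conc_wide[, sp$species])
  rownames(conc_mat) <- conc_wide$sample_id

  pqc_conc <- colMeans(conc_mat)                  # pooled from all study samples
  srm_conc <- truth$base_conc$base * 0.9          # fixed reference profile
  names(srm_conc) <- truth$base_conc$species
  srm_conc <- srm_conc[sp$species]
  blank_conc <- pqc_conc * 0.005                  # carryover level

  # deterministic M+2 interference map: receiver species <- donor with one
  # more double bond, same class and carbon count
  donors <- dplyr::inner_join(
    sp[c("species", "lipid_class", "total_carbons", "total_double_bonds")],
    dplyr::transmute(sp, lipid_class, total_carbons,
                     total_double_bonds = total_double_bonds - 1L,
                     donor = species),
    by = c("lipid_class", "total_carbons", "total_double_bonds"))
  donor_p2 <- m2_fraction(molecular_carbons(
    sp$lipid_class[match(donors$donor, sp$species)],
    sp$total_carbons[match(donors$donor, sp$species)]))

  layout <- design$batch_layout
  with_stream(seed, "acquisition", {
    # drift structure: per (batch, class) amplitude, per-species jitter
    classes <- unique(c(sp$lipid_class, istd$lipid_class))
    all_species <- c(sp$species, unique(istd$istd_species))
    species_class <- c(setNames(sp$lipid_class, sp$species),
                       setNames(istd$lipid_class, istd$istd_species))
    species_jitter <- setNames(exp(rnorm(length(all_species), 0, 0.3)),
                               all_species)

    batches <- purrr::map_dfr(seq_len(n_batches), function(b) {
      in_batch <- samples[samples$batch == b, ]
      run <- batch_run_order(nrow(in_batch), layout)
      run$batch <- b

      class_amp <- setNames(rnorm(length(classes), 1, 0.2), classes)
      batch_offset <- setNames(
        exp(rnorm(length(all_species), 0, 0.5 * drift_amplitude)),
        all_species)
      amp <- drift_amplitude * class_amp[species_class[all_species]] *
        species_jitter
      g <- plogis((run$injection_order - stats::median(run$injection_order)) / 17)
      # injections x species drift multiplier
      drift <- outer(g - 0.5, unname(amp)) + 1
      drift <- pmax(drift, 0.05) * rep(batch_offset, each = nrow(run))
      dimnames(drift) <- list(NULL, all_species)

      # per-injection analyte concentration rows
      conc_for <- function(type, slot) {
        switch(type,
          study = conc_mat[in_batch$sample_id[slot], ],
          pqc = pqc_conc, srm = srm_conc, blank = blank_conc,
          tqc = rep(0, length(pqc_conc)))
      }
      inj_conc <- t(vapply(seq_len(nrow(run)),
                           function(i) conc_for(run$sample_type[i], run$slot[i]),
                           numeric(ncol(conc_mat))))
      colnames(inj_conc) <- sp$species

      sample_ids <- ifelse(run$sample_type == "study",
        in_batch$sample_id[ifelse(run$sample_type == "study", run$slot, 1L)],
        sprintf("B%02d_%s%02d", b, toupper(run$sample_type), run$slot))

      sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
      noise_analyte <- matrix(
        if (sdlog > 0) rlnorm(nrow(run) * nrow(sp), 0, sdlog) else 1,
        nrow = nrow(run), ncol = nrow(sp))
      clean <- sweep(inj_conc, 2L,
                     unname(istd_conc[sp$lipid_class]) /
                       (istd_base_area * unname(divisor)), `/`) *
        drift[, sp$species] * noise_analyte

      # add isotope interference onto receivers
      observed <- clean
      if (nrow(donors) > 0L) {
        ridx <- match(donors$species, sp$species)
        didx <- match(donors$donor, sp$species)
        observed[, ridx] <- observed[, ridx] +
          sweep(clean[, didx, drop = FALSE], 2L, donor_p2, `*`)
      }

      analyte_rows <- tibble::tibble(
        sample_id = rep(sample_ids, times = nrow(sp)),
        sample_type = rep(run$sample_type, times = nrow(sp)),
        batch = b,
        injection_order = rep(run$injection_order, times = nrow(sp)),
        species = rep(sp$species, each = nrow(run)),
        transition_id = rep(paste(sp$species, "quantifier", sep = "|"),
                            each = nrow(run)),
        area = as.numeric(observed))

      # explicit M+2 isotope rows for the most abundant species (top 20%)
      hi <- sp$species[rank(-pqc_conc) <= ceiling(0.2 * nrow(sp))]
      hi_idx <- match(hi, sp$species)
      hi_p2 <- m2_fraction(molecular_carbons(sp$lipid_class[hi_idx],
                                             sp$total_carbons[hi_idx]))
      isotope_rows <- tibble::tibble(
        sample_id = rep(sample_ids, times = length(hi)),
        sample_type = rep(run$sample_type, times = length(hi)),
        batch = b,
        injection_order = rep(run$injection_order, times = length(hi)),
        species = rep(hi, each = nrow(run)),
        transition_id = rep(paste(hi, "isotope_M2", sep = "|"),
                            each = nrow(run)),
        area = as.numeric(sweep(clean[, hi_idx, drop = FALSE], 2L, hi_p2, `*`)))

      # qualifier rows for FA species: fixed 0.4 reference ratio x noise
      fa <- sp$species[sp$lipid_class == "FA"]
      fa_idx <- match(fa, sp$species)
      qual_noise <- matrix(
        if (sdlog > 0) rlnorm(nrow(run) * length(fa), 0, sdlog) else 1,
        nrow = nrow(run), ncol = length(fa))
      qualifier_rows <- tibble::tibble(
        sample_id = rep(sample_ids, times = length(fa)),
        sample_type = rep(run$sample_type, times = length(fa)),
        batch = b,
        injection_order = rep(run$injection_order, times = length(fa)),
        species = rep(fa, each = nrow(run)),
        transition_id = rep(paste(fa, "qualifier", sep = "|"),
                            each = nrow(run)),
        area = as.numeric(observed[, fa_idx, drop = FALSE] * 0.4 * qual_noise))

      # internal-standard rows: present in every injection except that TQCs
      # and blanks still carry ISTD (spiked before extraction)
      istd_species <- unique(istd$istd_species)
      istd_noise <- matrix(
        if (sdlog > 0) rlnorm(nrow(run) * length(istd_species), 0, sdlog) else 1,
        nrow = nrow(run), ncol = length(istd_species))
      istd_rows <- tibble::tibble(
        sample_id = rep(sample_ids, times = length(istd_species)),
        sample_type = rep(run$sample_type, times = length(istd_species)),
        batch = b,
        injection_order = rep(run$injection_order, times = length(istd_species)),
        species = rep(istd_species, each = nrow(run)),
        transition_id = rep(paste(istd_species, "quantifier", sep = "|"),
                            each = nrow(run)),
        area = istd_base_area *
          as.numeric(drift[, istd_species, drop = FALSE] * istd_noise))

      dplyr::bind_rows(analyte_rows, isotope_rows, qualifier_rows, istd_rows)
    })

    # attach subject/timepoint metadata for study rows
    meta <- samples[c("sample_id", "subject_id", "timepoint")]
    out <- dplyr::left_join(batches, meta, by = "sample_id")
    dplyr::arrange(out, .data$batch, .data$injection_order,
                   .data$transition_id)
  })
}
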