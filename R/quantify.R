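# Semi-quantitation of raw MRM peak areas: M+2 isotope correction,
# internal-standard ratio quantitation, acyl-chain correction factors for
# DG/TG, and chain-length/saturation response-factor lines for CE.

# natural abundance of 13C
C13_ABUNDANCE <- 0.0107

# Combined per-species divisor (acyl-chain CF x CE response factor) shared
# by quantitation and the synthetic acquisition generator so that the
# noise-free pipeline is exactly invertible. Sum-composition DG/TG species
# use CF = 1 unless an override is supplied.
species_divisors <- function(species_names, cf_overrides = NULL) {
  purrr::map_dbl(species_names, function(s) {
    sp <- parse_lipid_name(s)
    cf <- if (sp$lipid_class %in% c("DG", "TG") && is.null(sp$acyl_chains)) {
      if (!is.null(cf_overrides) && s %in% names(cf_overrides)) {
        cf_overrides[[s]]
      } else 1
    } else {
      correction_factor(sp)
    }
    rf <- if (sp$lipid_class == "CE") {
      ce_response_factor(sp$total_carbons, sp$total_double_bonds)
    } else 1
    cf * rf
  })
}

# Probability mass of the M+2 isotopologue of a molecule with `carbons`
# carbon atoms: two 13C substitutions, binomial second-order term.
m2_fraction <- function(carbons, a = C13_ABUNDANCE) {
  carbons * (carbons - 1) / 2 * a^2
}

#' Acyl-chain correction factor for DG/TG species
#'
#' DG and TG fragment by loss of a fatty acyl chain; when the chains differ,
#' the signal splits across several equally likely neutral losses and the
#' monitored transition retains only its share. The factor is 0.5 for DG
#' with two distinct chains, 0.33 for TG with three distinct chains, 0.66
#' for TG with exactly two identical chains, and 1 otherwise (including all
#' non-DG/TG classes, whose spectra are not corrected).
#'
#' Convention: the measured area ratio is *divided* by the returned factor
#' during quantitation (see [quantify()]), so CF = 1 is a no-op and smaller
#' factors scale concentrations up to compensate for the signal split.
#'
#' @param species A `lipid_species`. DG/TG species must be chain-resolved
#'   (e.g. `parse_lipid_name("DG 15:0_18:1")`).
#' @return A single numeric correction factor.
#' @examples
#' correction_factor(parse_lipid_name("DG 15:0_18:1"))     # 0.5
#' correction_factor(parse_lipid_name("TG 16:0_18:1_18:2")) # 0.33
#' correction_factor(parse_lipid_name("TG 17:0_17:0_17:0")) # 1
#' @export
correction_factor <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (!species$lipid_class %in% c("DG", "TG")) return(1)
  if (is.null(species$acyl_chains)) {
    abort(sprintf(
      "%s species '%s' needs a chain-resolved name (e.g. 'TG 16:0_18:1_18:2') to assign a correction factor",
      species$lipid_class, species$name))
  }
  chains <- apply(species$acyl_chains, 1L,
                  function(ch) paste(ch, collapse = ":"))
  n_distinct <- length(unique(chains))
  if (species$lipid_class == "DG") {
    if (n_distinct == 2L) 0.5 else 1
  } else {
    switch(n_distinct, 1, 0.66, 0.33)  # 1, 2 or 3 distinct chains
  }
}

#' Cholesteryl-ester response factor
#'
#' Detection efficiency of CE species varies with the fatty-acyl chain
#' length and saturation; the instrument response is modeled by linear
#' equations fitted on an equimolar CE calibrant mixture, selected solely by
#' double-bond count: saturated (0 double bonds) y = 0.13x - 0.71,
#' monounsaturated (1) y = 1.13x - 0.23, polyunsaturated (>= 2)
#' y = -0.07x + 1.54, with x the fatty-acyl carbon chain length.
#'
#' @param carbons Fatty-acyl chain length.
#' @param double_bonds Number of double bonds.
#' @return The response factor (positive); errors if the line evaluates to a
#'   non-positive value at the requested chain length.
#' @examples
#' ce_response_factor(20, 0)  # 0.13*20 - 0.71 = 1.89
#' ce_response_factor(20, 4)  # -0.07*20 + 1.54 = 0.14
#' @export
ce_response_factor <- function(carbons, double_bonds) {
  stopifnot(is.numeric(carbons), is.numeric(double_bonds),
            carbons >= 0, double_bonds >= 0)
  y <- if (double_bonds == 0) {
    0.13 * carbons - 0.71
  } else if (double_bonds == 1) {
    1.13 * carbons - 0.23
  } else {
    -0.07 * carbons + 1.54
  }
  if (y <= 0) {
    abort(sprintf(
      "CE response factor is non-positive (%.3f) for chain length %g with %g double bond(s)",
      y, carbons, double_bonds))
  }
  y
}

#' Correct M+2 isotope overlap between same-class species
#'
#' Within a class, the M+2 isotopologue of a species co-elutes with and is
#' isobaric to the monoisotopic peak of the species with the same total
#' carbon count and one fewer double bond. Species are processed in
#' decreasing double-bond order so the already-corrected interferent area is
#' subtracted: corrected(S) = observed(S) - p2(S') * corrected(S'), with
#' p2(C) = C(C-1)/2 * a^2 on the full molecular carbon count (acyl carbons
#' plus class backbone). Negative results are clipped to zero and flagged.
#'
#' @param table Peak-area table with columns `sample_id, sample_type, batch,
#'   injection_order, transition_id, area`.
#' @param panel A `lipid_panel`.
#' @return The table with corrected quantifier areas and a logical
#'   `deisotope_clipped` column.
#' @export
deisotope <- function(table, panel) {
  assert_columns(table, c("sample_id", "transition_id", "area"),
                 "peak-area table")
  tr <- panel$transitions
  sp <- panel$species
  # interference map: for quantifier of species S, the partner S' with
  # same class/carbons and one more double bond
  partner <- dplyr::inner_join(
    sp,
    dplyr::transmute(sp,
      lipid_class, total_carbons,
      total_double_bonds = total_double_bonds - 1L,
      partner_species = species,
      partner_p2 = m2_fraction(molecular_carbons(lipid_class, total_carbons))),
    by = c("lipid_class", "total_carbons", "total_double_bonds"))

  out <- table
  out$deisotope_clipped <- FALSE
  quant_id <- function(species) paste(species, "quantifier", sep = "|")

  # process species by decreasing double-bond count so each interferent is
  # already corrected when subtracted
  ord <- partner[order(-partner$total_double_bonds), ]
  if (nrow(ord) > 0L) {
    idx_by_tid <- split(seq_len(nrow(out)), out$transition_id)
    for (i in seq_len(nrow(ord))) {
      tid <- quant_id(ord$species[i])
      ptid <- quant_id(ord$partner_species[i])
      rows <- idx_by_tid[[tid]]
      prows <- idx_by_tid[[ptid]]
      if (is.null(rows) || is.null(prows)) next
      # align by sample id
      pa <- out$area[prows][match(out$sample_id[rows], out$sample_id[prows])]
      pa[is.na(pa)] <- 0
      corrected <- out$area[rows] - ord$partner_p2[i] * pa
      clipped <- corrected < 0
      out$area[rows] <- pmax(corrected, 0)
      out$deisotope_clipped[rows] <- out$deisotope_clipped[rows] | clipped
    }
  }
  out
}

#' Quantify peak areas against class internal standards
#'
#' Semi-quantitation: for each analyte species,
#' `conc = area / area_ISTD * ISTD_conc / CF / RF`, where the acyl-chain
#' correction factor CF applies to chain-resolved DG/TG species and the
#' response factor RF to CE species; both default to 1 elsewhere. Samples
#' whose class internal standard is missing or has zero area get missing
#' concentrations for that class, flagged `istd_missing`.
#'
#' @param table (Deisotoped) peak-area table.
#' @param panel A `lipid_panel`.
#' @param cf_overrides Optional named numeric vector of per-species
#'   correction-factor overrides for DG/TG species reported at
#'   sum-composition level.
#' @return A concentration table: `sample_id, sample_type, batch,
#'   injection_order, species, lipid_class, concentration, flags` (units of
#'   the class ISTD concentration).
#' @export
quantify <- function(table, panel, cf_overrides = NULL) {
  assert_columns(table, c("sample_id", "sample_type", "batch",
                          "injection_order", "transition_id", "area"),
                 "peak-area table")
  tr <- panel$transitions
  istd <- panel$istd_map

  quant <- tr[tr$role == "quantifier", ]
  analyte <- quant[!quant$is_istd, ]

  factors <- tibble::tibble(species = analyte$species,
                            lipid_class = analyte$lipid_class,
                            divisor = species_divisors(analyte$species,
                                                       cf_overrides))
  factors <- dplyr::left_join(factors, istd, by = "lipid_class")

  # ISTD areas per (sample, class): via the istd species quantifier
  istd_tid <- paste(istd$istd_species, "quantifier", sep = "|")
  istd_areas <- table[table$transition_id %in% istd_tid,
                      c("sample_id", "transition_id", "area")]
  istd_areas$istd_species <- sub("\\|quantifier$", "", istd_areas$transition_id)
  istd_areas <- dplyr::rename(istd_areas[c("sample_id", "istd_species", "area")],
                              istd_area = "area")

  rows <- table[table$transition_id %in%
                  paste(factors$species, "quantifier", sep = "|"), ]
  rows$species <- sub("\\|quantifier$", "", rows$transition_id)
  rows <- dplyr::left_join(rows, factors, by = "species")
  rows <- dplyr::left_join(rows, istd_areas,
                           by = c("sample_id", "istd_species"))

  bad_istd <- is.na(rows$istd_area) | rows$istd_area <= 0
  rows$concentration <- ifelse(bad_istd, NA_real_,
    rows$area / rows$istd_area * rows$istd_conc / rows$divisor)
  rows$flags <- ifelse(bad_istd, "istd_missing", "")
  if ("deisotope_clipped" %in% names(rows)) {
    rows$flags <- paste0(rows$flags,
                         ifelse(rows$deisotope_clipped,
                                ifelse(nzchar(rows$flags), ";clipped", "clipped"),
                                ""))
  }
  out <- rows[c("sample_id", "sample_type", "batch", "injection_order",
                "species", "lipid_class", "concentration", "flags")]
  dplyr::arrange(tibble::as_tibble(out), .data$sample_id, .data$species)
}

#' Qualifier-ratio check for fatty-acid measurements
#'
#' Each fatty acid is monitored by two transitions that share masses but
#' differ in collision energy; the qualifier/quantifier area ratio is a
#' per-species constant established on pooled-QC injections. Measurements
#' whose ratio deviates from the reference by more than `tolerance`
#' (relative) are flagged as possibly interfered.
#'
#' @param quantifier_area,qualifier_area Measured areas.
#' @param reference_ratio Qualifier/quantifier ratio established on PQCs.
#' @param tolerance Relative tolerance (default 0.5 = +/-50%).
#' @return `"pass"` or `"flag"` (vectorized).
#' @export
fa_qualifier_check <- function(quantifier_area, qualifier_area,
                               reference_ratio, tolerance = 0.5) {
  stopifnot(reference_ratio > 0, tolerance > 0)
  ratio <- ifelse(quantifier_area > 0, qualifier_area / quantifier_area, NA)
  ok <- !is.na(ratio) &
    abs(ratio - reference_ratio) <= tolerance * reference_ratio
  ifelse(ok, "pass", "flag")
}
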