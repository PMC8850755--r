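# Species reproducibility filtering and projection-based run QC.

#' Filter species by pooled-QC reproducibility and blank contamination
#'
#' A species is retained only if its coefficient of variation across PQC
#' injections is below `threshold_pct` (default 20%) and its highest
#' sample-type mean is not in the blank extracts (strictly greatest mean in
#' blanks drops the species).
#'
#' @param conc Concentration table (normalized, long format) containing PQC
#'   and blank rows.
#' @param threshold_pct CoV threshold in percent.
#' @return List with `conc` (the table restricted to retained species) and
#'   `metrics` (per-species `cov_pqc`, `blank_max_flag`, `retained`,
#'   `reason`).
#' @export
qc_filter <- function(conc, threshold_pct = 20) {
  assert_columns(conc, c("sample_id", "sample_type", "species",
                         "concentration"), "concentration table")
  if (!any(conc$sample_type == "pqc")) {
    abort("no PQC rows present; cannot compute CoV")
  }
  per_species <- conc |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      cov_pqc = cov_pct(.data$concentration[.data$sample_type == "pqc"]),
      blank_max_flag = {
        means <- tapply(.data$concentration, .data$sample_type, mean,
                        na.rm = TRUE)
        "blank" %in% names(means) && length(means) > 1L &&
          is.finite(means[["blank"]]) &&
          all(means[["blank"]] > means[setdiff(names(means), "blank")],
              na.rm = TRUE)
      },
      .groups = "drop")
  per_species$retained <- !is.na(per_species$cov_pqc) &
    per_species$cov_pqc < threshold_pct & !per_species$blank_max_flag
  per_species$reason <- dplyr::case_when(
    per_species$retained ~ "",
    per_species$blank_max_flag & (is.na(per_species$cov_pqc) |
      per_species$cov_pqc >= threshold_pct) ~ "cov;blank_max",
    per_species$blank_max_flag ~ "blank_max",
    TRUE ~ "cov")
  keep <- per_species$species[per_species$retained]
  list(conc = conc[conc$species %in% keep, ], metrics = per_species)
}

#' Two-component projection QC of a run
#'
#' Principal components on log-scaled species concentrations; reports the
#' per-sample scores and, for replicate sample types (PQC, TQC, SRM), the
#' within-type dispersion (mean distance to the type centroid in the
#' 2-component plane) relative to the overall score dispersion. Tight
#' clustering of identical injections indicates a consistent run.
#'
#' @param conc Concentration table (long format, retained species).
#' @return List with `scores` (sample_id, sample_type, PC1, PC2),
#'   `dispersion` (per replicate type), and `variance_explained`.
#' @export
pca_qc <- function(conc) {
  w <- conc_to_wide(conc)
  if (nrow(w$mat) < 3L) {
    abort("≥ 3 samples required for projection QC")
  }
  logm <- log(apply(w$mat, 2L, impute_half_min))
  keep <- apply(logm, 2L, function(x) all(is.finite(x)) && sd(x) > 0)
  p <- prcomp(logm[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- tibble::tibble(
    sample_id = rownames(w$mat),
    sample_type = w$meta$sample_type,
    PC1 = p$x[, 1], PC2 = if (ncol(p$x) >= 2L) p$x[, 2] else 0)
  overall <- mean(sqrt((scores$PC1 - mean(scores$PC1))^2 +
                         (scores$PC2 - mean(scores$PC2))^2))
  disp <- scores |>
    dplyr::filter(.data$sample_type %in% c("pqc", "tqc", "srm")) |>
    dplyr::group_by(.data$sample_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      within = mean(sqrt((.data$PC1 - mean(.data$PC1))^2 +
                           (.data$PC2 - mean(.data$PC2))^2)),
      relative = .data$within / overall, .groups = "drop")
  list(scores = scores, dispersion = disp,
       variance_explained = summary(p)$importance[2, 1:min(2, ncol(p$x))])
}
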