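# Synthetic study generator, part 1: study design, ground truth, and the
# clinical cohort with latent per-subject lipid states. Defaults emulate a
# serial-sampling reperfusion study: 80 STEMI subjects sampled pre-PCI (t0),
# 2 h (t1) and 24 h (t2) post-PCI, a 30-subject subset followed to 48 h (t3)
# and 30 days (t4), and 50 angiography controls sampled once.

#' Study design for the synthetic generator
#'
#' @param n_stemi Number of STEMI subjects (default 80).
#' @param n_control Number of control subjects (default 50).
#' @param n_late_subset STEMI subjects with late timepoints t3/t4 (default 30).
#' @param batch_layout Injections per analytical batch by sample type:
#'   60 study, 20 pooled-QC, 6 technical-QC, 4 reference-material, 12 blank.
#' @return A `study_design` list.
#' @export
study_design <- function(n_stemi = 80, n_control = 50, n_late_subset = 30,
                         batch_layout = c(study = 60, pqc = 20, tqc = 6,
                                          srm = 4, blank = 12)) {
  stopifnot(n_late_subset <= n_stemi,
            all(c("study", "pqc", "tqc", "srm", "blank") %in%
                  names(batch_layout)))
  structure(list(
    n_stemi = n_stemi, n_control = n_control, n_late_subset = n_late_subset,
    timepoints = c("t0", "t1", "t2"), late_timepoints = c("t3", "t4"),
    batch_layout = batch_layout
  ), class = "study_design")
}

# mean per-species plasma concentration (uM) by class; class totals implement
# the abundance ranking top-5 CE > PC > PC(O) > LPC > SM and bottom-5
# acylcarnitine < Hex3Cer < LPC(O) < GM3 < PE(P)
CLASS_MEAN_CONC <- c(
  "CE" = 130, "PC" = 80, "PC(O)" = 30, "PC(P)" = 3, "LPC" = 25,
  "LPC(O)" = 0.12, "PE" = 8, "PE(O)" = 1, "PE(P)" = 0.2, "LPE" = 0.6,
  "PI" = 2, "PS" = 0.5, "PG" = 0.5, "SM" = 18, "Cer" = 0.5, "dhCer" = 0.3,
  "HexCer" = 0.4, "Hex2Cer" = 0.4, "Hex3Cer" = 0.1, "GM3" = 0.15,
  "DG" = 2, "TG" = 6, "FA" = 15, "acylcarnitine" = 0.06, "OxPL" = 0.4
)

# planted per-class fold multipliers relative to t0; shapes mirror the
# reperfusion phenotype being emulated: neutral lipids fall at 2 h and
# overshoot at 24 h, fatty acids decline through 24 h, oxidized
# phospholipids rise acutely, acylcarnitines and LPC reach a nadir at 48 h
default_class_multipliers <- function() {
  m <- function(cls, t1, t2, t3, t4) {
    tibble::tibble(lipid_class = cls, t0 = 1, t1 = t1, t2 = t2,
                   t3 = t3, t4 = t4)
  }
  dplyr::bind_rows(
    m("DG",  0.70, 0.70 * 1.64, 1.00, 0.95),
    m("TG",  0.76, 0.76 * 1.59, 0.95, 0.85),
    m("FA",  0.60, 0.255, 0.40, 0.90),
    m("OxPL", 1.30, 1.25, 1.05, 1.00),
    m("acylcarnitine", 0.85, 0.75, 0.60, 0.90),
    m("LPC",    0.85, 0.80, 0.70, 0.90),
    m("LPC(O)", 0.85, 0.80, 0.70, 0.90),
    purrr::map_dfr(c("PE", "PE(O)", "PE(P)", "LPE", "PI", "PS", "PG"),
                   m, t1 = 0.80, t2 = 0.80, t3 = 0.95, t4 = 1.00),
    purrr::map_dfr(c("SM", "Cer", "dhCer", "HexCer", "Hex2Cer", "Hex3Cer",
                     "GM3", "PC", "PC(O)", "PC(P)", "CE"),
                   m, t1 = 0.80, t2 = 1.00, t3 = 1.00, t4 = 1.00)
  )
}

# species-level multiplier overrides (rows replace the class rows for the
# named species): polyunsaturated membrane species with outsized acute shifts
default_species_multiplier_overrides <- function() {
  tibble::tribble(
    ~species,   ~t0, ~t1,  ~t2,  ~t3,  ~t4,
    "PC 36:6",  1, 0.60, 0.90, 1.00, 1.00,
    "PC 34:4",  1, 0.65, 0.90, 1.00, 1.00,
    "PE 40:5",  1, 0.65, 0.80, 0.95, 1.00,
    "PE 40:6",  1, 0.65, 0.80, 0.95, 1.00,
    "SM 37:2",  1, 0.70, 0.90, 1.00, 1.00
  )
}

#' Ground truth for the synthetic study
#'
#' Builds per-species base concentrations (log-normal spread around class
#' means, rescaled so class totals are exact), planted timepoint fold
#' multipliers, planted troponin-association coefficients, and planted
#' STEMI-vs-control group folds.
#'
#' @param panel A `lipid_panel` (default [default_panel()]).
#' @param between_subject_cv Biological coefficient of variation across
#'   subjects (default 0.30).
#' @param within_subject_cv Residual within-subject CV across timepoints
#'   beyond the planted multipliers (default 0.10).
#' @param delta_baseline Expected delta troponin (ng/L) for a subject with
#'   average marker levels (default 2400).
#' @param delta_noise_sd Gaussian noise on delta troponin (default 900 ng/L;
#'   0 makes delta a deterministic function of the planted effects).
#' @param troponin_series_cv Multiplicative noise on the serial troponin
#'   draws (default 0.03; 0 disables).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(panel = default_panel(), between_subject_cv = 0.30,
                         within_subject_cv = 0.10, delta_baseline = 2400,
                         delta_noise_sd = 900, troponin_series_cv = 0.03) {
  sp <- panel$species
  # deterministic per-species spread from a name hash (no RNG involved)
  u <- purrr::map_dbl(sp$species, function(s) {
    (fnv1a32(paste0("base/", s)) + 0.5) / 4294967296
  })
  z <- stats::qnorm(u)
  base <- unname(CLASS_MEAN_CONC[sp$lipid_class]) * exp(0.8 * z)
  # rescale within class so class totals equal n_species * class_mean exactly
  base_conc <- tibble::tibble(species = sp$species,
                              lipid_class = sp$lipid_class, base = base) |>
    dplyr::group_by(.data$lipid_class) |>
    dplyr::mutate(base = .data$base * dplyr::n() *
                    CLASS_MEAN_CONC[unique(.data$lipid_class)] /
                    sum(.data$base)) |>
    dplyr::ungroup()

  structure(list(
    base_conc = base_conc,
    class_multipliers = default_class_multipliers(),
    species_multiplier_overrides = default_species_multiplier_overrides(),
    # ng/L change in delta troponin per natural-log-unit of baseline lipid;
    # scaled so the marker associations reach the |t| ~ 2-3 regime a cohort
    # of 80 subjects resolves
    troponin_effects = c(
      "acylcarnitine 18:2" = 1800, "TG 51:0" = -1500, "LPC 17:1" = -1400,
      "PI 34:1" = -600, "PI 34:0" = -450, "LPC 18:0" = -450,
      "FA 18:2" = 500, "SM 38:2" = 400),
    group_effects_class = c("acylcarnitine" = 1.5, "LPC" = 1.3),
    group_effects_species = c("acylcarnitine 18:2" = 1.6, "LPC 17:1" = 1.5),
    between_subject_cv = between_subject_cv,
    within_subject_cv = within_subject_cv,
    delta_baseline = delta_baseline,
    delta_noise_sd = delta_noise_sd,
    troponin_series_cv = troponin_series_cv
  ), class = "ground_truth")
}

#' Per-species timepoint multiplier table implied by a ground truth
#'
#' @param truth A `ground_truth`.
#' @param panel The panel the truth was built on.
#' @return Tibble `species, lipid_class, t0..t4` of planted fold multipliers.
#' @export
planted_multipliers <- function(truth, panel = default_panel()) {
  tp_cols <- c("t0", "t1", "t2", "t3", "t4")
  base <- dplyr::left_join(panel$species[c("species", "lipid_class")],
                           truth$class_multipliers, by = "lipid_class")
  ov <- truth$species_multiplier_overrides
  hit <- match(base$species, ov$species)
  for (col in tp_cols) {
    base[[col]] <- ifelse(is.na(hit), base[[col]], ov[[col]][hit])
  }
  base
}

#' Generate the synthetic clinical cohort and latent lipid states
#'
#' Simulates covariates, per-subject true lipid concentrations at every
#' sampled timepoint (base concentration x between-subject log-normal
#' variation x planted timepoint multiplier x within-subject noise), a
#' serial troponin series whose peak is baseline + planted lipid effects +
#' noise, and a MACE indicator with probability increasing in delta
#' troponin.
#'
#' @param design A `study_design`.
#' @param truth A `ground_truth`.
#' @param seed Master seed; all randomness is drawn from named streams of it.
#' @return List with `clinical` (one row per subject), `troponin`
#'   (long: subject_id, time_h, tnt_ng_l), and `lipid_truth`
#'   (long: subject_id, timepoint, species, lipid_class, true_conc).
#' @export
generate_cohort <- function(design = study_design(),
                            truth = ground_truth(), seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))

  n_s <- design$n_stemi; n_c <- design$n_control
  ids_stemi <- sprintf("S%03d", seq_len(n_s))
  ids_ctrl <- sprintf("C%03d", seq_len(n_c))

  clinical <- with_stream(seed, "cohort", {
    tibble::tibble(
      subject_id = c(ids_stemi, ids_ctrl),
      group = rep(c("STEMI", "control"), c(n_s, n_c)),
      age = round(pmin(92, pmax(32, rnorm(n_s + n_c,
        mean = rep(c(63.7, 60.9), c(n_s, n_c)), sd = 12)))),
      sex = ifelse(runif(n_s + n_c) <
        rep(c(0.675, 0.62), c(n_s, n_c)), "M", "F"),
      bmi = round(rlnorm(n_s + n_c, log(28), 0.15), 1),
      smoker = runif(n_s + n_c) < rep(c(0.275, 0.12), c(n_s, n_c)),
      diabetes = runif(n_s + n_c) < rep(c(0.20, 0.14), c(n_s, n_c)),
      ischemic_time = ifelse(rep(c(TRUE, FALSE), c(n_s, n_c)),
        round(rlnorm(n_s + n_c, log(150), 0.55)), NA_real_)
    )
  })
  late_ids <- ids_stemi[seq_len(design$n_late_subset)]
  clinical$late_subset <- clinical$subject_id %in% late_ids

  # latent lipid states
  mult <- planted_multipliers(truth, panel_from_truth(truth))
  sdlog_bs <- sqrt(log(1 + truth$between_subject_cv^2))
  sdlog_ws <- sqrt(log(1 + truth$within_subject_cv^2))
  n_species <- nrow(truth$base_conc)

  subj_tp <- dplyr::bind_rows(
    tidyr::expand_grid(subject_id = ids_stemi,
                       timepoint = design$timepoints),
    tidyr::expand_grid(subject_id = late_ids,
                       timepoint = design$late_timepoints),
    tibble::tibble(subject_id = ids_ctrl, timepoint = "t0")
  )

  lipid_truth <- with_stream(seed, "lipids", {
    # per-subject baseline level per species
    all_ids <- c(ids_stemi, ids_ctrl)
    base_mat <- matrix(
      rlnorm(length(all_ids) * n_species, meanlog = 0, sdlog = sdlog_bs),
      nrow = length(all_ids), dimnames = list(all_ids, truth$base_conc$species))
    base_mat <- sweep(base_mat, 2L, truth$base_conc$base, `*`)
    # control group planted elevations are on the STEMI side: controls are
    # divided by the group fold
    gf <- rep(1, n_species)
    names(gf) <- truth$base_conc$species
    cls_hit <- truth$base_conc$lipid_class %in%
      names(truth$group_effects_class)
    gf[cls_hit] <- truth$group_effects_class[
      truth$base_conc$lipid_class[cls_hit]]
    sp_hit <- names(truth$group_effects_species)
    gf[sp_hit] <- truth$group_effects_species[sp_hit]
    base_mat[ids_ctrl, ] <- sweep(base_mat[ids_ctrl, , drop = FALSE],
                                  2L, gf, `/`)

    rows <- subj_tp
    tp_mult <- as.matrix(mult[c("t0", "t1", "t2", "t3", "t4")])
    rownames(tp_mult) <- mult$species
    out <- purrr::pmap_dfr(rows, function(subject_id, timepoint) {
      m <- tp_mult[truth$base_conc$species, timepoint]
      noise <- if (timepoint == "t0") 1 else
        rlnorm(n_species, 0, sdlog_ws)
      conc <- unname(base_mat[subject_id, ] * m * noise)
      tibble::tibble(
        subject_id = subject_id, timepoint = timepoint,
        species = truth$base_conc$species,
        lipid_class = truth$base_conc$lipid_class,
        true_conc = conc)
    })
    out
  })

  # troponin: delta = b0 + sum(effect_i * centered log baseline lipid) + noise
  trop <- with_stream(seed, "troponin", {
    eff <- truth$troponin_effects
    t0 <- lipid_truth[lipid_truth$timepoint == "t0" &
                        lipid_truth$subject_id %in% ids_stemi &
                        lipid_truth$species %in% names(eff), ]
    logbase <- log(truth$base_conc$base)
    names(logbase) <- truth$base_conc$species
    t0$centered <- log(t0$true_conc) - logbase[t0$species]
    contrib <- tapply(t0$centered * eff[t0$species], t0$subject_id, sum)
    contrib <- contrib[ids_stemi]
    delta <- pmax(60, truth$delta_baseline + contrib +
                    rnorm(n_s, 0, truth$delta_noise_sd))
    baseline <- rlnorm(n_s, log(120), 0.7)
    times <- c(0, 4, 8, 12, 24, 48, 72)
    shape <- c(0, 0.45, 0.85, 1, 0.8, 0.45, 0.2)
    tibble::tibble(
      subject_id = rep(ids_stemi, each = length(times)),
      time_h = rep(times, n_s),
      tnt_ng_l = rep(baseline, each = length(times)) +
        rep(delta, each = length(times)) * rep(shape, n_s) *
        rlnorm(n_s * length(times), 0, truth$troponin_series_cv))
  })

  clinical$mace <- FALSE
  deltas <- vapply(split(trop$tnt_ng_l, trop$subject_id)[ids_stemi],
                   function(x) max(x) - x[1], numeric(1))
  clinical$mace[match(ids_stemi, clinical$subject_id)] <- with_stream(
    seed, "mace",
    runif(n_s) < plogis(-1.9 + 1.2 * as.numeric(scale(deltas))))

  list(clinical = clinical, troponin = trop, lipid_truth = lipid_truth)
}

# the truth's base_conc carries the panel species; reconstruct the minimal
# species frame needed by planted_multipliers without re-deriving the panel
panel_from_truth <- function(truth) {
  list(species = truth$base_conc[c("species", "lipid_class")])
}
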