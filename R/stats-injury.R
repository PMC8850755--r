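# Myocardial-injury association statistics: delta troponin, covariate-
# adjusted per-lipid regressions, tertile and MACE stratification with fold
# changes, late-phase trajectories, and the STEMI-vs-control comparison.

#' Delta troponin for one subject
#'
#' The absolute change from the baseline (pre-PCI) troponin value to the
#' peak value of the series; the peak includes the baseline draw, so the
#' result is never negative.
#'
#' @param series Tibble or data frame with columns `time_h` and `tnt_ng_l`
#'   (the baseline is the row with the smallest time, which must be
#'   present), or a numeric vector whose first element is the baseline.
#' @param window_h Only draws within this many hours are considered
#'   (default Inf, i.e. the full series).
#' @return Delta troponin in ng/L.
#' @export
delta_troponin <- function(series, window_h = Inf) {
  if (is.numeric(series)) {
    series <- tibble::tibble(time_h = seq_along(series) - 1, tnt_ng_l = series)
  }
  assert_columns(series, c("time_h", "tnt_ng_l"), "troponin series")
  series <- series[is.finite(series$tnt_ng_l), ]
  if (nrow(series) < 2L) abort("need at least two troponin measurements")
  if (min(series$time_h) > 0) abort("no_baseline: no pre-PCI troponin draw")
  baseline <- series$tnt_ng_l[which.min(series$time_h)]
  peak <- max(series$tnt_ng_l[series$time_h <= window_h])
  max(0, peak - baseline)
}

#' Delta troponin for every subject in a cohort
#'
#' @param troponin Long troponin table (`subject_id, time_h, tnt_ng_l`).
#' @param window_h Passed to [delta_troponin()].
#' @return Tibble `subject_id, delta_tnt`.
#' @export
cohort_delta_troponin <- function(troponin, window_h = Inf) {
  assert_columns(troponin, c("subject_id", "time_h", "tnt_ng_l"),
                 "troponin table")
  parts <- split(troponin[c("time_h", "tnt_ng_l")], troponin$subject_id)
  tibble::tibble(
    subject_id = names(parts),
    delta_tnt = vapply(parts, delta_troponin, numeric(1),
                       window_h = window_h))
}

#' Covariate-adjusted lipid-troponin regression
#'
#' Ordinary least squares of delta troponin on the log lipid concentration,
#' adjusting for age, sex, BMI, current smoking, diabetes history, and
#' ischemic time (binary covariates coded 0/1, ischemic time in minutes).
#' Reports the unstandardized coefficient B of the log-lipid term with its
#' t-based 95% CI and two-sided p-value.
#'
#' @param delta Per-subject delta troponin (ng/L).
#' @param log_lipid Per-subject log concentration at one timepoint.
#' @param covariates Data frame with columns `age, sex, bmi, smoker,
#'   diabetes, ischemic_time` (sex as `"M"/"F"` or 0/1), or NULL for an
#'   unadjusted regression.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `B, ci_low, ci_high, p, n, significant, flag`.
#' @export
adjusted_regression <- function(delta, log_lipid, covariates = NULL,
                                conf_level = 0.95) {
  df <- data.frame(delta = delta, lipid = log_lipid)
  if (!is.null(covariates)) {
    assert_columns(covariates, c("age", "sex", "bmi", "smoker", "diabetes",
                                 "ischemic_time"), "covariate table")
    cv <- data.frame(
      age = covariates$age,
      sex = if (is.character(covariates$sex)) {
        as.integer(covariates$sex == "M")
      } else as.integer(covariates$sex),
      bmi = covariates$bmi,
      smoker = as.integer(covariates$smoker),
      diabetes = as.integer(covariates$diabetes),
      ischemic_time = covariates$ischemic_time)
    df <- cbind(df, cv)
  }
  df <- df[complete.cases(df), ]
  p_params <- ncol(df)  # intercept + slopes
  if (nrow(df) < p_params + 10L) {
    return(tibble::tibble(B = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_, n = nrow(df),
                          significant = FALSE, flag = "insufficient_n"))
  }
  fit <- lm(delta ~ ., data = df)
  flag <- "ok"
  if (kappa(model.matrix(fit), exact = FALSE) > 1e8) flag <- "collinear"
  est <- summary(fit)$coefficients["lipid", ]
  ci <- confint(fit, "lipid", level = conf_level)
  tibble::tibble(B = est[["Estimate"]], ci_low = ci[1], ci_high = ci[2],
                 p = est[["Pr(>|t|)"]], n = nrow(df),
                 significant = est[["Pr(>|t|)"]] < 1 - conf_level,
                 flag = flag)
}

#' Per-species regression screen at one timepoint
#'
#' @param conc Concentration table (study rows, one timepoint).
#' @param delta Tibble `subject_id, delta_tnt`.
#' @param clinical Clinical table with the covariate columns.
#' @param adjust Include the covariates (default TRUE). No multiplicity
#'   correction is applied across species: the screen reports raw p-values.
#' @return Tibble of [adjusted_regression()] results, one row per species.
#' @export
regression_screen <- function(conc, delta, clinical, adjust = TRUE) {
  assert_columns(conc, c("subject_id", "species", "concentration"),
                 "concentration table")
  merged <- dplyr::inner_join(conc, delta, by = "subject_id")
  merged <- dplyr::inner_join(merged, clinical, by = "subject_id")
  merged |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(d, key) {
      adjusted_regression(
        d$delta_tnt, log(impute_half_min(d$concentration)),
        covariates = if (adjust) d else NULL)
    }) |>
    dplyr::ungroup()
}

#' Tertile split of delta troponin
#'
#' Boundaries at the empirical 33.3rd/66.7th percentiles; the comparison
#' groups are the top tertile versus the combined middle and bottom
#' tertiles. Boundary ties go to the lower group. With n = 80 distinct
#' values this yields 27 vs 53 subjects.
#'
#' @param deltas Per-subject delta troponin values.
#' @return List with `labels` (`"top"`/`"lower"` per subject), `thresholds`
#'   (lower, upper), `n_top`, `n_lower`, and `flag` (`"degenerate"` when the
#'   split collapses).
#' @export
tertile_split <- function(deltas) {
  stopifnot(is.numeric(deltas), length(deltas) >= 3L)
  thresholds <- quantile(deltas, c(1, 2) / 3, names = FALSE)
  labels <- ifelse(deltas > thresholds[2], "top", "lower")
  n_top <- sum(labels == "top")
  flag <- if (n_top == 0L || n_top == length(deltas)) "degenerate" else "ok"
  list(labels = labels, thresholds = thresholds, n_top = n_top,
       n_lower = sum(labels == "lower"), flag = flag)
}

#' Group fold change with unpaired t-test
#'
#' log2 of the ratio of raw-scale group means, with a two-sided Student's
#' unpaired t-test on the log-transformed values. Both groups need at least
#' 3 observations.
#'
#' @param values Per-subject concentrations at one timepoint.
#' @param labels Two-level grouping; `group_a` is the numerator.
#' @param group_a Numerator level (default the first level encountered).
#' @return Tibble `log2_fc, p, n_a, n_b, significant`.
#' @export
group_fold_change <- function(values, labels, group_a = NULL) {
  stopifnot(length(values) == length(labels))
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  lv <- unique(labels)
  if (length(lv) != 2L) abort("labels must have exactly two levels")
  group_a <- group_a %||% lv[1]
  a <- values[labels == group_a]; b <- values[labels != group_a]
  if (length(a) < 3L || length(b) < 3L) {
    return(tibble::tibble(log2_fc = NA_real_, p = NA_real_,
                          n_a = length(a), n_b = length(b),
                          significant = FALSE))
  }
  la <- log(impute_half_min(a)); lb <- log(impute_half_min(b))
  p <- if (sd(c(la, lb)) == 0) 1 else
    tryCatch(t.test(la, lb, var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  tibble::tibble(log2_fc = log2(mean(a) / mean(b)), p = p,
                 n_a = length(a), n_b = length(b),
                 significant = !is.na(p) & p < 0.05)
}

#' Late-phase trajectory statistics
#'
#' For the prospectively followed subset with five timepoints (t0..t4):
#' per species, a repeated-measures ANOVA with Greenhouse-Geisser
#' correction over the five timepoints (complete cases), then pairwise
#' baseline comparisons (each later timepoint vs t0, Bonferroni m = 4) with
#' star categories at 0.05/0.01/0.001.
#'
#' @param conc Concentration table for the late-phase subset (study rows,
#'   timepoints t0..t4).
#' @param species Species (or class-total identifiers) to analyze; defaults
#'   to all present.
#' @return List with `anova` and `vs_baseline` tibbles.
#' @export
late_phase_trajectories <- function(conc, species = NULL) {
  assert_columns(conc, c("subject_id", "timepoint", "species",
                         "concentration"), "concentration table")
  tps <- c("t0", "t1", "t2", "t3", "t4")
  species <- species %||% unique(conc$species)
  res <- purrr::map(species, function(s) {
    d <- conc[conc$species == s & conc$timepoint %in% tps, ]
    wide <- tidyr::pivot_wider(d, id_cols = "subject_id",
                               names_from = "timepoint",
                               values_from = "concentration")
    present <- intersect(tps, names(wide))
    raw <- as.matrix(wide[, present])
    raw <- raw[complete.cases(raw), , drop = FALSE]
    logm <- log(apply(raw, 2L, impute_half_min))
    a <- rm_anova_gg(logm)
    anova_row <- tibble::tibble(species = s, F = a$F, gg_epsilon = a$gg_epsilon,
                                p_gg = a$p_gg, n = a$n, flag = a$flag)
    if (a$flag == "insufficient_n" || length(present) < 2L) {
      return(list(anova = anova_row, vs_baseline = tibble::tibble()))
    }
    m <- length(present) - 1L
    vs <- purrr::map_dfr(setdiff(present, "t0"), function(tp) {
      pt <- t.test(logm[, tp], logm[, "t0"], paired = TRUE)$p.value
      pc <- min(1, pt * m)
      tibble::tibble(
        species = s, timepoint = tp,
        mean_log_change = mean(logm[, tp] - logm[, "t0"]),
        p = pt, p_corrected = pc,
        stars = dplyr::case_when(pc < 0.001 ~ "***", pc < 0.01 ~ "**",
                                 pc < 0.05 ~ "*", TRUE ~ ""))
    })
    list(anova = anova_row, vs_baseline = vs)
  })
  list(anova = purrr::map_dfr(res, "anova"),
       vs_baseline = purrr::map_dfr(res, "vs_baseline"))
}

#' STEMI-vs-control comparison
#'
#' Unpaired two-sided Student's t-test on log values for the listed species
#' and their class totals, pre-PCI STEMI samples against control samples.
#'
#' @param stemi_conc Concentration table for STEMI t0 study samples.
#' @param control_conc Concentration table for control samples.
#' @param species Species to test; empty input yields an empty result.
#' @param include_class_totals Also test each listed species' class total.
#' @return Tibble with one row per comparison (`unit` is `"species"` or
#'   `"class_total"`).
#' @export
control_comparison <- function(stemi_conc, control_conc, species,
                               include_class_totals = TRUE) {
  if (length(species) == 0L) {
    return(tibble::tibble(target = character(), unit = character(),
                          log2_fc = numeric(), p = numeric(),
                          n_a = integer(), n_b = integer(),
                          significant = logical()))
  }
  one <- function(target, va, vb, unit) {
    fc <- group_fold_change(c(va, vb),
                            rep(c("stemi", "control"),
                                c(length(va), length(vb))),
                            group_a = "stemi")
    dplyr::mutate(fc, target = target, unit = unit, .before = 1L)
  }
  sp_rows <- purrr::map_dfr(species, function(s) {
    one(s, stemi_conc$concentration[stemi_conc$species == s],
        control_conc$concentration[control_conc$species == s], "species")
  })
  if (!include_class_totals) return(sp_rows)
  classes <- unique(stemi_conc$lipid_class[match(species, stemi_conc$species)])
  classes <- classes[!is.na(classes)]
  tot_s <- class_totals(stemi_conc)
  tot_c <- class_totals(control_conc)
  cl_rows <- purrr::map_dfr(classes, function(cl) {
    one(paste("total", cl), tot_s$total[tot_s$lipid_class == cl],
        tot_c$total[tot_c$lipid_class == cl], "class_total")
  })
  dplyr::bind_rows(sp_rows, cl_rows)
}
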