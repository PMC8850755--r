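# Repeated-measures statistics over the sampling timepoints: one-way
# within-subject ANOVA with the Greenhouse-Geisser sphericity correction,
# Bonferroni-corrected pairwise paired comparisons, class totals, percent
# differences with bootstrap SEM, within-class composition log-ratios, and
# hierarchically clustered heatmap data.

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One within-subject factor. F comes from the standard within-subject
#' decomposition; the sphericity correction epsilon is estimated from the
#' sample covariance matrix of the timepoint measurements (orthonormal
#' contrast form) and clamped to `[1/(k-1), 1]`; the p-value uses
#' `F(eps*(k-1), eps*(k-1)*(n-1))` degrees of freedom.
#'
#' @param values Numeric matrix, subjects x timepoints. Rows with missing
#'   values are dropped (complete-case analysis).
#' @return List with `F`, `gg_epsilon`, `p_gg`, `p_uncorrected`, `df`,
#'   `n`, `k`, and `flag` (`"ok"` or `"insufficient_n"`).
#' @examples
#' m <- matrix(rnorm(60), 20, 3)
#' rm_anova_gg(m)
#' @export
rm_anova_gg <- function(values) {
  values <- as.matrix(values)
  values <- values[complete.cases(values), , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  if (k < 2L) abort("need at least two timepoints")
  if (n < 3L) {
    return(list(F = NA_real_, gg_epsilon = NA_real_, p_gg = NA_real_,
                p_uncorrected = NA_real_, df = c(NA_real_, NA_real_),
                n = n, k = k, flag = "insufficient_n"))
  }
  grand <- mean(values)
  subj_means <- rowMeans(values)
  time_means <- colMeans(values)
  ss_time <- n * sum((time_means - grand)^2)
  resid <- sweep(sweep(values, 1L, subj_means), 2L, time_means) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  if (ss_time <= .Machine$double.eps * abs(grand + 1)) {
    return(list(F = 0, gg_epsilon = 1, p_gg = 1, p_uncorrected = 1,
                df = c(df1, df2), n = n, k = k, flag = "ok"))
  }
  Fstat <- (ss_time / df1) / (ss_err / df2)

  # epsilon from orthonormal contrasts of the sample covariance matrix
  S <- stats::cov(values)
  C <- contr_orthonormal(k)
  M <- t(C) %*% S %*% C
  tr <- sum(diag(M))
  eps <- if (tr <= 0 || sum(M^2) <= 0) 1 else tr^2 / (df1 * sum(M * M))
  eps <- min(1, max(1 / df1, eps))

  p_gg <- pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)
  list(F = Fstat, gg_epsilon = eps, p_gg = p_gg,
       p_uncorrected = pf(Fstat, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), n = n, k = k, flag = "ok")
}

# orthonormal polynomial-style contrasts (k x k-1), t(C) %*% C = I
contr_orthonormal <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2L, sqrt(colSums(C^2)), `/`)
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Paired t-tests for every timepoint pair, with
#' `p_corrected = min(1, p * m)` where m is the number of pairs; a species
#' is called significant at a pair when the corrected p is below `alpha`.
#'
#' @param values Subjects x timepoints matrix (complete cases used per pair).
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble `pair, mean_diff, percent_difference, sem, p, p_corrected,
#'   significant`.
#' @export
pairwise_bonferroni <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  k <- ncol(values)
  tps <- colnames(values) %||% paste0("t", seq_len(k) - 1L)
  colnames(values) <- tps
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ok <- complete.cases(values[, c(a, b)])
    va <- values[ok, a]; vb <- values[ok, b]
    diffs <- vb - va
    p <- if (sum(ok) < 3L || sd(diffs) == 0) {
      if (all(diffs == 0)) 1 else NA_real_
    } else {
      t.test(vb, va, paired = TRUE)$p.value
    }
    pd <- if (mean(va) != 0) 100 * (mean(vb) - mean(va)) / mean(va) else NA_real_
    tibble::tibble(
      pair = paste(tps[a], tps[b], sep = "_vs_"),
      mean_diff = mean(diffs),
      percent_difference = pd,
      sem = sd(diffs) / sqrt(sum(ok)),
      p = p,
      p_corrected = pmin(1, p * m),
      significant = !is.na(p) & pmin(1, p * m) < alpha)
  })
}

#' Percent difference between two timepoints with bootstrap SEM
#'
#' `100 * (mean_b - mean_a) / mean_a` on the untransformed concentration
#' scale; the SEM is the standard deviation of the statistic over
#' nonparametric bootstrap resamples of subjects.
#'
#' @param a,b Paired per-subject values at the two timepoints.
#' @param n_boot Bootstrap draws (default 2000).
#' @param seed Seed for the bootstrap.
#' @return List with `percent_difference` and `sem`.
#' @export
percent_difference <- function(a, b, n_boot = 2000, seed = 1L) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  pd <- 100 * (mean(b) - mean(a)) / mean(a)
  sem <- with_stream(seed, "pd_boot", {
    n <- length(a)
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      100 * (mean(b[idx]) - mean(a[idx])) / mean(a[idx])
    }, numeric(1))
    sd(boots)
  })
  list(percent_difference = pd, sem = sem)
}

#' Per-sample class totals
#'
#' Sums retained species concentrations within each lipid class per sample;
#' missing values are excluded from the sum and reported as reduced
#' coverage.
#'
#' @param conc Concentration table (long format with `lipid_class`).
#' @return Tibble `sample_id, sample_type, subject_id, timepoint,
#'   lipid_class, total, n_species, coverage`.
#' @export
class_totals <- function(conc) {
  assert_columns(conc, c("sample_id", "species", "lipid_class",
                         "concentration"), "concentration table")
  keep <- intersect(c("sample_id", "sample_type", "subject_id", "timepoint"),
                    names(conc))
  conc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keep, "lipid_class")))) |>
    dplyr::summarise(
      total = sum(.data$concentration, na.rm = TRUE),
      n_species = dplyr::n(),
      coverage = mean(is.finite(.data$concentration)),
      .groups = "drop")
}

#' Within-class composition log-ratios across timepoints
#'
#' Per sample, each species' share of its class total; the reported value is
#' the log2 ratio of the mean share at each timepoint to the mean share at
#' the reference timepoint. Uniform scaling of a class within a sample
#' leaves the shares, and hence the ratios, unchanged.
#'
#' @param conc Concentration table for study samples with `subject_id` and
#'   `timepoint` columns.
#' @param lipid_class Class to analyze.
#' @param reference Reference timepoint (default `"t0"`).
#' @return Tibble `species, timepoint, mean_share, log2_ratio`.
#' @export
within_class_log_ratio <- function(conc, lipid_class, reference = "t0") {
  assert_columns(conc, c("sample_id", "species", "lipid_class",
                         "concentration", "timepoint"),
                 "concentration table")
  cls <- conc[conc$lipid_class == lipid_class &
                is.finite(conc$concentration), ]
  if (nrow(cls) == 0L) abort(sprintf("no data for class '%s'", lipid_class))
  shares <- cls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(share = .data$concentration /
                    sum(.data$concentration)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$species, .data$timepoint) |>
    dplyr::summarise(mean_share = mean(.data$share), .groups = "drop")
  ref <- shares[shares$timepoint == reference, c("species", "mean_share")]
  names(ref)[2] <- "ref_share"
  out <- dplyr::left_join(shares, ref, by = "species")
  out$log2_ratio <- log2(out$mean_share / out$ref_share)
  out[c("species", "timepoint", "mean_share", "log2_ratio")]
}

#' Hierarchically clustered heatmap data
#'
#' Euclidean-distance, complete-linkage clustering of log-transformed
#' species rows (and optionally sample columns); returns the orderings, the
#' row dendrogram, and the matrix to plot.
#'
#' @param mat Species x samples numeric matrix (raw concentrations; log
#'   applied internally with half-minimum imputation per species).
#' @param cluster_columns Also cluster the columns (default TRUE).
#' @return List with `matrix` (log-transformed), `row_order`, `col_order`,
#'   `row_hclust`, and `col_hclust` (NULL if not clustered).
#' @export
cluster_heatmap_data <- function(mat, cluster_columns = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  logm <- t(apply(mat, 1L, impute_half_min))
  logm <- log(logm)
  dimnames(logm) <- dimnames(mat)
  hr <- hclust(dist(logm, method = "euclidean"), method = "complete")
  hc <- if (cluster_columns && ncol(logm) >= 2L) {
    hclust(dist(t(logm), method = "euclidean"), method = "complete")
  }
  list(matrix = logm,
       row_order = rownames(mat)[hr$order] %||% hr$order,
       col_order = if (!is.null(hc)) (colnames(mat)[hc$order] %||% hc$order),
       row_hclust = hr, col_hclust = hc)
}

#' Species-level temporal screen
#'
#' Runs the repeated-measures ANOVA with Greenhouse-Geisser correction and
#' Bonferroni pairwise comparisons for every species, on log-transformed
#' concentrations (half-minimum imputation for non-positive values),
#' complete-case per species. Percent differences are computed on the raw
#' scale.
#'
#' @param conc Concentration table for study samples with `subject_id` and
#'   `timepoint` columns.
#' @param timepoints Ordered timepoints to include (default t0, t1, t2).
#' @param alpha Significance level on the corrected p.
#' @return List with `anova` (per species) and `pairwise` (per species and
#'   pair).
#' @export
species_temporal_screen <- function(conc, timepoints = c("t0", "t1", "t2"),
                                    alpha = 0.05) {
  assert_columns(conc, c("subject_id", "timepoint", "species",
                         "concentration", "sample_type"),
                 "concentration table")
  conc <- conc[conc$timepoint %in% timepoints & conc$sample_type == "study", ]
  species <- unique(conc$species)
  res <- purrr::map(species, function(s) {
    d <- conc[conc$species == s, ]
    wide <- tidyr::pivot_wider(d, id_cols = "subject_id",
                               names_from = "timepoint",
                               values_from = "concentration")
    raw <- as.matrix(wide[, timepoints])
    raw <- raw[complete.cases(raw), , drop = FALSE]
    logm <- log(apply(raw, 2L, impute_half_min))
    a <- rm_anova_gg(logm)
    pw <- pairwise_bonferroni(logm, alpha = alpha)
    # percent differences on the raw scale
    raw_pd <- pairwise_bonferroni(raw, alpha = alpha)
    pw$percent_difference <- raw_pd$percent_difference
    list(anova = tibble::tibble(species = s, F = a$F,
                                gg_epsilon = a$gg_epsilon, p_gg = a$p_gg,
                                n = a$n, flag = a$flag),
         pairwise = dplyr::mutate(pw, species = s, .before = 1L))
  })
  list(anova = purrr::map_dfr(res, "anova"),
       pairwise = purrr::map_dfr(res, "pairwise"))
}
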