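# Pooled-QC anchored drift normalization. The primary method regresses each
# species' pooled-QC (PQC) intensity on injection order, batch, and the
# intensities of its most PQC-correlated companion species with a random
# forest, then divides every injection by the predicted systematic
# component (SERRF-style). A deterministic loess fallback implements the
# same contract per species/batch against injection order alone.

conc_to_wide <- function(conc) {
  assert_columns(conc, c("sample_id", "sample_type", "batch",
                         "injection_order", "species", "concentration"),
                 "concentration table")
  meta <- dplyr::distinct(conc[c("sample_id", "sample_type", "batch",
                                 "injection_order")])
  wide <- tidyr::pivot_wider(conc, id_cols = "sample_id",
                             names_from = "species",
                             values_from = "concentration")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$sample_id
  meta <- meta[match(rownames(mat), meta$sample_id), ]
  list(mat = mat, meta = meta)
}

wide_to_conc <- function(mat, conc) {
  idx <- cbind(match(conc$sample_id, rownames(mat)),
               match(conc$species, colnames(mat)))
  out <- conc
  out$concentration <- mat[idx]
  out
}

# rescale each species so the PQC median is exactly preserved
preserve_pqc_median <- function(norm_mat, raw_mat, pqc_rows) {
  for (j in seq_len(ncol(norm_mat))) {
    med_raw <- median(raw_mat[pqc_rows, j], na.rm = TRUE)
    med_norm <- median(norm_mat[pqc_rows, j], na.rm = TRUE)
    if (is.finite(med_raw) && is.finite(med_norm) && med_norm > 0) {
      norm_mat[, j] <- norm_mat[, j] * med_raw / med_norm
    }
  }
  norm_mat
}

#' Random-forest pooled-QC drift normalization
#'
#' Per species: a random forest is trained on PQC injections to predict the
#' species' log concentration from injection order, batch, and the log
#' concentrations of the `k_correlated` most PQC-correlated other species;
#' the fitted values over all injections are the systematic (drift)
#' component, and every measurement is scaled by
#' `median(PQC) / predicted`. PQC medians are preserved exactly.
#'
#' @param conc Concentration table from [quantify()] (long format, PQC rows
#'   carried as `sample_type == "pqc"`).
#' @param k_correlated Companion species count (default 10).
#' @param trees Random-forest size (default 500).
#' @param seed Seed for forest construction.
#' @param min_pqc Minimum PQC injections per batch; below this the function
#'   falls back to [loess_normalize()] with a warning.
#' @return The concentration table with normalized concentrations.
#' @export
serrf_normalize <- function(conc, k_correlated = 10, trees = 500, seed = 1L,
                            min_pqc = 5L) {
  w <- conc_to_wide(conc)
  pqc_rows <- which(w$meta$sample_type == "pqc")
  if (length(pqc_rows) == 0L) {
    abort("no PQC samples present; cannot drift-normalize")
  }
  pqc_per_batch <- table(w$meta$batch[pqc_rows])
  if (length(pqc_per_batch) < length(unique(w$meta$batch)) ||
      any(pqc_per_batch < min_pqc)) {
    warn("fewer than the required PQC injections in at least one batch; falling back to loess normalization")
    return(loess_normalize(conc))
  }

  logm <- log(apply(w$mat, 2L, impute_half_min))
  # degenerate species (zero everywhere) stay untouched
  usable <- apply(logm, 2L, function(x) all(is.finite(x)) && sd(x) > 0)
  pqc_cor <- stats::cor(logm[pqc_rows, usable, drop = FALSE])

  # Companion features are standardized separately within the PQC stratum
  # and within the remaining injections. The forest is trained on
  # PQC-scaled features and applied to stratum-scaled features, so only a
  # companion's position within its own stratum - its drift component - is
  # carried into the prediction, not biological differences between study
  # samples and the pooled QC.
  scale_cols <- function(m) {
    apply(m, 2L, function(x) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) s <- 1
      (x - mean(x)) / s
    })
  }
  Z <- logm
  Z[pqc_rows, ] <- scale_cols(logm[pqc_rows, , drop = FALSE])
  Z[-pqc_rows, ] <- scale_cols(logm[-pqc_rows, , drop = FALSE])

  norm <- w$mat
  batch_f <- as.numeric(factor(w$meta$batch))
  base_df <- data.frame(.order = w$meta$injection_order, .batch = batch_f)

  usable_names <- colnames(logm)[usable]
  for (s in usable_names) {
    companions <- names(sort(abs(pqc_cor[s, setdiff(usable_names, s)]),
                             decreasing = TRUE))
    companions <- head(companions, k_correlated)
    df <- cbind(base_df, as.data.frame(Z[, companions, drop = FALSE]))
    names(df) <- c(".order", ".batch", paste0("x", seq_along(companions)))
    df$y <- logm[, s]
    fit <- ranger::ranger(
      y ~ ., data = df[pqc_rows, ], num.trees = trees,
      seed = stream_seed(seed, paste0("serrf/", s)), num.threads = 1L,
      respect.unordered.factors = TRUE)
    pred <- predict(fit, data = df, num.threads = 1L)$predictions
    med_pqc <- median(w$mat[pqc_rows, s], na.rm = TRUE)
    norm[, s] <- w$mat[, s] * med_pqc / exp(pred)
  }
  norm <- preserve_pqc_median(norm, w$mat, pqc_rows)
  wide_to_conc(norm, conc)
}

#' Loess pooled-QC drift normalization
#'
#' Deterministic fallback for [serrf_normalize()]: per species and batch, a
#' local regression of PQC log concentration on injection order gives the
#' systematic component; every injection is scaled by
#' `median(PQC) / predicted`. Batches with too few PQCs for a loess fit use
#' a linear fit; PQC medians are preserved exactly.
#'
#' @param conc Concentration table (long format).
#' @param span Loess span (default 0.9).
#' @return The concentration table with normalized concentrations.
#' @export
loess_normalize <- function(conc, span = 0.9) {
  w <- conc_to_wide(conc)
  pqc_rows <- which(w$meta$sample_type == "pqc")
  if (length(pqc_rows) == 0L) {
    abort("no PQC samples present; cannot drift-normalize")
  }
  norm <- w$mat
  logm <- log(apply(w$mat, 2L, impute_half_min))
  for (s in colnames(w$mat)) {
    if (!all(is.finite(logm[, s])) || sd(logm[, s]) == 0) next
    med_pqc <- median(w$mat[pqc_rows, s], na.rm = TRUE)
    for (b in unique(w$meta$batch)) {
      rows_b <- which(w$meta$batch == b)
      pqc_b <- intersect(rows_b, pqc_rows)
      if (length(pqc_b) < 2L) next
      o <- w$meta$injection_order[pqc_b]
      y <- logm[pqc_b, s]
      pred <- if (length(pqc_b) >= 5L) {
        fit <- tryCatch(
          loess(y ~ o, span = span, degree = 1L,
                control = stats::loess.control(surface = "direct")),
          error = function(e) NULL)
        if (is.null(fit)) NULL else
          predict(fit, newdata = data.frame(o = w$meta$injection_order[rows_b]))
      }
      if (is.null(pred)) {
        fit <- lm(y ~ o)
        pred <- predict(fit,
                        newdata = data.frame(o = w$meta$injection_order[rows_b]))
      }
      norm[rows_b, s] <- w$mat[rows_b, s] * med_pqc / exp(pred)
    }
  }
  norm <- preserve_pqc_median(norm, w$mat, pqc_rows)
  wide_to_conc(norm, conc)
}
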