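# mean-form Greenhouse-Geisser epsilon (independent of the orthonormal
# contrast route used by the implementation)
gg_epsilon_oracle <- function(values) {
  S <- stats::cov(values)
  k <- ncol(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  rowbar <- rowMeans(S)
  num <- k^2 * (dbar - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2)
  num / den
}

test_that("constant responses give F = 0 and p = 1", {
  m <- matrix(rep(c(1, 5, 2, 7), times = 3), ncol = 3)
  res <- rm_anova_gg(m)
  expect_equal(res$F, 0)
  expect_equal(res$p_gg, 1)
})

test_that("with two timepoints the RM-ANOVA equals the paired t-test", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    m <- matrix(rnorm(2 * n, sd = runif(1, 0.5, 3)), ncol = 2)
    m[, 2] <- m[, 2] + runif(1, -1, 1)
    res <- rm_anova_gg(m)
    tt <- t.test(m[, 1], m[, 2], paired = TRUE)
    expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
    expect_equal(res$gg_epsilon, 1)
    expect_equal(res$p_gg, tt$p.value, tolerance = 1e-10)
  }
})

test_that("epsilon matches the covariance-mean oracle and approaches 1 under
           compound symmetry", {
  set.seed(102)
  eps_hat <- replicate(20, {
    subject <- rnorm(200, sd = 1)
    m <- subject + matrix(rnorm(200 * 3, sd = 0.7), ncol = 3)
    res <- rm_anova_gg(m)
    expect_equal(res$gg_epsilon,
                 min(1, max(0.5, gg_epsilon_oracle(m))), tolerance = 1e-10)
    res$gg_epsilon
  })
  expect_gt(mean(eps_hat), 0.9)
})

test_that("insufficient subjects are flagged, not errored", {
  res <- rm_anova_gg(matrix(rnorm(4), ncol = 2))
  expect_equal(res$flag, "insufficient_n")
  expect_true(is.na(res$p_gg))
})

test_that("Bonferroni pairwise comparisons scale p by the number of pairs", {
  set.seed(103)
  m <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("t0", "t1", "t2")))
  pw <- pairwise_bonferroni(m)
  expect_equal(nrow(pw), 3L)  # k(k-1)/2
  expect_equal(pw$p_corrected, pmin(1, pw$p * 3))
  # identical groups -> corrected p = 1
  ident <- cbind(t0 = m[, 1], t1 = m[, 1])
  expect_equal(pairwise_bonferroni(ident)$p_corrected, 1)
  # the rule itself: p = 0.02 with m = 3 is not significant
  expect_false(0.02 * 3 < 0.05)
})

test_that("percent differences follow the raw-scale mean formula", {
  a <- c(10, 10, 10, 10)
  expect_equal(percent_difference(a, a, n_boot = 50)$percent_difference, 0)
  pd <- percent_difference(a, c(7, 7, 7, 7), n_boot = 50)
  expect_equal(pd$percent_difference, -30)
  # reciprocal property: (1 + d_ab/100)(1 + d_ba/100) = 1
  set.seed(104)
  x <- rlnorm(30, 3, 0.3); y <- rlnorm(30, 2.8, 0.3)
  d_ab <- percent_difference(x, y, n_boot = 50)$percent_difference
  d_ba <- percent_difference(y, x, n_boot = 50)$percent_difference
  expect_equal((1 + d_ab / 100) * (1 + d_ba / 100), 1, tolerance = 1e-10)
  # bootstrap SEM is positive and seeded-reproducible
  s1 <- percent_difference(x, y, n_boot = 200, seed = 9)$sem
  s2 <- percent_difference(x, y, n_boot = 200, seed = 9)$sem
  expect_gt(s1, 0)
  expect_identical(s1, s2)
})

test_that("class totals sum retained species and ignore species order", {
  conc <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 3),
    sample_type = "study",
    species = rep(c("PC 34:1", "PC 36:2", "TG 50:1"), 2),
    lipid_class = rep(c("PC", "PC", "TG"), 2),
    concentration = c(1, 2, 5, 3, 4, 7))
  tot <- class_totals(conc)
  expect_equal(tot$total[tot$sample_id == "a" & tot$lipid_class == "PC"], 3)
  expect_equal(tot$total[tot$sample_id == "b" & tot$lipid_class == "TG"], 7)
  shuffled <- conc[c(3, 1, 2, 6, 5, 4), ]
  tot2 <- class_totals(shuffled)
  expect_equal(dplyr::arrange(tot2, sample_id, lipid_class)$total,
               dplyr::arrange(tot, sample_id, lipid_class)$total)
  # single-species class total equals that species
  expect_equal(tot$n_species[tot$lipid_class == "TG"], c(1L, 1L))
})

test_that("within-class log-ratios are invariant to uniform class scaling", {
  set.seed(105)
  conc <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", 1:6),
    timepoint = c("t0", "t1"),
    species = c("PC 34:1", "PC 36:2", "PC 36:6")) |>
    dplyr::mutate(
      sample_id = paste(subject_id, timepoint, sep = "_"),
      lipid_class = "PC",
      concentration = rlnorm(dplyr::n(), 2, 0.1))
  base <- within_class_log_ratio(conc, "PC")
  doubled <- dplyr::mutate(conc, concentration = concentration * 2)
  expect_equal(within_class_log_ratio(doubled, "PC")$log2_ratio,
               base$log2_ratio)
  # a single-species class always has share 1 and log-ratio 0
  single <- dplyr::filter(conc, species == "PC 34:1")
  res <- within_class_log_ratio(single, "PC")
  expect_true(all(res$mean_share == 1))
  expect_true(all(res$log2_ratio == 0))
})

test_that("a planted share shift yields a positive log-ratio with
           compensating negatives", {
  set.seed(106)
  conc <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", 1:20),
    timepoint = c("t0", "t1"),
    species = c("PC 34:1", "PC 36:2", "PC 36:6")) |>
    dplyr::mutate(
      sample_id = paste(subject_id, timepoint, sep = "_"),
      lipid_class = "PC",
      concentration = rlnorm(dplyr::n(), 2, 0.05) *
        ifelse(species == "PC 36:6" & timepoint == "t1", 1.5, 1))
  res <- within_class_log_ratio(conc, "PC")
  t1 <- res[res$timepoint == "t1", ]
  expect_gt(t1$log2_ratio[t1$species == "PC 36:6"], 0)
  expect_lt(t1$log2_ratio[t1$species == "PC 34:1"], 0)
  expect_lt(t1$log2_ratio[t1$species == "PC 36:2"], 0)
})

# naive complete-linkage agglomeration for the clustering oracle
complete_linkage_oracle <- function(d) {
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  diag(dm) <- Inf
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      h <- max(dm[active[[i]], active[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- c(active[-c(best[2], best[3])], list(merged))
  }
  heights
}

test_that("heatmap clustering matches a brute-force agglomeration oracle", {
  set.seed(107)
  mat <- matrix(rlnorm(4 * 6, 3, 1), nrow = 4,
                dimnames = list(paste0("sp", 1:4), paste0("s", 1:6)))
  res <- cluster_heatmap_data(mat, cluster_columns = FALSE)
  oracle <- complete_linkage_oracle(dist(res$matrix))
  expect_equal(sort(res$row_hclust$height), sort(oracle), tolerance = 1e-10)

  # identical rows merge at height zero
  mat2 <- mat; mat2[2, ] <- mat2[1, ]
  res2 <- cluster_heatmap_data(mat2, cluster_columns = FALSE)
  expect_equal(min(res2$row_hclust$height), 0)
})

test_that("three planted abundance tiers are recovered by a 3-cut", {
  set.seed(108)
  tiers <- rep(c(1, 100, 10000), each = 5)
  mat <- matrix(rlnorm(15 * 8, log(tiers), 0.2), nrow = 15,
                dimnames = list(sprintf("sp%02d", 1:15), NULL))
  res <- cluster_heatmap_data(mat, cluster_columns = FALSE)
  cut <- cutree(res$row_hclust, k = 3)
  expect_equal(length(unique(paste(cut, rep(1:3, each = 5)))), 3L)
})
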