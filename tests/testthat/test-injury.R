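test_that("delta troponin is peak minus baseline, never negative", {
  series <- tibble::tibble(time_h = c(0, 4, 8, 12),
                           tnt_ng_l = c(120, 900, 5943.5, 3000))
  expect_equal(delta_troponin(series), 5823.5)
  flat <- tibble::tibble(time_h = c(0, 4, 8), tnt_ng_l = c(100, 100, 100))
  expect_equal(delta_troponin(flat), 0)
  declining <- tibble::tibble(time_h = c(0, 4), tnt_ng_l = c(500, 100))
  expect_equal(delta_troponin(declining), 0)
  no_baseline <- tibble::tibble(time_h = c(4, 8), tnt_ng_l = c(100, 400))
  expect_error(delta_troponin(no_baseline), "no_baseline")
  expect_error(delta_troponin(tibble::tibble(time_h = 0, tnt_ng_l = 100)),
               "two")
  # a peak window excludes later draws
  late_peak <- tibble::tibble(time_h = c(0, 24, 96),
                              tnt_ng_l = c(100, 600, 2000))
  expect_equal(delta_troponin(late_peak, window_h = 72), 500)
})

test_that("adjusted regression with null covariates equals the
           normal-equations solve", {
  set.seed(201)
  n <- 60
  x <- rnorm(n)
  y <- 3 + 700 * x + rnorm(n, sd = 50)
  res <- adjusted_regression(y, x, covariates = NULL)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$B, beta[2], tolerance = 1e-8)

  # adding covariates that have no effect leaves B essentially unchanged
  cov <- tibble::tibble(age = rnorm(n, 60, 10), sex = rbinom(n, 1, 0.5),
                        bmi = rnorm(n, 28, 3), smoker = rbinom(n, 1, 0.3),
                        diabetes = rbinom(n, 1, 0.2),
                        ischemic_time = rnorm(n, 150, 40))
  res2 <- adjusted_regression(y, x, covariates = cov)
  expect_equal(res2$B, res$B, tolerance = 0.1)
})

test_that("null lipid-troponin associations reject at the nominal rate", {
  set.seed(202)
  reps <- 400
  p <- replicate(reps, {
    n <- 40
    adjusted_regression(rnorm(n, 2000, 800), rnorm(n))$p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  # p-values roughly uniform
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("confounded lipid effects vanish after covariate adjustment", {
  set.seed(203)
  n <- 300
  age <- rnorm(n, 60, 10)
  lipid <- 0.05 * age + rnorm(n, sd = 0.3)       # driven by age only
  delta <- 60 * age + rnorm(n, sd = 300)         # outcome driven by age only
  cov <- tibble::tibble(age = age, sex = rbinom(n, 1, 0.5),
                        bmi = rnorm(n, 28, 3), smoker = rbinom(n, 1, 0.3),
                        diabetes = rbinom(n, 1, 0.2),
                        ischemic_time = rnorm(n, 150, 40))
  unadj <- adjusted_regression(delta, lipid, covariates = NULL)
  adj <- adjusted_regression(delta, lipid, covariates = cov)
  expect_true(unadj$significant)
  expect_gt(unadj$B, 100)
  expect_false(adj$significant)
  expect_lt(abs(adj$B), abs(unadj$B) / 3)
})

test_that("tertile split yields 27 vs 53 for 80 distinct values", {
  set.seed(204)
  res <- tertile_split(runif(80, 60, 8000))
  expect_equal(res$n_top, 27L)
  expect_equal(res$n_lower, 53L)
  expect_equal(res$flag, "ok")
  # exact thirds: 1..9 puts {7,8,9} on top
  res9 <- tertile_split(1:9)
  expect_equal(sum(res9$labels == "top"), 3L)
  expect_setequal(which(res9$labels == "top"), 7:9)
  # all-equal values collapse the split and are flagged
  expect_equal(tertile_split(rep(5, 12))$flag, "degenerate")
})

test_that("tertile sizes stay within 1 of n/3 for distinct values", {
  set.seed(205)
  for (n in c(9, 10, 20, 33, 50, 80, 81)) {
    res <- tertile_split(sample(seq_len(10 * n), n))
    expect_lte(abs(res$n_top - ceiling(n / 3)), 1)
  }
})

test_that("group fold changes are log2 mean ratios with a Student t-test", {
  expect_equal(group_fold_change(c(rep(100, 5), rep(100, 5)),
                                 rep(c("a", "b"), each = 5),
                                 group_a = "a")$log2_fc, 0)
  res <- group_fold_change(c(rep(200, 5), rep(100, 5)),
                           rep(c("a", "b"), each = 5), group_a = "a")
  expect_equal(res$log2_fc, 1)
  # groups below 3 observations yield no test
  small <- group_fold_change(c(1, 2, 100, 120, 130),
                             c("a", "a", "b", "b", "b"), group_a = "a")
  expect_true(is.na(small$p))
})

test_that("late-phase trajectories star baseline comparisons", {
  set.seed(206)
  n <- 20
  tps <- c("t0", "t1", "t2", "t3", "t4")
  # V-shaped marker with nadir at t3 (48 h); flat reference species
  mult <- c(1, 0.85, 0.75, 0.45, 0.9)
  base <- rlnorm(n, log(5), 0.2)
  conc <- purrr::map_dfr(seq_along(tps), function(i) {
    tibble::tibble(
      subject_id = sprintf("S%02d", 1:n), timepoint = tps[i],
      species = "acylcarnitine 18:2", lipid_class = "acylcarnitine",
      concentration = base * mult[i] * rlnorm(n, 0, 0.08))
  })
  flat <- dplyr::mutate(conc, species = "PC 34:1", lipid_class = "PC",
                        concentration = rlnorm(dplyr::n(), log(50), 0.1))
  res <- late_phase_trajectories(dplyr::bind_rows(conc, flat))
  vs <- res$vs_baseline
  marker_t3 <- vs[vs$species == "acylcarnitine 18:2" & vs$timepoint == "t3", ]
  expect_lt(marker_t3$p_corrected, 0.05)
  expect_lt(marker_t3$mean_log_change, 0)
  expect_true(marker_t3$stars != "")
  flat_rows <- vs[vs$species == "PC 34:1", ]
  expect_true(all(flat_rows$stars == ""))
  # m = 4 baseline comparisons per species
  expect_equal(sum(vs$species == "acylcarnitine 18:2"), 4L)

  # two subjects are insufficient
  tiny <- conc[conc$subject_id %in% c("S01", "S02"), ]
  res2 <- late_phase_trajectories(tiny)
  expect_equal(res2$anova$flag, "insufficient_n")
})

test_that("control comparison tests species and their class totals", {
  set.seed(207)
  mk <- function(ids, fold) {
    tidyr::expand_grid(subject_id = ids,
                       species = c("LPC 17:1", "LPC 18:0")) |>
      dplyr::mutate(sample_id = subject_id, sample_type = "study",
                    lipid_class = "LPC",
                    concentration = rlnorm(dplyr::n(), log(10), 0.25) * fold)
  }
  stemi <- mk(sprintf("S%02d", 1:80), 1.5)
  ctrl <- mk(sprintf("C%02d", 1:50), 1)
  res <- control_comparison(stemi, ctrl, "LPC 17:1")
  sp <- res[res$unit == "species", ]
  cl <- res[res$unit == "class_total", ]
  expect_gt(sp$log2_fc, 0)
  expect_true(sp$significant)
  expect_gt(cl$log2_fc, 0)
  expect_true(cl$significant)
  # empty species list is vacuous, not an error
  empty <- control_comparison(stemi, ctrl, character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("planted marker signs are recovered in at least 90% of seeds", {
  # latent-state surrogate of the downstream analyses: true concentrations
  # with measurement-level noise, regression + tertile fold-change signs
  # for the three planted markers, over 12 generator seeds
  panel <- default_panel()
  truth <- ground_truth(panel)
  design <- study_design()
  markers <- c("acylcarnitine 18:2" = 1, "TG 51:0" = -1, "LPC 17:1" = -1)
  ok <- vapply(1:12, function(seed) {
    co <- generate_cohort(design, truth, seed = seed)
    tl <- co$lipid_truth
    set.seed(seed + 999)
    tl$concentration <- tl$true_conc *
      rlnorm(nrow(tl), 0, sqrt(log(1 + 0.15^2)))
    st <- tl[grepl("^S", tl$subject_id) & tl$timepoint == "t1" &
               tl$species %in% names(markers), ]
    delta <- cohort_delta_troponin(co$troponin)
    split <- tertile_split(delta$delta_tnt)
    lab <- tibble::tibble(subject_id = delta$subject_id,
                          tertile = split$labels)
    all(vapply(names(markers), function(s) {
      d <- st[st$species == s, ]
      reg <- adjusted_regression(
        delta$delta_tnt[match(d$subject_id, delta$subject_id)],
        log(d$concentration),
        co$clinical[match(d$subject_id, co$clinical$subject_id), ])
      d2 <- dplyr::inner_join(d, lab, by = "subject_id")
      fc <- group_fold_change(d2$concentration, d2$tertile, group_a = "top")
      sign(reg$B) == markers[[s]] && sign(fc$log2_fc) == markers[[s]]
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
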