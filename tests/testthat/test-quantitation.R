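# independent oracle: build the observed-areas linear system from the M+2
# overlap structure and solve it directly (matrix solve, not the sequential
# recursion used by the implementation)
deisotope_oracle <- function(observed, panel) {
  sp <- panel$species
  n <- nrow(sp)
  P <- diag(n)
  for (i in seq_len(n)) {
    donor <- which(sp$lipid_class == sp$lipid_class[i] &
                     sp$total_carbons == sp$total_carbons[i] &
                     sp$total_double_bonds == sp$total_double_bonds[i] + 1L)
    if (length(donor) == 1L) {
      C <- lipidflux:::molecular_carbons(sp$lipid_class[donor],
                                         sp$total_carbons[donor])
      P[i, donor] <- lipidflux:::m2_fraction(C)
    }
  }
  as.numeric(solve(P, observed))
}

test_that("correction factors implement the five acyl-chain outcomes", {
  expect_equal(correction_factor(parse_lipid_name("DG 15:0_18:1")), 0.5)
  expect_equal(correction_factor(parse_lipid_name("DG 15:0_15:0")), 1.0)
  expect_equal(correction_factor(parse_lipid_name("TG 16:0_18:1_18:2")), 0.33)
  expect_equal(correction_factor(parse_lipid_name("TG 16:0_16:0_18:1")), 0.66)
  expect_equal(correction_factor(parse_lipid_name("TG 17:0_17:0_17:0")), 1.0)
  # non-DG/TG classes are never corrected
  expect_equal(correction_factor(parse_lipid_name("PC 34:1")), 1.0)
  expect_equal(correction_factor(parse_lipid_name("CE 18:2")), 1.0)
  # DG/TG at sum-composition level demand chain-resolved input
  expect_error(correction_factor(parse_lipid_name("TG 51:0")),
               "chain-resolved")
})

test_that("correction factor is a pure function of chain multiplicity", {
  set.seed(42)
  for (i in 1:50) {
    chains <- sprintf("%d:%d", sample(12:22, 3, replace = TRUE),
                      sample(0:3, 3, replace = TRUE))
    tg <- parse_lipid_name(paste("TG", paste(chains, collapse = "_")))
    cf <- correction_factor(tg)
    n_distinct <- length(unique(chains))
    expect_equal(cf, c(1, 0.66, 0.33)[n_distinct])
    dg <- parse_lipid_name(paste("DG", paste(chains[1:2], collapse = "_")))
    expect_equal(correction_factor(dg),
                 if (chains[1] == chains[2]) 1 else 0.5)
  }
})

test_that("CE response lines evaluate as printed and guard positivity", {
  expect_equal(ce_response_factor(20, 0), 0.13 * 20 - 0.71)
  expect_equal(ce_response_factor(16, 1), 1.13 * 16 - 0.23)
  expect_equal(ce_response_factor(20, 4), -0.07 * 20 + 1.54)
  expect_equal(ce_response_factor(18, 2), -0.07 * 18 + 1.54)
  # the polyunsaturated line crosses zero at x = 22
  expect_error(ce_response_factor(22, 5), "non-positive")
  expect_error(ce_response_factor(24, 6), "non-positive")
})

test_that("M+2 interference is subtracted recursively and clipped at zero", {
  panel <- lipidflux:::build_panel(
    tibble::tibble(species = c("PC 34:2", "PC 34:1", "PC 34:0"),
                   lipid_class = "PC"),
    tibble::tibble(lipid_class = "PC", istd_species = "PC 13:0_13:0",
                   istd_conc = 10, istd_units = "uM"))
  p2 <- lipidflux:::m2_fraction(42)  # PC backbone 8 + 34 acyl carbons
  tab <- tibble::tibble(
    sample_id = "s1", sample_type = "study", batch = 1L,
    injection_order = 1L,
    transition_id = paste(c("PC 34:2", "PC 34:1", "PC 34:0"), "quantifier",
                          sep = "|"),
    area = c(1000, 100, 50))
  out <- deisotope(tab, panel)
  a <- setNames(out$area, out$transition_id)
  corr_341 <- 100 - p2 * 1000
  expect_equal(unname(a["PC 34:1|quantifier"]), corr_341)
  expect_equal(unname(a["PC 34:2|quantifier"]), 1000)  # no higher-db donor
  expect_equal(unname(a["PC 34:0|quantifier"]), 50 - p2 * corr_341)

  # clipping: observed below the predicted interference
  tab$area <- c(1e6, 10, 50)
  out2 <- deisotope(tab, panel)
  expect_equal(out2$area[out2$transition_id == "PC 34:1|quantifier"], 0)
  expect_true(out2$deisotope_clipped[out2$transition_id == "PC 34:1|quantifier"])
})

test_that("species without a double-bond partner are unchanged", {
  panel <- small_panel()
  set.seed(1)
  sp <- panel$species
  lonely <- sp$species[!paste(sp$lipid_class, sp$total_carbons,
                              sp$total_double_bonds + 1L) %in%
                         paste(sp$lipid_class, sp$total_carbons,
                               sp$total_double_bonds)]
  tab <- tibble::tibble(
    sample_id = "s1", sample_type = "study", batch = 1L, injection_order = 1L,
    transition_id = paste(sp$species, "quantifier", sep = "|"),
    area = runif(nrow(sp), 100, 1000))
  out <- deisotope(tab, panel)
  keep <- out$transition_id %in% paste(lonely, "quantifier", sep = "|")
  expect_equal(out$area[keep],
               tab$area[tab$transition_id %in%
                          paste(lonely, "quantifier", sep = "|")])
})

test_that("deisotoping matches the matrix-solve oracle on a small panel", {
  panel <- lipidflux:::build_panel(
    tibble::tibble(
      species = c("PC 34:3", "PC 34:2", "PC 34:1", "PC 34:0",
                  "TG 52:3", "TG 52:2", "SM 36:1"),
      lipid_class = c("PC", "PC", "PC", "PC", "TG", "TG", "SM")),
    tibble::tibble(lipid_class = c("PC", "TG", "SM"),
                   istd_species = c("PC 13:0_13:0", "TG 17:0_17:0_17:0",
                                    "SM 12:0"),
                   istd_conc = 10, istd_units = "uM"))
  set.seed(9)
  clean <- runif(7, 100, 5000)
  # build observed areas by forward convolution of the overlap structure
  sp <- panel$species
  observed <- clean
  for (i in seq_len(nrow(sp))) {
    donor <- which(sp$lipid_class == sp$lipid_class[i] &
                     sp$total_carbons == sp$total_carbons[i] &
                     sp$total_double_bonds == sp$total_double_bonds[i] + 1L)
    if (length(donor) == 1L) {
      C <- lipidflux:::molecular_carbons(sp$lipid_class[donor],
                                         sp$total_carbons[donor])
      observed[i] <- observed[i] + lipidflux:::m2_fraction(C) * clean[donor]
    }
  }
  tab <- tibble::tibble(
    sample_id = "s1", sample_type = "study", batch = 1L, injection_order = 1L,
    transition_id = paste(sp$species, "quantifier", sep = "|"),
    area = observed)
  out <- deisotope(tab, panel)
  oracle <- deisotope_oracle(observed, panel)
  expect_equal(out$area, oracle, tolerance = 1e-6)
  expect_equal(out$area, clean, tolerance = 1e-6)
})

test_that("quantitation is an ISTD ratio with CF/RF divisors", {
  panel <- lipidflux:::build_panel(
    tibble::tibble(species = c("PC 34:1", "TG 50:1"),
                   lipid_class = c("PC", "TG")),
    tibble::tibble(lipid_class = c("PC", "TG"),
                   istd_species = c("PC 13:0_13:0", "TG 17:0_17:0_17:0"),
                   istd_conc = c(10, 10), istd_units = "uM"))
  tab <- tibble::tibble(
    sample_id = "s1", sample_type = "study", batch = 1L, injection_order = 1L,
    transition_id = paste(c("PC 34:1", "TG 50:1", "PC 13:0_13:0",
                            "TG 17:0_17:0_17:0"), "quantifier", sep = "|"),
    area = c(2000, 2000, 1000, 1000))
  conc <- quantify(tab, panel)
  expect_equal(conc$concentration[conc$species == "PC 34:1"], 20)
  # sum-composition TG defaults to CF = 1; an override divides
  conc2 <- quantify(tab, panel, cf_overrides = c("TG 50:1" = 0.33))
  expect_equal(conc2$concentration[conc2$species == "TG 50:1"], 20 / 0.33)
})

test_that("missing or zero ISTD areas flag the sample instead of dropping it", {
  panel <- lipidflux:::build_panel(
    tibble::tibble(species = "PC 34:1", lipid_class = "PC"),
    tibble::tibble(lipid_class = "PC", istd_species = "PC 13:0_13:0",
                   istd_conc = 10, istd_units = "uM"))
  tab <- tibble::tibble(
    sample_id = c("s1", "s2"), sample_type = "study", batch = 1L,
    injection_order = 1:2,
    transition_id = "PC 34:1|quantifier", area = c(500, 600))
  istd_row <- tibble::tibble(
    sample_id = "s1", sample_type = "study", batch = 1L, injection_order = 1L,
    transition_id = "PC 13:0_13:0|quantifier", area = 1000)
  conc <- quantify(dplyr::bind_rows(tab, istd_row), panel)
  expect_equal(conc$concentration[conc$sample_id == "s1"], 5)
  expect_true(is.na(conc$concentration[conc$sample_id == "s2"]))
  expect_match(conc$flags[conc$sample_id == "s2"], "istd_missing")
})

test_that("quantitation is invariant to a per-sample scale factor", {
  s <- small_study(seed = 21, n_stemi = 6, n_control = 3, n_late = 2,
                   drift_amplitude = 0, noise_cv = 0)
  conc1 <- quantify(s$acq, s$panel)
  scaled <- s$acq
  k <- setNames(runif(length(unique(scaled$sample_id)), 0.5, 2),
                unique(scaled$sample_id))
  scaled$area <- scaled$area * k[scaled$sample_id]
  conc2 <- quantify(scaled, s$panel)
  expect_equal(conc1$concentration, unname(conc2$concentration),
               tolerance = 1e-12)
})

test_that("fatty-acid qualifier ratios flag interfered measurements", {
  expect_equal(fa_qualifier_check(1000, 400, reference_ratio = 0.4), "pass")
  expect_equal(fa_qualifier_check(1000, 0, reference_ratio = 0.4), "flag")
  # interferent inflating only the quantifier by 3x drops the ratio to 1/3
  # of the reference, beyond the default 50% tolerance
  expect_equal(fa_qualifier_check(3000, 400, reference_ratio = 0.4), "flag")
  expect_equal(fa_qualifier_check(c(1000, 3000), c(400, 400), 0.4),
               c("pass", "flag"))
})
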