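# MRM panel data model: species list, transitions, internal-standard map.
# The packaged default panel reconstructs class membership (25 classes,
# 322 species) representative of a targeted plasma lipidomics screen;
# m/z values are approximate panel-config data and take no part in any
# computation downstream of panel validation.

ALLOWED_CHAINS <- function(lipid_class) {
  switch(lipid_class,
    "TG" = 3L,
    "DG" = , "PC" = , "PE" = , "PS" = , "PG" = , "PI" = , "OxPL" = 2L,
    1L)
}

# species shorthand lists per class; counts sum to 322
default_species_by_class <- function() {
  cd <- function(cls, spec) sprintf("%s %s", cls, spec)
  list(
    # polyunsaturated CE species with chains of >= 22 carbons are excluded:
    # the fitted response line is non-positive there and such species
    # cannot be quantified under this response model
    "CE" = cd("CE", c("14:0","15:0","16:0","16:1","17:0","18:0","18:1","18:2",
                      "18:3","19:2","20:0","20:2","20:3","20:4","20:5","22:0",
                      "22:1","24:0","24:1","26:0")),
    "PC" = cd("PC", c("30:0","31:0","32:0","32:1","32:2","33:1","34:0","34:1",
                      "34:2","34:3","34:4","35:2","36:1","36:2","36:3","36:4",
                      "36:5","36:6","37:4","38:2","38:4","38:5","38:6","39:6",
                      "40:4","40:6","40:7","40:8","42:6","44:12")),
    "PC(O)" = sprintf("PC(O-%s)", c("32:0","32:1","33:1","34:1","34:2","34:3",
                      "35:4","36:2","36:3","36:4","36:5","38:4","38:5","40:5",
                      "40:6","42:5","44:4","44:5")),
    "PC(P)" = sprintf("PC(P-%s)", c("32:0","34:1","34:2","36:2","36:4","38:4",
                      "38:5","38:6","40:5","40:6","42:6","44:6")),
    "LPC" = cd("LPC", c("14:0","15:0","16:0","16:1","17:0","17:1","18:0",
                      "18:1","18:2","18:3","20:3","20:4","20:5","22:5","22:6",
                      "24:0")),
    "LPC(O)" = sprintf("LPC(O-%s)", c("16:0","17:0","18:0","18:1","20:0","22:1")),
    "PE" = cd("PE", c("32:1","34:1","34:2","34:3","36:1","36:2","36:3","36:4",
                      "36:5","38:3","38:4","38:5","38:6","40:4","40:5","40:6",
                      "40:7","42:5","42:6","42:7")),
    "PE(O)" = sprintf("PE(O-%s)", c("34:1","34:2","36:2","36:3","36:4","36:5",
                      "38:4","38:5","40:4","40:5","40:6","40:7")),
    "PE(P)" = sprintf("PE(P-%s)", c("34:1","36:2","36:4","38:4","38:5","38:6",
                      "40:5","40:6")),
    "LPE" = cd("LPE", c("16:0","18:0","18:1","18:2","20:4","20:5","22:5","22:6")),
    "PI" = cd("PI", c("32:0","32:1","34:0","34:1","34:2","36:1","36:2","36:3",
                      "36:4","38:3","38:4","38:5","38:6","40:5","40:6")),
    "PS" = cd("PS", c("36:1","36:2","38:3","38:4","40:5","40:6","42:6","44:6")),
    "PG" = cd("PG", c("32:0","34:1","34:2","36:1","36:2","36:4","38:4","38:6")),
    "SM" = cd("SM", c("31:1","32:1","32:2","33:1","34:1","34:2","35:1","36:1",
                      "36:2","37:1","37:2","38:1","38:2","39:1","40:1","40:2",
                      "41:1","41:2","42:1","42:2")),
    "Cer" = cd("Cer", c("32:1","34:0","34:1","36:1","38:1","40:1","40:2",
                      "41:1","42:1","42:2","43:1","44:1")),
    "dhCer" = cd("dhCer", c("34:0","36:0","38:0","40:0","41:0","42:0","43:0","44:0")),
    "HexCer" = cd("HexCer", c("34:1","36:1","38:1","40:1","41:1","42:1","42:2",
                      "43:1","44:1","44:2")),
    "Hex2Cer" = cd("Hex2Cer", c("34:1","36:1","38:1","40:1","42:1","42:2")),
    "Hex3Cer" = cd("Hex3Cer", c("34:1","36:1","38:1","40:1","42:1")),
    "GM3" = cd("GM3", c("34:1","36:1","38:1","40:1","41:1","42:1")),
    "DG" = cd("DG", c("30:0","32:0","32:1","34:0","34:1","34:2","36:1","36:2",
                      "36:3","36:4","38:4","38:5","38:6","40:6","40:7")),
    "TG" = cd("TG", c("44:0","46:0","46:1","48:0","48:1","48:2","50:0","50:1",
                      "50:2","50:3","51:0","51:1","52:1","52:2","52:3","52:4",
                      "53:2","54:1","54:2","54:3","54:4","54:5","54:6","55:2",
                      "56:2","56:4","56:6","56:7","58:8","58:10")),
    "FA" = cd("FA", c("14:0","16:0","16:1","18:0","18:1","18:2","18:3","20:3",
                      "20:4","20:5","22:4","22:5","22:6","24:0","24:1")),
    "acylcarnitine" = cd("acylcarnitine", c("12:0","14:0","16:0","16:1","18:0",
                      "18:1","18:2","20:0")),
    "OxPL" = c("POVPC","PONPC","PGPC","PAzPC","KOdiAPC","KDdiAPC")
  )
}

default_istd_map <- function() {
  tibble::tribble(
    ~lipid_class,    ~istd_species,          ~istd_conc, ~istd_units,
    "CE",            "CE 23:0",              100, "uM",
    "PC",            "PC 13:0_13:0",          10, "uM",
    "PC(O)",         "PC 13:0_13:0",          10, "uM",
    "PC(P)",         "PC 13:0_13:0",          10, "uM",
    "LPC",           "LPC 13:0",              10, "uM",
    "LPC(O)",        "LPC 13:0",              10, "uM",
    "PE",            "PE 17:0_17:0",          10, "uM",
    "PE(O)",         "PE 17:0_17:0",          10, "uM",
    "PE(P)",         "PE 17:0_17:0",          10, "uM",
    "LPE",           "LPE 14:0",              10, "uM",
    "PI",            "PG 17:0_17:0",          10, "uM",
    "PS",            "PS 17:0_17:0",          10, "uM",
    "PG",            "PG 17:0_17:0",          10, "uM",
    "SM",            "SM 12:0",               10, "uM",
    "Cer",           "Cer 17:0",               5, "uM",
    "dhCer",         "dhCer 8:0",              5, "uM",
    "HexCer",        "HexCer 16:0",            5, "uM",
    "Hex2Cer",       "Hex2Cer 16:0",           5, "uM",
    "Hex3Cer",       "Hex3Cer 17:0",           5, "uM",
    "GM3",           "Hex3Cer 17:0",           5, "uM",
    "DG",            "DG 15:0_15:0",          10, "uM",
    "TG",            "TG 17:0_17:0_17:0",     10, "uM",
    "FA",            "FA 15:0",               50, "uM",
    "acylcarnitine", "acylcarnitine 3:0",      1, "uM",
    "OxPL",          "PC 9:0_9:0",             5, "uM"
  )
}

# Approximate precursor/product m/z from class base mass + CH2/double-bond
# increments; panel-config stand-ins, never used in quantitation.
CLASS_BASE_MZ <- c(
  "CE" = 386.4, "PC" = 258.1, "PC(O)" = 244.2, "PC(P)" = 242.2,
  "LPC" = 241.1, "LPC(O)" = 227.2, "PE" = 216.1, "PE(O)" = 202.1,
  "PE(P)" = 200.1, "LPE" = 199.1, "PI" = 337.1, "PS" = 260.1, "PG" = 247.1,
  "SM" = 465.3, "Cer" = 282.3, "dhCer" = 284.3, "HexCer" = 444.3,
  "Hex2Cer" = 606.4, "Hex3Cer" = 768.4, "GM3" = 897.5, "DG" = 110.1,
  "TG" = 92.1, "FA" = 1.0, "acylcarnitine" = 162.1, "OxPL" = 258.1
)

approx_mz <- function(lipid_class, carbons, double_bonds) {
  round(CLASS_BASE_MZ[lipid_class] + 14.0157 * carbons - 2.0157 * double_bonds, 1)
}

approx_product_mz <- function(lipid_class, precursor) {
  pc_like <- lipid_class %in% c("PC", "PC(O)", "PC(P)", "LPC", "LPC(O)",
                                "SM", "OxPL")
  ifelse(pc_like, 184.3,
    ifelse(lipid_class == "FA", precursor,
      ifelse(lipid_class %in% c("PE", "PE(O)", "PE(P)", "LPE"),
             round(precursor - 141.0, 1), round(precursor - 17.0, 1))))
}

#' Packaged default MRM panel
#'
#' A representative targeted plasma lipidomics panel: 322 lipid species
#' across 25 classes/subclasses, each class with an assigned internal
#' standard (odd-chain or short-chain species not present endogenously).
#' Fatty acids carry a quantifier and a qualifier transition (same masses,
#' different collision energy); all other species carry one quantifier.
#'
#' @return A `lipid_panel` object: list with `transitions`, `species`,
#'   `istd_map`, and `class_count`.
#' @examples
#' p <- default_panel()
#' p$class_count
#' nrow(p$species)
#' @export
default_panel <- function() {
  by_class <- default_species_by_class()
  rows <- purrr::imap_dfr(by_class, function(names, cls) {
    tibble::tibble(species = names, lipid_class = cls)
  })
  build_panel(rows, default_istd_map())
}

build_panel <- function(species_rows, istd_map) {
  parsed <- purrr::map(species_rows$species, parse_lipid_name)
  species <- tibble::tibble(
    species = purrr::map_chr(parsed, canonical_lipid_name),
    lipid_class = purrr::map_chr(parsed, "lipid_class"),
    total_carbons = purrr::map_int(parsed, "total_carbons"),
    total_double_bonds = purrr::map_int(parsed, "total_double_bonds"),
    oxidized = purrr::map_lgl(parsed, "oxidized_flag")
  )
  if (!all(species$lipid_class == species_rows$lipid_class)) {
    abort("panel species parsed into a different class than declared")
  }
  if (anyDuplicated(species$species)) {
    abort(sprintf("duplicate panel species: %s",
                  paste(unique(species$species[duplicated(species$species)]),
                        collapse = ", ")))
  }
  missing_istd <- setdiff(unique(species$lipid_class), istd_map$lipid_class)
  if (length(missing_istd) > 0L) {
    abort(sprintf("no internal standard assigned for class(es): %s",
                  paste(missing_istd, collapse = ", ")))
  }

  istd_parsed <- purrr::map(unique(istd_map$istd_species), parse_lipid_name)
  istd_species <- tibble::tibble(
    species = purrr::map_chr(istd_parsed, canonical_lipid_name),
    lipid_class = purrr::map_chr(istd_parsed, "lipid_class"),
    total_carbons = purrr::map_int(istd_parsed, "total_carbons"),
    total_double_bonds = purrr::map_int(istd_parsed, "total_double_bonds"),
    oxidized = FALSE
  )

  make_transitions <- function(sp, is_istd) {
    pre <- approx_mz(sp$lipid_class, sp$total_carbons, sp$total_double_bonds)
    base <- tibble::tibble(
      species = sp$species, lipid_class = sp$lipid_class,
      precursor_mz = unname(pre),
      product_mz = unname(approx_product_mz(sp$lipid_class, pre)),
      polarity = ifelse(sp$lipid_class == "FA", "negative", "positive"),
      role = "quantifier", is_istd = is_istd
    )
    qual <- base[base$lipid_class == "FA", ]
    if (nrow(qual) > 0L) qual$role <- "qualifier"
    dplyr::bind_rows(base, qual)
  }
  transitions <- dplyr::bind_rows(
    make_transitions(species, FALSE),
    make_transitions(istd_species, TRUE)
  )
  transitions$transition_id <- paste(transitions$species, transitions$role,
                                     sep = "|")
  if (anyDuplicated(transitions$transition_id)) {
    abort("duplicate (species, role) transition rows in panel")
  }

  structure(list(
    transitions = transitions,
    species = species,
    istd_map = istd_map,
    class_count = length(unique(species$lipid_class))
  ), class = "lipid_panel")
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat(sprintf("<lipid_panel> %d species, %d classes, %d transitions (+%d ISTD)\n",
              nrow(x$species), x$class_count,
              sum(!x$transitions$is_istd), sum(x$transitions$is_istd)))
  invisible(x)
}

#' Load an MRM panel from CSV
#'
#' Expected columns: `species, lipid_class, precursor_mz, product_mz,
#' polarity, role, istd_species, istd_conc, istd_units`. Internal-standard
#' rows are recognized by `species` matching the class `istd_species`.
#'
#' @param path Path to the panel CSV.
#' @return A `lipid_panel`.
#' @export
load_panel <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c("species", "lipid_class", "precursor_mz", "product_mz",
                       "polarity", "role", "istd_species", "istd_conc",
                       "istd_units"), "panel CSV")
  if (anyDuplicated(df[c("species", "role")])) {
    dup <- df$species[duplicated(df[c("species", "role")])]
    abort(sprintf("duplicate (species, role) rows in panel CSV: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  istd_map <- dplyr::distinct(
    df[!is.na(df$istd_species) & nzchar(df$istd_species),
       c("lipid_class", "istd_species", "istd_conc", "istd_units")])
  if (anyDuplicated(istd_map$lipid_class)) {
    abort("conflicting internal-standard assignments within a class")
  }
  analyte <- df[df$role == "quantifier" &
                  !(df$species %in% istd_map$istd_species), ]
  no_istd <- setdiff(unique(analyte$lipid_class), istd_map$lipid_class)
  if (length(no_istd) > 0L) {
    abort(sprintf("no internal standard assigned for class(es): %s",
                  paste(no_istd, collapse = ", ")))
  }
  build_panel(analyte[c("species", "lipid_class")], istd_map)
}

#' Write a panel to CSV (round-trips with [load_panel()])
#'
#' @param panel A `lipid_panel`.
#' @param path Output CSV path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "lipid_panel"))
  tr <- panel$transitions
  out <- dplyr::left_join(tr, panel$istd_map, by = "lipid_class")
  out <- out[c("species", "lipid_class", "precursor_mz", "product_mz",
               "polarity", "role", "istd_species", "istd_conc", "istd_units")]
  readr::write_csv(out, path)
  invisible(path)
}
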