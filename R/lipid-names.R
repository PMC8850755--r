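#' Lipid classes covered by the panel
#'
#' The 25 lipid classes/subclasses handled by the pipeline, in panel order.
#' Ether (O-) and plasmalogen (P-) subclasses are distinct classes for
#' quantitation because each carries its own internal-standard assignment.
#'
#' @export
LIPID_CLASSES <- c(
  "CE", "PC", "PC(O)", "PC(P)", "LPC", "LPC(O)",
  "PE", "PE(O)", "PE(P)", "LPE", "PI", "PS", "PG",
  "SM", "Cer", "dhCer", "HexCer", "Hex2Cer", "Hex3Cer", "GM3",
  "DG", "TG", "FA", "acylcarnitine", "OxPL"
)

# Named oxidized-phospholipid standards. Sum composition is the two acyl
# chains (palmitoyl + the oxidatively truncated chain); all are
# phosphocholine-containing and detected via the m/z 184.3 product ion.
OXPL_ALIASES <- tibble::tribble(
  ~alias,    ~carbons, ~double_bonds, ~full_name,
  "POVPC",   21L, 0L, "1-palmitoyl-2-(5-oxovaleroyl)-sn-glycero-3-phosphocholine",
  "PONPC",   25L, 0L, "1-palmitoyl-2-(9-oxo)nonanoyl-sn-glycero-3-phosphocholine",
  "PGPC",    21L, 0L, "1-palmitoyl-2-glutaroyl-sn-glycero-3-phosphocholine",
  "PAzPC",   25L, 0L, "1-palmitoyl-2-azelaoyl-sn-glycero-3-phosphocholine",
  "KOdiAPC", 24L, 1L, "1-palmitoyl-2-(5-keto-6-octene-dioyl)-sn-glycero-3-phosphocholine",
  "KDdiAPC", 28L, 1L, "1-palmitoyl-2-(4-keto-dodec-3-ene-dioyl)-sn-glycero-3-phosphocholine"
)

# Carbons contributed by the non-acyl part of the molecule, per class.
# Added to the shorthand's total acyl carbon count to estimate the full
# molecular carbon number used for isotope-abundance calculations.
# Glycerophospholipids: glycerol (3) + headgroup; sphingolipids: the
# shorthand already counts the sphingoid base, so only the headgroup/sugars
# are added; CE adds the cholesterol skeleton; acylcarnitine adds carnitine.
BACKBONE_CARBONS <- c(
  "CE" = 27, "PC" = 8, "PC(O)" = 8, "PC(P)" = 8, "LPC" = 8, "LPC(O)" = 8,
  "PE" = 5, "PE(O)" = 5, "PE(P)" = 5, "LPE" = 5, "PI" = 9, "PS" = 6,
  "PG" = 6, "SM" = 5, "Cer" = 0, "dhCer" = 0, "HexCer" = 6, "Hex2Cer" = 12,
  "Hex3Cer" = 18, "GM3" = 23, "DG" = 3, "TG" = 3, "FA" = 0,
  "acylcarnitine" = 7, "OxPL" = 8
)

#' Parse a lipid shorthand name
#'
#' Accepts sum-composition shorthand (`"TG 51:0"`), ether/plasmalogen
#' subclass notation (`"PC(O-36:3)"`, `"PE(P-38:4)"`), chain-resolved names
#' (`"TG 17:0_17:0_17:0"`, `"DG 15:0_18:1"`), reversed acylcarnitine style
#' (`"18:2 acylcarnitine"`), and the named oxidized-phospholipid standards
#' (POVPC, PONPC, PGPC, PAzPC, KOdiAPC, KDdiAPC). Class tokens are matched
#' case-insensitively; the canonical casing is restored on output.
#'
#' @param name A single lipid shorthand string.
#' @return A list of class `lipid_species` with fields `name` (canonical),
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `ether_flag`,
#'   `plasmalogen_flag`, `oxidized_flag`, and `acyl_chains` (a two-column
#'   matrix of per-chain carbons/double bonds, or `NULL` when the name is at
#'   sum-composition level).
#' @examples
#' parse_lipid_name("TG 51:0")
#' parse_lipid_name("PC(O-36:3)")
#' parse_lipid_name("PGPC")
#' @export
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    abort("`name` must be a single non-empty string")
  }
  raw <- trimws(name)

  # named OxPL standards
  hit <- which(tolower(OXPL_ALIASES$alias) == tolower(raw))
  if (length(hit) == 1L) {
    return(new_lipid_species(
      name = OXPL_ALIASES$alias[hit], lipid_class = "OxPL",
      total_carbons = OXPL_ALIASES$carbons[hit],
      total_double_bonds = OXPL_ALIASES$double_bonds[hit],
      oxidized_flag = TRUE
    ))
  }

  # reversed acylcarnitine style: "18:2 acylcarnitine" / "16:0 AC"
  m <- regmatches(raw, regexec(
    "^([0-9]+):([0-9]+)\\s+(acylcarnitine|ac)$", raw, ignore.case = TRUE))[[1]]
  if (length(m) == 4L) {
    return(new_lipid_species(
      name = sprintf("acylcarnitine %s:%s", m[2], m[3]),
      lipid_class = "acylcarnitine",
      total_carbons = as.integer(m[2]), total_double_bonds = as.integer(m[3])
    ))
  }

  # ether/plasmalogen notation: CLASS(O-C:D) or CLASS(P-C:D)
  m <- regmatches(raw, regexec(
    "^([A-Za-z]+[0-9]*)\\(([OPop])-([0-9]+):([0-9]+)\\)$", raw))[[1]]
  if (length(m) == 5L) {
    base <- match_class_token(m[2], raw)
    sub <- sprintf("%s(%s)", base, toupper(m[3]))
    if (!sub %in% LIPID_CLASSES) {
      abort(sprintf("no %s- subclass is defined for class '%s' (in '%s')",
                    m[3], base, raw))
    }
    return(new_lipid_species(
      name = sprintf("%s(%s-%s:%s)", base, toupper(m[3]), m[4], m[5]),
      lipid_class = sub,
      total_carbons = as.integer(m[4]), total_double_bonds = as.integer(m[5]),
      ether_flag = toupper(m[3]) == "O",
      plasmalogen_flag = toupper(m[3]) == "P"
    ))
  }

  # CLASS C:D or chain-resolved CLASS C1:D1_C2:D2[_C3:D3]
  m <- regmatches(raw, regexec(
    "^([A-Za-z][A-Za-z0-9()]*?)\\s+([0-9]+:[0-9]+(?:_[0-9]+:[0-9]+)*)$", raw))[[1]]
  if (length(m) == 3L) {
    cls <- match_class_token(m[2], raw)
    chains <- do.call(rbind, lapply(strsplit(m[3], "_", fixed = TRUE)[[1]],
      function(ch) as.integer(strsplit(ch, ":", fixed = TRUE)[[1]])))
    colnames(chains) <- c("carbons", "double_bonds")
    n_chain <- nrow(chains)
    expected <- ALLOWED_CHAINS(cls)
    if (n_chain > 1L) {
      if (n_chain != expected) {
        abort(sprintf(
          "'%s': %s species take %d acyl chains, got %d", raw, cls, expected, n_chain))
      }
      return(new_lipid_species(
        name = sprintf("%s %s", cls,
                       paste(sprintf("%d:%d", chains[, 1], chains[, 2]), collapse = "_")),
        lipid_class = cls,
        total_carbons = sum(chains[, 1]), total_double_bonds = sum(chains[, 2]),
        acyl_chains = chains
      ))
    }
    return(new_lipid_species(
      name = sprintf("%s %d:%d", cls, chains[1, 1], chains[1, 2]),
      lipid_class = cls,
      total_carbons = chains[1, 1], total_double_bonds = chains[1, 2],
      oxidized_flag = cls == "OxPL"
    ))
  }

  abort(sprintf("cannot parse lipid name '%s': unrecognized token structure", raw))
}

match_class_token <- function(token, raw) {
  i <- which(tolower(LIPID_CLASSES) == tolower(token))
  if (length(i) != 1L) {
    abort(sprintf("cannot parse lipid name '%s': unknown class token '%s'",
                  raw, token))
  }
  LIPID_CLASSES[i]
}

new_lipid_species <- function(name, lipid_class, total_carbons,
                              total_double_bonds, ether_flag = FALSE,
                              plasmalogen_flag = FALSE, oxidized_flag = FALSE,
                              acyl_chains = NULL) {
  if (!is.null(acyl_chains)) {
    stopifnot(sum(acyl_chains[, 1]) == total_carbons,
              sum(acyl_chains[, 2]) == total_double_bonds)
  }
  structure(list(
    name = name, lipid_class = lipid_class,
    total_carbons = as.integer(total_carbons),
    total_double_bonds = as.integer(total_double_bonds),
    ether_flag = ether_flag, plasmalogen_flag = plasmalogen_flag,
    oxidized_flag = oxidized_flag, acyl_chains = acyl_chains
  ), class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  [class %s, C%d:%d%s]\n",
              x$name, x$lipid_class, x$total_carbons, x$total_double_bonds,
              if (x$oxidized_flag) ", oxidized" else ""))
  invisible(x)
}

#' Canonical shorthand string for a parsed lipid
#'
#' Round-trips with [parse_lipid_name()]: parsing a canonical string and
#' re-canonicalizing is the identity.
#'
#' @param species A `lipid_species` object.
#' @return A single string.
#' @export
canonical_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  species$name
}

# Full molecular carbon count used for isotope-abundance computations:
# acyl carbons from the shorthand plus the class backbone contribution.
molecular_carbons <- function(lipid_class, total_carbons) {
  unname(BACKBONE_CARBONS[lipid_class] + total_carbons)
}
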