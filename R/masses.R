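#' @keywords internal
#' Monoisotopic atomic masses (Da) of the elements handled by the formula
#' parser. Values follow the IUPAC/CODATA recommendations at sub-ppm accuracy.
ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  Se = 79.9165213
)

#' Mass of the electron in Da (CODATA).
#' @keywords internal
ELECTRON_MASS <- 0.00054857990946

#' Mass of the proton (H minus one electron) in Da.
#' @keywords internal
PROTON_MASS <- 1.00727646688

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style formulas such as `"C8H11N5O3"` or `"C6H8O6"`. Element
#' symbols must start with an upper-case letter; counts default to 1. A
#' leading `"+"` or `"-"` sign is stripped (signs are handled by the caller
#' for biotransformation rules).
#'
#' @param formula Character scalar molecular formula.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C8H11N5O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- sub("^[+-]", "", trimws(formula))
  if (!nzchar(f)) stop("empty formula")
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  tokens <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(nchar(tokens)) != nchar(f)) {
    stop("unparseable formula: '", formula, "'")
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(ELEMENT_MASSES)) {
      stop("unknown element '", sym, "' in formula '", formula, "'")
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Monoisotopic neutral mass of a molecular formula
#'
#' @param formula Character formula (see [parse_formula()]) or a named
#'   integer vector of element counts.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C8H11N5O3")  # acyclovir
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (any(counts < 0)) stop("negative element count")
  sum(ELEMENT_MASSES[names(counts)] * counts)
}

#' Table of common ion forms (adducts and isotopologues)
#'
#' Mass deltas are applied to the neutral monoisotopic mass before dividing by
#' the absolute charge; electron masses are accounted for, so `[M+H]+` adds
#' the proton mass (1.007276 Da), not the mass of a hydrogen atom.
#'
#' @return A data.frame with columns `adduct`, `mass_delta` (Da, applied to M
#'   before division by charge), `charge`, `polarity`.
#' @export
adduct_table <- function() {
  H <- ELEMENT_MASSES[["H"]]; Na <- ELEMENT_MASSES[["Na"]]
  K <- ELEMENT_MASSES[["K"]]; Cl <- ELEMENT_MASSES[["Cl"]]
  N <- ELEMENT_MASSES[["N"]]; C <- ELEMENT_MASSES[["C"]]
  O <- ELEMENT_MASSES[["O"]]
  e <- ELECTRON_MASS
  data.frame(
    adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M+2H]2+",
               "[M-H]-", "[M+Cl]-", "[M+HCOO]-", "[M-2H]2-"),
    mass_delta = c(H - e, Na - e, K - e, N + 4 * H - e, 2 * (H - e),
                   -(H - e), Cl + e, H + C + 2 * O + e, -2 * (H - e)),
    charge = c(1L, 1L, 1L, 1L, 2L, -1L, -1L, -1L, -2L),
    polarity = c(rep("positive", 5L), rep("negative", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Mass difference of the 13C-12C isotopologue spacing (Da)
#' @keywords internal
C13_SPACING <- 1.0033548378

#' Expected m/z of an ion form of a neutral molecule
#'
#' @param neutral_mass Monoisotopic neutral mass in Da.
#' @param adduct Adduct label present in [adduct_table()] (e.g. `"[M+H]+"`).
#' @return Expected m/z.
#' @examples
#' expected_ion_mz(300, "[M+H]+")   # 301.007276
#' expected_ion_mz(300, "[M+2H]2+") # 151.007276
#' @export
expected_ion_mz <- function(neutral_mass, adduct) {
  tab <- adduct_table()
  i <- match(adduct, tab$adduct)
  if (is.na(i)) stop("unknown adduct '", adduct, "'")
  (neutral_mass + tab$mass_delta[i]) / abs(tab$charge[i])
}

#' Implied neutral mass from an observed m/z under an adduct hypothesis
#' @param mz Observed m/z.
#' @param adduct Adduct label in [adduct_table()].
#' @return Implied neutral monoisotopic mass (Da).
#' @export
implied_neutral_mass <- function(mz, adduct) {
  tab <- adduct_table()
  i <- match(adduct, tab$adduct)
  if (is.na(i)) stop("unknown adduct '", adduct, "'")
  mz * abs(tab$charge[i]) - tab$mass_delta[i]
}

#' Signed ppm mass error of an observed mass against a theoretical mass
#'
#' The reference is the theoretical mass: `(observed - theoretical) /
#' theoretical * 1e6`.
#'
#' @param observed,theoretical Masses in Da.
#' @return Signed error in ppm.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

#' Test whether two masses match within a ppm tolerance
#' @param observed,theoretical Masses in Da.
#' @param ppm Tolerance in ppm (half-width of the window).
#' @return Logical.
#' @export
ppm_match <- function(observed, theoretical, ppm) {
  abs(ppm_error(observed, theoretical)) <= ppm
}
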