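## Physical constants used throughout. Lengths are nanometers internally;
## photon energies cross the interface in keV.

#' Classical electron radius in nanometers
#'
#' @return The classical electron radius \eqn{r_0 = 2.8179403 \times 10^{-6}}
#'   nm, the coupling constant between electron density and the refractive
#'   index decrement.
#' @export
#' @examples
#' classicalElectronRadius()
classicalElectronRadius <- function() 2.8179403e-6

## hc in eV nm, so that lambda[nm] = 1239.842 / E[eV]
.hc_eV_nm <- 1239.842

#' Convert photon energy to wavelength
#'
#' Uses \eqn{\lambda~[\mathrm{nm}] = 1239.842 / E~[\mathrm{eV}]}.
#'
#' @param energy_keV photon energy in keV (vectorized).
#' @return wavelength in nm.
#' @seealso [wavelengthToEnergy()]
#' @export
#' @examples
#' energyToWavelength(7.5)   # 0.1653 nm
energyToWavelength <- function(energy_keV) {
  stopifnot(is.numeric(energy_keV), all(energy_keV > 0))
  .hc_eV_nm / (energy_keV * 1000)
}

#' Convert wavelength to photon energy
#'
#' @param wavelength_nm wavelength in nm (vectorized).
#' @return photon energy in keV.
#' @export
wavelengthToEnergy <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm), all(wavelength_nm > 0))
  .hc_eV_nm / wavelength_nm / 1000
}

## Standard atomic weights (IUPAC 2021 abridged) and atomic numbers for the
## elements that occur in soft-tissue / embedding-medium stoichiometries.
.elementTable <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
             "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Se", "Br", "I"),
  Z = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
        11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
        25L, 26L, 27L, 28L, 29L, 30L, 34L, 35L, 53L),
  mass = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
           18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
           35.45, 39.948, 39.098, 40.078, 54.938, 55.845, 58.933, 58.693,
           63.546, 65.38, 78.971, 79.904, 126.90),
  stringsAsFactors = FALSE
)

.avogadro <- 6.02214076e23

#' Parse a molecular formula string
#'
#' Accepts compact Hill-style formulas such as \code{"C30H62"} or
#' \code{"C2932H4724N828O840S8Fe4"}.
#'
#' @param formula a formula string, or an already-named numeric vector of
#'   element counts (returned unchanged after validation).
#' @return named integer vector of element counts.
#' @export
#' @examples
#' parseFormula("C30H62")
parseFormula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("numeric formula must be a named vector of element counts")
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(formula))
      stop("cannot parse formula: ", formula)
    sym <- sub("[0-9]*$", "", toks)
    num <- sub("^[A-Za-z]+", "", toks)
    counts <- ifelse(nzchar(num), as.numeric(num), 1)
    names(counts) <- sym
    if (anyDuplicated(sym))
      counts <- tapply(counts, factor(sym, levels = unique(sym)), sum)
  }
  unknown <- setdiff(names(counts), .elementTable$symbol)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 1) || any(counts != round(counts)))
    stop("element counts must be positive integers")
  storage.mode(counts) <- "double"
  counts
}

## molar mass (g/mol) and electrons per formula unit
.formulaMass <- function(counts) {
  i <- match(names(counts), .elementTable$symbol)
  sum(counts * .elementTable$mass[i])
}

.formulaElectrons <- function(counts) {
  i <- match(names(counts), .elementTable$symbol)
  sum(counts * .elementTable$Z[i])
}
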