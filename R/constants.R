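## Physical constants and per-element tables used across the package.
## Units: lengths in Angstrom, energies in eV, charges in e, masses in amu,
## time in fs (MD converts internally).

#' Physical constants used by celliq
#'
#' @format A list with elements:
#' \describe{
#'   \item{ke}{Coulomb constant, eV Angstrom / e^2.}
#'   \item{kb}{Boltzmann constant, eV / K.}
#'   \item{acc}{Conversion factor (eV / (amu Angstrom)) -> Angstrom / fs^2,
#'     also (eV/amu) -> (Angstrom/fs)^2.}
#' }
#' @export
celliq_constants <- list(
  ke  = 14.399645,        # eV*Angstrom/e^2
  kb  = 8.617333262e-5,   # eV/K
  acc = 9.64853322e-3     # eV/(amu*Angstrom) -> Angstrom/fs^2
)

# Single-bond covalent radii [Angstrom] for the elements the package is
# routinely used with; indexed by atomic number as character key.
.covalent_radii <- c(
  "1" = 0.32, "3" = 1.33, "6" = 0.75, "7" = 0.71, "8" = 0.63,
  "9" = 0.64, "11" = 1.55, "12" = 1.39, "13" = 1.26, "14" = 1.16,
  "15" = 1.11, "16" = 1.03, "17" = 0.99, "19" = 1.96, "20" = 1.71,
  "35" = 1.14, "47" = 1.28, "53" = 1.33, "79" = 1.24
)

# Standard atomic masses [amu], indexed by atomic number.
.atomic_masses <- c(
  "1" = 1.008, "3" = 6.94, "6" = 12.011, "7" = 14.007, "8" = 15.999,
  "9" = 18.998, "11" = 22.990, "12" = 24.305, "13" = 26.982, "14" = 28.085,
  "15" = 30.974, "16" = 32.06, "17" = 35.45, "19" = 39.098, "20" = 40.078,
  "35" = 79.904, "47" = 107.868, "53" = 126.904, "79" = 196.967
)

# Element symbols, indexed by atomic number.
.element_symbols <- c(
  "1" = "H", "3" = "Li", "6" = "C", "7" = "N", "8" = "O", "9" = "F",
  "11" = "Na", "12" = "Mg", "13" = "Al", "14" = "Si", "15" = "P",
  "16" = "S", "17" = "Cl", "19" = "K", "20" = "Ca", "35" = "Br",
  "47" = "Ag", "53" = "I", "79" = "Au"
)

#' Look up single-bond covalent radii
#'
#' @param z Integer vector of atomic numbers.
#' @return Numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(z) {
  key <- as.character(z)
  miss <- !(key %in% names(.covalent_radii))
  if (any(miss)) {
    stop("no covalent radius tabulated for element Z = ",
         paste(unique(z[miss]), collapse = ", "))
  }
  unname(.covalent_radii[key])
}

#' Look up standard atomic masses
#'
#' @param z Integer vector of atomic numbers.
#' @return Numeric vector of masses in amu.
#' @export
atomic_mass <- function(z) {
  key <- as.character(z)
  miss <- !(key %in% names(.atomic_masses))
  if (any(miss)) {
    stop("no atomic mass tabulated for element Z = ",
         paste(unique(z[miss]), collapse = ", "))
  }
  unname(.atomic_masses[key])
}

# symbol <-> atomic number helpers (internal)
.z_to_symbol <- function(z) {
  key <- as.character(z)
  miss <- !(key %in% names(.element_symbols))
  if (any(miss)) stop("unknown element Z = ", paste(unique(z[miss]), collapse = ", "))
  unname(.element_symbols[key])
}

.symbol_to_z <- function(sym) {
  lut <- stats::setNames(as.integer(names(.element_symbols)), .element_symbols)
  miss <- !(sym %in% names(lut))
  if (any(miss)) stop("unknown element symbol: ", paste(unique(sym[miss]), collapse = ", "))
  unname(lut[sym])
}

# error function via the normal CDF (exact relation, no approximation)
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
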