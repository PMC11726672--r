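#' Physical constants used throughout the package
#'
#' CODATA 2018 values. Energies are carried in hartree for electronic
#' energies and kcal/mol for thermal corrections and free-energy
#' differences; the hartree-to-kcal/mol conversion is pinned at 627.5095.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_to_kcal}{kcal/mol per hartree (627.5095)}
#'   \item{R_kcal}{gas constant, kcal/(mol K)}
#'   \item{R_cal}{gas constant, cal/(mol K)}
#'   \item{h}{Planck constant, J s}
#'   \item{c_cm}{speed of light, cm/s}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{NA_const}{Avogadro constant, 1/mol}
#'   \item{amu_kg}{atomic mass unit, kg}
#'   \item{atm_Pa}{standard atmosphere, Pa}
#'   \item{proton_mass_u}{proton mass, u}
#' }
#' @export
physical_constants <- list(
  hartree_to_kcal = 627.5095,
  R_kcal   = 1.9872041e-3,   # kcal mol-1 K-1
  R_cal    = 1.9872041,      # cal mol-1 K-1
  h        = 6.62607015e-34, # J s
  c_cm     = 2.99792458e10,  # cm s-1
  kB       = 1.380649e-23,   # J K-1
  NA_const = 6.02214076e23,  # mol-1
  amu_kg   = 1.66053906660e-27,
  atm_Pa   = 101325,
  proton_mass_u = 1.00727646688
)

# Most-abundant-isotope atomic masses (u), the convention of standard
# thermochemistry codes. Keys are capitalised element symbols.
.atomic_masses <- c(
  H = 1.00782503, He = 4.00260325, Li = 7.01600344, Be = 9.01218306,
  B = 11.00930536, C = 12.0, N = 14.00307401, O = 15.99491462,
  F = 18.99840316, Ne = 19.99244018, Na = 22.98976928, Mg = 23.98504170,
  Al = 26.98153853, Si = 27.97692653, P = 30.97376200, S = 31.97207117,
  Cl = 34.96885268, Ar = 39.96238312, K = 38.96370649, Ca = 39.96259086,
  Fe = 55.93493633, Zn = 63.92914201, Se = 79.91652176, Br = 78.91833760,
  I = 126.90447190
)

#' Atomic masses for a vector of element symbols
#'
#' @param elements character vector of element symbols (any case).
#' @return numeric vector of masses in u.
#' @export
atomic_mass <- function(elements) {
  key <- normalize_element(elements)
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(key[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# "FE" -> "Fe", "c" -> "C"; errors on symbols absent from the table are
# left to the callers that need masses.
normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

is_known_element <- function(x) {
  normalize_element(x) %in% names(.atomic_masses)
}
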