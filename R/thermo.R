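#' Rotational constants from a geometry
#'
#' Principal moments of inertia about the center of mass, converted to
#' rotational constants B = h / (8 pi^2 I) in GHz, sorted descending.
#' For linear molecules the moment about the molecular axis vanishes and
#' the corresponding constant is unbounded: it is reported as \code{Inf}
#' and the result carries \code{attr(, "linear") = TRUE}. Monoatomic
#' input has no rotational constants and is an error.
#'
#' @param structure a \code{\link{structure3d}}.
#' @param masses optional per-atom masses in u (defaults to
#'   most-abundant-isotope masses looked up by element).
#' @return numeric length-3 vector (GHz, descending), possibly with a
#'   \code{linear} attribute.
#' @export
rotational_constants <- function(structure, masses = NULL) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (n < 2) stop("monoatomic input has no rotational constants")
  if (is.null(masses)) masses <- atomic_mass(structure$atoms$element)
  stopifnot(length(masses) == n, all(masses > 0))
  com <- colSums(xyz * masses) / sum(masses)
  r <- sweep(xyz, 2, com)
  # inertia tensor in u Angstrom^2
  I <- matrix(0, 3, 3)
  r2 <- rowSums(r^2)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(masses * ((a == b) * r2 - r[, a] * r[, b]))
  }
  mom <- sort(eigen(I, symmetric = TRUE)$values)  # ascending
  pc <- physical_constants
  to_ghz <- function(i_ua2) {
    i_si <- i_ua2 * pc$amu_kg * 1e-20
    pc$h / (8 * pi^2 * i_si) / 1e9
  }
  # a vanishing smallest moment marks a linear molecule
  linear <- mom[1] < 1e-8 * max(mom)
  b <- ifelse(mom < 1e-8 * max(mom), Inf, to_ghz(pmax(mom, .Machine$double.xmin)))
  b <- sort(b, decreasing = TRUE)
  if (linear) attr(b, "linear") <- TRUE
  b
}

#' Rigid-rotor/harmonic-oscillator thermal corrections
#'
#' Ideal-gas translational, rigid-rotor rotational and harmonic-
#' oscillator vibrational contributions to the enthalpy correction,
#' entropy, and Gibbs correction at temperature \code{temperature} and
#' a 1 atm standard state, with symmetry number 1. Harmonic frequencies
#' are multiplied by \code{scale} before the zero-point and all thermal
#' vibrational terms.
#'
#' @param frequencies harmonic frequencies in cm-1; negative values mark
#'   imaginary modes and are an error unless \code{drop_imaginary}.
#' @param rot_constants rotational constants in GHz (length 3, from
#'   \code{\link{rotational_constants}} or an input table), or
#'   \code{NULL} for an atomic species with no rotational contribution.
#'   A leading \code{Inf} (or a \code{linear} attribute) selects the
#'   linear-rotor expressions.
#' @param mass molecular mass in u.
#' @param temperature temperature in K (default 310.15, physiological).
#' @param pressure pressure in atm (default 1).
#' @param scale frequency scale factor (default 0.971).
#' @param drop_imaginary drop negative-tagged modes with a warning
#'   instead of erroring.
#' @return a \code{thermo_corrections} list: \code{h_corr} and
#'   \code{g_corr} in kcal/mol, \code{s_corr} in cal/(mol K),
#'   \code{zpe} in kcal/mol, plus the inputs used.
#' @export
rrho_corrections <- function(frequencies, rot_constants, mass,
                             temperature = 310.15, pressure = 1,
                             scale = 0.971, drop_imaginary = FALSE) {
  stopifnot(temperature > 0, pressure > 0, mass > 0, scale > 0)
  pc <- physical_constants
  Tk <- temperature
  freqs <- as.numeric(frequencies)
  if (any(freqs < 0)) {
    if (!drop_imaginary) {
      stop(sum(freqs < 0), " imaginary (negative-tagged) frequency(ies); ",
           "use drop_imaginary = TRUE to discard them")
    }
    warning("dropping ", sum(freqs < 0), " imaginary frequency(ies)")
    freqs <- freqs[freqs >= 0]
  }
  freqs <- freqs[freqs > 0] * scale

  # translational: H = 5/2 RT, S from the Sackur-Tetrode equation
  m_kg <- mass * pc$amu_kg
  q_trans <- (2 * pi * m_kg * pc$kB * Tk / pc$h^2)^1.5 *
    (pc$kB * Tk / (pressure * pc$atm_Pa))
  s_trans <- pc$R_cal * (log(q_trans) + 2.5)
  e_trans <- 1.5 * pc$R_kcal * Tk

  # rotational (symmetry number 1)
  s_rot <- 0; e_rot <- 0
  if (!is.null(rot_constants) && length(rot_constants)) {
    b <- sort(as.numeric(rot_constants), decreasing = TRUE)
    if (length(b) != 3) stop("rot_constants must hold 3 values or be NULL")
    linear <- isTRUE(attr(rot_constants, "linear")) || is.infinite(b[1])
    theta <- pc$h * b * 1e9 / pc$kB  # rotational temperatures, K
    if (linear) {
      th <- theta[is.finite(theta)][1]
      q_rot <- Tk / th
      s_rot <- pc$R_cal * (log(q_rot) + 1)
      e_rot <- pc$R_kcal * Tk
    } else {
      q_rot <- sqrt(pi) * sqrt(Tk^3 / prod(theta))
      s_rot <- pc$R_cal * (log(q_rot) + 1.5)
      e_rot <- 1.5 * pc$R_kcal * Tk
    }
  }

  # vibrational (harmonic), scaled frequencies throughout
  zpe <- 0; e_vib <- 0; s_vib <- 0
  if (length(freqs)) {
    theta_v <- pc$h * pc$c_cm * freqs / pc$kB  # K
    u <- theta_v / Tk
    zpe <- sum(pc$R_kcal * theta_v / 2)
    e_vib <- zpe + pc$R_kcal * sum(theta_v / expm1(u))
    s_vib <- pc$R_cal * sum(u / expm1(u) - log(-expm1(-u)))
  }

  h_corr <- e_trans + e_rot + e_vib + pc$R_kcal * Tk  # + PV term
  s_corr <- s_trans + s_rot + s_vib
  g_corr <- h_corr - Tk * s_corr / 1000
  out <- list(h_corr = h_corr, s_corr = s_corr, g_corr = g_corr, zpe = zpe,
              temperature = Tk, pressure = pressure, scale_factor = scale)
  class(out) <- "thermo_corrections"
  out
}

#' @export
print.thermo_corrections <- function(x, ...) {
  cat(sprintf(paste0("RRHO corrections at %.2f K, %.3g atm (scale %.3f):\n",
                     "  H_corr = %.4f kcal/mol\n  S      = %.4f cal/(mol K)\n",
                     "  G_corr = %.4f kcal/mol  (ZPE %.4f)\n"),
              x$temperature, x$pressure, x$scale_factor,
              x$h_corr, x$s_corr, x$g_corr, x$zpe))
  invisible(x)
}
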