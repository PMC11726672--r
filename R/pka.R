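#' Gas-phase Gibbs free energy of a bare proton
#'
#' A proton has no electrons or internal structure, so its ideal-gas
#' free energy is purely translational: H = 5/2 RT and S from the
#' Sackur-Tetrode equation at the stated pressure, G = H - TS.
#' The default standard state is 1 bar, the modern thermochemical
#' convention under which the tabulated S(H+) = 26.04 cal/(mol K) and
#' G = -6.28 kcal/mol at 298.15 K are defined (at 1 atm the entropy is
#' 0.026 cal/(mol K) smaller and G is -6.27 kcal/mol).
#'
#' @param temperature temperature in K.
#' @param pressure pressure (default 1).
#' @param pressure_unit \code{"bar"} (default) or \code{"atm"}.
#' @return Gibbs free energy in kcal/mol (negative: entropy dominates).
#' @export
proton_gas_free_energy <- function(temperature = 298.15, pressure = 1,
                                   pressure_unit = c("bar", "atm")) {
  stopifnot(temperature > 0, pressure > 0)
  pressure_unit <- match.arg(pressure_unit)
  pc <- physical_constants
  p_pa <- pressure * if (pressure_unit == "bar") 1e5 else pc$atm_Pa
  m_kg <- pc$proton_mass_u * pc$amu_kg
  q_trans <- (2 * pi * m_kg * pc$kB * temperature / pc$h^2)^1.5 *
    (pc$kB * temperature / p_pa)
  s <- pc$R_cal * (log(q_trans) + 2.5)        # Sackur-Tetrode, cal/(mol K)
  h <- 2.5 * pc$R_kcal * temperature          # kcal/mol
  h - temperature * s / 1000
}

#' Construct the component energies of a proton-based pKa cycle
#'
#' Holds the six free energies of the dissociation cycle
#' HA+ -> A + H+: gas-phase Gibbs energies of the acid and conjugate
#' base, their solvation free energies, and the proton's gas-phase and
#' solvation free energies. The proton values cannot be computed
#' quantum-mechanically; the defaults are the experimental
#' dG_sol(H+) = -265.6 kcal/mol and the Sackur-Tetrode gas-phase value
#' at the cycle temperature (-6.28 kcal/mol at 298.15 K; the sign
#' convention is configurable because the literature often prints the
#' magnitude).
#'
#' @param g_gas_ha,g_gas_a gas-phase Gibbs energies of HA+ and A
#'   (kcal/mol; "method 2" semantics: evaluated at solution-phase
#'   geometries).
#' @param dg_sol_ha,dg_sol_a solvation free energies of HA+ and A
#'   (kcal/mol).
#' @param dg_sol_h proton solvation free energy (kcal/mol).
#' @param g_gas_h proton gas-phase free energy (kcal/mol); default
#'   computed from \code{\link{proton_gas_free_energy}} at
#'   \code{temperature}.
#' @param temperature temperature in K (default 310.15).
#' @return a \code{pka_cycle} list.
#' @export
pka_cycle <- function(g_gas_ha, g_gas_a, dg_sol_ha, dg_sol_a,
                      dg_sol_h = -265.6, g_gas_h = NULL,
                      temperature = 310.15) {
  if (is.null(g_gas_h)) g_gas_h <- proton_gas_free_energy(temperature)
  vals <- c(g_gas_ha = g_gas_ha, g_gas_a = g_gas_a, dg_sol_ha = dg_sol_ha,
            dg_sol_a = dg_sol_a, dg_sol_h = dg_sol_h, g_gas_h = g_gas_h,
            temperature = temperature)
  if (!all(is.finite(vals))) stop("non-finite cycle component")
  stopifnot(temperature > 0)
  out <- as.list(vals)
  class(out) <- "pka_cycle"
  out
}

#' Aqueous dissociation free energy from a thermodynamic cycle
#'
#' dG_gas = G_gas(A) + G_gas(H+) - G_gas(HA+);
#' ddG_sol = dG_sol(A) + dG_sol(H+) - dG_sol(HA+);
#' dG_aq = dG_gas + ddG_sol.
#'
#' @param cycle a \code{\link{pka_cycle}}.
#' @param standard_state_correction add RT ln(24.46) per mole change of
#'   gas-phase standard state (1 atm -> 1 M) to dG_aq; off by default.
#' @return a \code{pka_result} list: \code{dg_gas}, \code{ddg_sol},
#'   \code{dg_aq} (kcal/mol), \code{pka}, \code{temperature}.
#' @export
delta_g_aq <- function(cycle, standard_state_correction = FALSE) {
  stopifnot(inherits(cycle, "pka_cycle"))
  dg_gas <- cycle$g_gas_a + cycle$g_gas_h - cycle$g_gas_ha
  ddg_sol <- cycle$dg_sol_a + cycle$dg_sol_h - cycle$dg_sol_ha
  dg_aq <- dg_gas + ddg_sol
  if (standard_state_correction) {
    # HA+(1 M) -> A(1 M) + H+(1 M): net +1 mole of solute, one
    # 1 atm -> 1 M compression term RT ln(24.46)
    dg_aq <- dg_aq + physical_constants$R_kcal * cycle$temperature * log(24.46)
  }
  out <- list(dg_gas = dg_gas, ddg_sol = ddg_sol, dg_aq = dg_aq,
              pka = pka_from_dg(dg_aq, cycle$temperature),
              temperature = cycle$temperature)
  class(out) <- "pka_result"
  out
}

#' pKa from an aqueous dissociation free energy
#'
#' pKa = dG_aq / (RT ln 10). An error of 1.36 kcal/mol in dG_aq at
#' 298.15 K corresponds to one pKa unit.
#'
#' @param dg_aq aqueous dissociation free energy in kcal/mol.
#' @param temperature temperature in K.
#' @return pKa (dimensionless).
#' @export
pka_from_dg <- function(dg_aq, temperature = 310.15) {
  stopifnot(temperature > 0)
  dg_aq / (physical_constants$R_kcal * temperature * log(10))
}

#' @export
print.pka_result <- function(x, ...) {
  cat(sprintf(paste0("pKa cycle at %.2f K:\n  dG_gas  = %8.3f kcal/mol\n",
                     "  ddG_sol = %8.3f kcal/mol\n  dG_aq   = %8.3f kcal/mol\n",
                     "  pKa     = %8.3f\n"),
              x$temperature, x$dg_gas, x$ddg_sol, x$dg_aq, x$pka))
  invisible(x)
}
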