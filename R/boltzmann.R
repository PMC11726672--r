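#' Boltzmann populations of a conformer ensemble
#'
#' Relative Gibbs energies are taken against the minimum and populations
#' follow p_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT) with
#' R = 1.9872041e-3 kcal/(mol K). The default temperature is 310.15 K
#' (physiological).
#'
#' @param g per-conformer Gibbs free energies in kcal/mol.
#' @param temperature temperature in K.
#' @param ids optional conformer identifiers.
#' @return a \code{population_result} data.frame with columns
#'   \code{conformer_id}, \code{delta_g_kcal}, \code{population},
#'   \code{population_pct}, sorted by ascending delta G; the temperature
#'   is carried as an attribute.
#' @export
boltzmann_populations <- function(g, temperature = 310.15, ids = NULL) {
  g <- as.numeric(g)
  if (!length(g)) stop("empty Gibbs-energy input")
  stopifnot(all(is.finite(g)), temperature > 0)
  if (is.null(ids)) ids <- sprintf("conf_%03d", seq_along(g))
  dg <- g - min(g)
  w <- exp(-dg / (physical_constants$R_kcal * temperature))
  p <- w / sum(w)
  out <- data.frame(conformer_id = as.character(ids),
                    delta_g_kcal = dg,
                    population = p,
                    population_pct = 100 * p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$delta_g_kcal), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "temperature") <- temperature
  class(out) <- c("population_result", "data.frame")
  out
}

#' Full conformer free-energy pipeline
#'
#' Deduplicates an ensemble, computes RRHO corrections from its
#' frequencies and rotational constants, extrapolates DZ/TZ/QZ
#' electronic energies to the CBS limit, assembles Gibbs free energies,
#' and returns Boltzmann populations.
#'
#' @param et an \code{energy_table} with \code{e_dz}/\code{e_tz}/
#'   \code{e_qz} columns, frequencies, rotational constants and masses.
#' @param temperature temperature in K (default 310.15).
#' @param scale frequency scale factor (default 0.971).
#' @param pressure pressure in atm (default 1).
#' @param dedup run the uniqueness screen first (default TRUE).
#' @param rel_tol,e_tol dedup tolerances, see
#'   \code{\link{dedup_conformers}}.
#' @param drop_imaginary passed to \code{\link{rrho_corrections}}.
#' @return a \code{population_result} with extra columns \code{g_kcal}
#'   (absolute assembled G) and \code{e_cbs_hartree}.
#' @export
conformer_free_energies <- function(et, temperature = 310.15, scale = 0.971,
                                    pressure = 1, dedup = TRUE,
                                    rel_tol = 0.01, e_tol = 0.1,
                                    drop_imaginary = FALSE) {
  if (dedup) et <- dedup_conformers(et, rel_tol = rel_tol, e_tol = e_tol)$unique
  if (!all(et$cbs_eligible)) {
    stop("conformer(s) lack DZ/TZ/QZ energies for CBS: ",
         paste(et$conformer_id[!et$cbs_eligible], collapse = ", "))
  }
  g <- vapply(seq_len(nrow(et)), function(i) {
    cbs <- cbs_extrapolate(et$e_dz[i], et$e_tz[i], et$e_qz[i])
    tc <- rrho_corrections(et$freqs[[i]], et$rotconst[[i]], et$mass_u[i],
                           temperature = temperature, pressure = pressure,
                           scale = scale, drop_imaginary = drop_imaginary)
    assemble_gibbs(cbs$e_cbs, tc$g_corr)
  }, numeric(1))
  e_cbs <- vapply(seq_len(nrow(et)), function(i) {
    cbs_extrapolate(et$e_dz[i], et$e_tz[i], et$e_qz[i])$e_cbs
  }, numeric(1))
  out <- boltzmann_populations(g, temperature = temperature,
                               ids = et$conformer_id)
  out$g_kcal <- g[match(out$conformer_id, et$conformer_id)]
  out$e_cbs_hartree <- e_cbs[match(out$conformer_id, et$conformer_id)]
  out
}
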