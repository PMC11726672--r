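#' Complete-basis-set extrapolation (inverse-polynomial scheme)
#'
#' Solves E(n) = E_CBS + A n^-p1 + B n^-p2 exactly through the three
#' correlation-consistent energies at cardinal numbers n = 2, 3, 4
#' (double-, triple-, quadruple-zeta). The default exponent pair (4, 5)
#' is the "4-5 inverse polynomial" scheme; the exponents and a cardinal
#' offset are configurable.
#'
#' @param e2,e3,e4 electronic energies (hartree) at cardinal numbers
#'   2, 3, 4.
#' @param exponents the two inverse-polynomial exponents (default
#'   \code{c(4, 5)}).
#' @param offset additive offset on the cardinal numbers (default 0;
#'   some schemes use half-integer effective cardinal numbers).
#' @return a \code{cbs_series} list: \code{e_cbs}, \code{coeff_a},
#'   \code{coeff_b} (hartree), inputs, and the fit residuals.
#' @export
cbs_extrapolate <- function(e2, e3, e4, exponents = c(4, 5), offset = 0) {
  e <- c(e2, e3, e4)
  if (length(e) != 3 || !all(is.finite(e))) {
    stop("cbs_extrapolate needs three finite energies")
  }
  stopifnot(length(exponents) == 2, exponents[1] != exponents[2])
  n <- 2:4 + offset
  M <- cbind(1, n^(-exponents[1]), n^(-exponents[2]))
  coef <- solve(M, e)
  resid <- as.numeric(M %*% coef - e)
  out <- list(e_cbs = coef[1], coeff_a = coef[2], coeff_b = coef[3],
              e2 = e2, e3 = e3, e4 = e4,
              exponents = exponents, offset = offset, residuals = resid)
  class(out) <- "cbs_series"
  out
}

#' @export
print.cbs_series <- function(x, ...) {
  cat(sprintf("CBS extrapolation (n^-%g + n^-%g): E_CBS = %.8f hartree\n",
              x$exponents[1], x$exponents[2], x$e_cbs))
  cat(sprintf("  A = %.6f, B = %.6f; max residual %.2e hartree\n",
              x$coeff_a, x$coeff_b, max(abs(x$residuals))))
  invisible(x)
}

#' Combine a CBS electronic energy with a thermal Gibbs correction
#'
#' G = 627.5095 * e_cbs + g_corr, i.e. the high-level electronic energy
#' (hartree) converted to kcal/mol plus the RRHO Gibbs correction
#' (kcal/mol). Absolute values are large; only differences between
#' conformers are meaningful.
#'
#' @param e_cbs electronic energy in hartree.
#' @param g_corr Gibbs correction in kcal/mol.
#' @return Gibbs free energy in kcal/mol.
#' @export
assemble_gibbs <- function(e_cbs, g_corr) {
  if (!all(is.finite(e_cbs)) || !all(is.finite(g_corr))) {
    stop("non-finite input to assemble_gibbs")
  }
  physical_constants$hartree_to_kcal * e_cbs + g_corr
}
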