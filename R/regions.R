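#' Transmembrane helix residue ranges of the mu-opioid receptor
#'
#' Inclusive residue intervals in human MOR numbering (the mouse
#' receptor matches after a +2 renumbering): the conserved region
#' 66-349 and the seven transmembrane helices. Shipped as the default
#' range map for \code{\link{region_rmsd_report}}; users can supply
#' their own named list of \code{c(start, end)} intervals.
#'
#' @return named list of integer length-2 vectors.
#' @export
mor_helix_ranges <- function() {
  list(
    conserved = c(66L, 349L),
    TM1 = c(66L, 98L),  TM2 = c(103L, 133L), TM3 = c(138L, 173L),
    TM4 = c(182L, 207L), TM5 = c(226L, 264L), TM6 = c(270L, 308L),
    TM7 = c(313L, 338L)
  )
}

# (residue number, atom name) intersection pairing between two
# structures sharing a numbering; returns a two-column index matrix.
pair_by_residue <- function(a, b) {
  ka <- paste(a$atoms$resno, a$atoms$name)
  kb <- paste(b$atoms$resno, b$atoms$name)
  common <- intersect(ka, kb)
  cbind(match(common, ka), match(common, kb))
}

#' Per-region RMSD report after a single global fit
#'
#' Pairs atoms of the two structures by (residue number, atom name)
#' within the requested selection, superposes once on \code{fit_region}
#' (default the conserved region), then reports the RMSD of each region
#' without refitting, so that regional deviations are measured in the
#' common frame. \code{refit_per_region = TRUE} instead refits within
#' each region. Residues missing from either structure are dropped from
#' the pairing and counted.
#'
#' @param a,b \code{structure3d} objects on a shared numbering (apply
#'   \code{\link{renumber_offset}} first if needed).
#' @param ranges named list of inclusive residue intervals (default
#'   \code{\link{mor_helix_ranges}()}).
#' @param selection atom selection used for pairing (default
#'   \code{"backbone"}).
#' @param fit_region name of the range used for the global fit.
#' @param refit_per_region refit inside every region instead of using
#'   the global frame.
#' @return data.frame (region, rmsd_angstrom, n_atoms, n_residues); a
#'   region with no paired atoms is reported with NA rather than
#'   erroring.
#' @export
region_rmsd_report <- function(a, b, ranges = mor_helix_ranges(),
                               selection = "backbone",
                               fit_region = "conserved",
                               refit_per_region = FALSE) {
  a <- select_atoms(a, selection)
  b <- select_atoms(b, selection)
  pr <- pair_by_residue(a, b)
  if (!nrow(pr)) stop("no atoms pair by (residue number, atom name)")
  n_dropped <- (nrow(a$atoms) - nrow(pr)) + (nrow(b$atoms) - nrow(pr))
  if (n_dropped > 0) {
    message(n_dropped, " unpaired atom records dropped from the pairing")
  }
  resno <- a$atoms$resno[pr[, 1]]
  if (!fit_region %in% names(ranges)) {
    stop("fit_region '", fit_region, "' not in the range map")
  }
  fr <- ranges[[fit_region]]
  in_fit <- resno >= fr[1] & resno <= fr[2]
  if (sum(in_fit) < 3) stop("fewer than 3 paired atoms in the fit region")
  sup <- kabsch(a, b, pr[in_fit, , drop = FALSE])
  xa <- sup$transform(coords(a))
  xb <- coords(b)
  rows <- lapply(names(ranges), function(nm) {
    rg <- ranges[[nm]]
    sel <- resno >= rg[1] & resno <= rg[2]
    if (!any(sel)) {
      return(data.frame(region = nm, rmsd_angstrom = NA_real_,
                        n_atoms = 0L, n_residues = 0L))
    }
    pri <- pr[sel, , drop = FALSE]
    r <- if (refit_per_region && sum(sel) >= 3) {
      kabsch(a, b, pri)$rmsd
    } else {
      rmsd_fixed(xa, xb, pri)
    }
    data.frame(region = nm, rmsd_angstrom = r, n_atoms = sum(sel),
               n_residues = length(unique(resno[sel])))
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- sup
  out
}
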