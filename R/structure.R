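#' Molecular structure container
#'
#' A light container for one set of atomic coordinates: an atom table
#' (element, atom name, residue name, residue number, chain, x/y/z in
#' Angstrom) plus a free-text title. Atom order is preserved exactly as
#' read from the source file.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric n x 3 matrix of coordinates (Angstrom).
#' @param name atom names (defaults to the element symbols).
#' @param resid residue names (default "LIG").
#' @param resno integer residue numbers (default 1).
#' @param chain chain identifiers (default "A").
#' @param title free-text title.
#' @return An object of class \code{"structure3d"}.
#' @export
structure3d <- function(element, xyz, name = element, resid = "LIG",
                        resno = 1L, chain = "A", title = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (length(element) != n) stop("element/coordinate length mismatch")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  element <- normalize_element(element)
  bad <- !is_known_element(element)
  if (any(bad)) {
    stop("unknown element symbol(s): ", paste(unique(element[bad]), collapse = ", "))
  }
  atoms <- data.frame(
    element = element,
    name = rep_len(as.character(name), n),
    resid = rep_len(as.character(resid), n),
    resno = rep_len(as.integer(resno), n),
    chain = rep_len(as.character(chain), n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  obj <- list(atoms = atoms, title = as.character(title)[1])
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms")
  if (nzchar(x$title)) cat(" |", x$title)
  cat("\n  elements:",
      paste(names(sort(table(x$atoms$element), decreasing = TRUE)), collapse = " "),
      "\n  chains:", paste(unique(x$atoms$chain), collapse = " "),
      "| residues:", length(unique(paste(x$atoms$chain, x$atoms$resno))), "\n")
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param x a \code{structure3d}.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "structure3d"))
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a structure
#'
#' @param x a \code{structure3d}.
#' @param value n x 3 coordinate matrix.
#' @return the modified structure.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(inherits(x, "structure3d"), nrow(value) == nrow(x$atoms))
  x$atoms$x <- value[, 1]; x$atoms$y <- value[, 2]; x$atoms$z <- value[, 3]
  x
}

#' Number of atoms in a structure
#' @param x a \code{structure3d}.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

# Names constituting the peptide backbone; the "non-hydrogen backbone"
# convention used for receptor RMSDs.
.backbone_names <- c("N", "CA", "C", "O")

#' Subset a structure by a named atom selection
#'
#' @param x a \code{structure3d}.
#' @param selection one of \code{"all"}, \code{"backbone"} (N, CA, C, O),
#'   \code{"calpha"}, \code{"heavy"} (all non-hydrogen atoms).
#' @return the subsetted \code{structure3d}; errors if no atoms remain.
#' @export
select_atoms <- function(x, selection = c("all", "backbone", "calpha", "heavy")) {
  selection <- match.arg(selection)
  keep <- switch(selection,
    all      = rep(TRUE, nrow(x$atoms)),
    backbone = x$atoms$name %in% .backbone_names & x$atoms$element != "H",
    calpha   = x$atoms$name == "CA",
    heavy    = x$atoms$element != "H"
  )
  if (!any(keep)) stop("selection '", selection, "' matches no atoms")
  x$atoms <- x$atoms[keep, , drop = FALSE]
  rownames(x$atoms) <- NULL
  x
}

#' Shift all residue numbers of a structure by a constant offset
#'
#' Used to place two receptors on a common numbering before residue-based
#' pairing (e.g. the mouse MOR is shifted by +2 to match human MOR
#' numbering).
#'
#' @param x a \code{structure3d}.
#' @param offset integer shift applied to every residue number.
#' @return the renumbered structure; atoms are otherwise untouched.
#' @export
renumber_offset <- function(x, offset) {
  stopifnot(inherits(x, "structure3d"), length(offset) == 1, is.finite(offset))
  x$atoms$resno <- x$atoms$resno + as.integer(offset)
  x
}
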