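#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD
#' between paired atoms of two coordinate sets, via SVD of the
#' cross-covariance with a determinant correction that forbids
#' reflections.
#'
#' @param moving,fixed \code{\link{structure3d}} objects or n x 3
#'   coordinate matrices.
#' @param pairing two-column integer matrix of (moving, fixed) atom
#'   indices; by default atoms are paired 1:1 by position (requires
#'   equal atom counts).
#' @return a \code{superposition} list: \code{rotation} (3 x 3, det
#'   +1), \code{translation} (applied as x R + t), \code{rmsd} (A),
#'   \code{n_atoms}, and \code{transform(xyz)}, a function applying the
#'   fit to arbitrary coordinates.
#' @export
kabsch <- function(moving, fixed, pairing = NULL) {
  xm <- if (inherits(moving, "structure3d")) coords(moving) else as.matrix(moving)
  xf <- if (inherits(fixed, "structure3d")) coords(fixed) else as.matrix(fixed)
  if (is.null(pairing)) {
    if (nrow(xm) != nrow(xf)) stop("unequal atom counts need an explicit pairing")
    pairing <- cbind(seq_len(nrow(xm)), seq_len(nrow(xf)))
  }
  pairing <- as.matrix(pairing)
  if (nrow(pairing) < 3) stop("need at least 3 atom pairs")
  a <- xm[pairing[, 1], , drop = FALSE]
  b <- xf[pairing[, 2], , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (qr(a0)$rank < 2) stop("paired atoms are collinear; superposition is degenerate")
  H <- crossprod(a0, b0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # b ~ a %*% t(R)
  rot <- t(R)
  trans <- cb - ca %*% rot
  fit <- a0 %*% rot
  rmsd <- sqrt(mean(rowSums((fit - b0)^2)))
  out <- list(
    rotation = rot,
    translation = as.numeric(trans),
    rmsd = rmsd,
    n_atoms = nrow(pairing),
    transform = function(xyz) sweep(as.matrix(xyz) %*% rot, 2, -as.numeric(trans))
  )
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atom pairs: rmsd = %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' RMSD between paired atoms without fitting
#'
#' Root of the mean squared Euclidean deviation over the paired atoms,
#' in the coordinates as given (no superposition).
#'
#' @param a,b \code{structure3d} objects or n x 3 matrices.
#' @param pairing two-column index matrix; default pairs 1:1 by position.
#' @return RMSD in Angstrom.
#' @export
rmsd_fixed <- function(a, b, pairing = NULL) {
  xa <- if (inherits(a, "structure3d")) coords(a) else as.matrix(a)
  xb <- if (inherits(b, "structure3d")) coords(b) else as.matrix(b)
  if (is.null(pairing)) {
    if (nrow(xa) != nrow(xb)) stop("unequal atom counts need an explicit pairing")
    pairing <- cbind(seq_len(nrow(xa)), seq_len(nrow(xb)))
  }
  pairing <- as.matrix(pairing)
  if (!nrow(pairing)) stop("empty pairing")
  d <- xa[pairing[, 1], , drop = FALSE] - xb[pairing[, 2], , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}
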