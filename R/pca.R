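#' Principal component analysis of Cartesian C-alpha coordinates
#'
#' Stacks each structure's gap-free C-alpha coordinates into a
#' 3 x n_positions vector, mean-centers across structures, and
#' eigen-decomposes the covariance matrix. Each eigenvalue (A^2) is an
#' independent collective displacement variance; its fraction of the
#' eigenvalue sum is the proportion of total positional variance
#' carried by that component. The sign of every mode is fixed so that
#' its largest-magnitude loading is positive.
#'
#' @param ens a superposed \code{aligned_ensemble} (superposed on the
#'   fly over all positions if not).
#' @return a \code{pca_cartesian} list: \code{eigenvalues} (length
#'   3 n_positions, descending), \code{variance_proportions},
#'   \code{cumulative_proportions}, \code{projections} (structures x
#'   components scores), \code{mode_vectors} (3 n_positions x
#'   components), \code{mean_coords} (n_positions x 3),
#'   \code{positions}, \code{labels}, \code{degenerate} (TRUE when the
#'   ensemble has no positional variance at all, in which case the
#'   proportions are NA rather than NaN).
#' @export
pca_cartesian <- function(ens) {
  stopifnot(inherits(ens, "aligned_ensemble"))
  n <- dim(ens$coords)[2]
  if (n < 2) stop("need at least 2 structures for PCA")
  if (!ens$superposed) ens <- superpose_ensemble(ens)
  m <- dim(ens$coords)[1]
  # structure-major matrix: row j = (x1,y1,z1, x2,y2,z2, ...)
  X <- t(apply(ens$coords, 2, function(x) as.numeric(t(x))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  vec <- eig$vectors
  # sign convention: largest-|loading| element of each mode positive
  for (k in seq_len(ncol(vec))) {
    imax <- which.max(abs(vec[, k]))
    if (vec[imax, k] < 0) vec[, k] <- -vec[, k]
  }
  total <- sum(ev)
  degenerate <- total <= 1e-12
  prop <- if (degenerate) rep(NA_real_, length(ev)) else ev / total
  out <- list(
    eigenvalues = ev,
    variance_proportions = prop,
    cumulative_proportions = if (degenerate) prop else cumsum(prop),
    projections = Xc %*% vec,
    mode_vectors = vec,
    mean_coords = matrix(mu, ncol = 3, byrow = TRUE),
    positions = ens$positions,
    labels = ens$labels,
    degenerate = degenerate
  )
  rownames(out$projections) <- ens$labels
  class(out) <- "pca_cartesian"
  out
}

#' @export
print.pca_cartesian <- function(x, ...) {
  cat("pca_cartesian:", length(x$eigenvalues), "eigenvalues over",
      length(x$positions), "positions,", length(x$labels), "structures\n")
  if (x$degenerate) {
    cat("  degenerate ensemble: no positional variance\n")
  } else {
    cat(sprintf("  PC1 %.2f%%, PC2 %.2f%% (cumulative %.2f%%)\n",
                100 * x$variance_proportions[1],
                100 * x$variance_proportions[2],
                100 * x$cumulative_proportions[2]))
  }
  invisible(x)
}

#' Interpolated structures along one principal component
#'
#' Produces \code{n_frames} pseudo-structures sweeping the ensemble
#' mean from -amplitude to +amplitude along a mode, for visualising
#' the collective motion the component describes.
#'
#' @param pca a \code{pca_cartesian}.
#' @param component component index.
#' @param amplitude sweep amplitude in Angstrom (displacement along the
#'   unit mode vector at the extremes).
#' @param n_frames number of frames (default 11).
#' @return list of \code{structure3d} (C-alpha pseudo-atoms); write
#'   with \code{\link{write_xyz}}.
#' @export
export_mode_trajectory <- function(pca, component, amplitude, n_frames = 11) {
  stopifnot(inherits(pca, "pca_cartesian"), n_frames >= 1)
  if (component < 1 || component > ncol(pca$mode_vectors)) {
    stop("component ", component, " out of range 1..",
         ncol(pca$mode_vectors))
  }
  mode <- matrix(pca$mode_vectors[, component], ncol = 3, byrow = TRUE)
  s_seq <- if (n_frames == 1) 0 else seq(-1, 1, length.out = n_frames)
  lapply(seq_along(s_seq), function(i) {
    xyz <- pca$mean_coords + s_seq[i] * amplitude * mode
    structure3d(rep("C", nrow(xyz)), xyz, name = "CA", resid = "ALA",
                resno = pca$positions,
                title = sprintf("PC%d frame %d/%d (s = %+.3f)",
                                component, i, n_frames, s_seq[i]))
  })
}
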