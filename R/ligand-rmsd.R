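#' Heavy-atom RMSD with optimal like-element atom matching
#'
#' Minimum superposed RMSD between two conformers of the same molecule
#' allowing any permutation of atoms within each element, as used when
#' comparing conformer geometries whose atom orders differ. The search
#' alternates (i) a per-element Hungarian assignment under the current
#' superposition with squared-distance cost and (ii) a Kabsch refit
#' under the current assignment, until the assignment is stable
#' (at most \code{max_rounds} rounds). Because the alternation can
#' stick in local minima, it is started from the input atom order and
#' from a principal-axes pre-alignment under each of the four proper
#' axis-flip hypotheses, keeping the best result.
#'
#' @param a,b \code{\link{structure3d}} objects of the same molecule;
#'   hydrogens are excluded before matching.
#' @param max_rounds assignment/refit alternation cap per start.
#' @return the minimised RMSD (Angstrom), with attributes
#'   \code{permutation} (index into b's heavy atoms for each of a's)
#'   and \code{superposition}.
#' @export
ligand_heavy_rmsd <- function(a, b, max_rounds = 50) {
  a <- select_atoms(a, "heavy"); b <- select_atoms(b, "heavy")
  ea <- a$atoms$element; eb <- b$atoms$element
  ta <- table(ea); tb <- table(eb)
  if (!identical(sort(names(ta)), sort(names(tb))) ||
      !all(ta[sort(names(ta))] == tb[sort(names(ta))])) {
    only_a <- setdiff(paste0(names(ta), "x", as.integer(ta)),
                      paste0(names(tb), "x", as.integer(tb)))
    only_b <- setdiff(paste0(names(tb), "x", as.integer(tb)),
                      paste0(names(ta), "x", as.integer(ta)))
    stop("heavy-atom element multisets differ (a: ",
         paste(only_a, collapse = ", "), " vs b: ",
         paste(only_b, collapse = ", "), ")")
  }
  xa <- coords(a); xb <- coords(b)
  n <- nrow(xa)
  groups <- split(seq_len(n), ea)            # indices into a
  groups_b <- split(seq_len(n), eb)          # indices into b

  assign_under <- function(xa_t) {
    perm <- integer(n)
    for (el in names(groups)) {
      ia <- groups[[el]]; ib <- groups_b[[el]]
      if (length(ia) == 1L) { perm[ia] <- ib; next }
      cost <- outer(ia, ib, Vectorize(function(i, j) sum((xa_t[i, ] - xb[j, ])^2)))
      perm[ia] <- ib[solve_assignment(cost)]
    }
    perm
  }

  refine <- function(xa_start) {
    perm <- assign_under(xa_start)
    best <- NULL
    for (round in seq_len(max_rounds)) {
      sup <- kabsch(xa, xb, cbind(seq_len(n), perm))
      best <- list(perm = perm, sup = sup)
      new_perm <- assign_under(sup$transform(xa))
      if (identical(new_perm, perm)) break
      perm <- new_perm
    }
    best
  }

  # principal-axes frames (unit weights) for the pre-alignment starts:
  # every proper axis permutation/flip hypothesis, since near-degenerate
  # inertia axes make any single hypothesis unreliable
  axes <- function(x) eigen(stats::cov(x), symmetric = TRUE)$vectors
  ca <- sweep(xa, 2, colMeans(xa)); cb <- sweep(xb, 2, colMeans(xb))
  Va <- axes(ca); Vb <- axes(cb)
  axis_perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                     c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  starts <- list(xa)  # input order / raw frame
  for (p in axis_perms) {
    for (r in seq_len(nrow(signs))) {
      R <- Vb %*% (diag(as.numeric(signs[r, ])) %*% t(Va[, p]))
      if (det(R) < 0) next  # reflections are not rigid motions
      starts[[length(starts) + 1L]] <-
        sweep(ca %*% t(R), 2, -colMeans(xb))
    }
  }
  results <- lapply(starts, refine)
  rmsds <- vapply(results, function(r) r$sup$rmsd, numeric(1))
  best <- results[[which.min(rmsds)]]
  out <- best$sup$rmsd
  attr(out, "permutation") <- best$perm
  attr(out, "superposition") <- best$sup
  out
}
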