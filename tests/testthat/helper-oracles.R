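# Independent oracles used to cross-check the package implementations.
# Each is deliberately written along a different algorithmic route than
# the code it checks.

# Superposed RMSD via the Kearsley quaternion characteristic matrix:
# the smallest eigenvalue of the 4x4 matrix equals the residual sum of
# squares of the optimal proper rotation.
quaternion_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  m <- a - b; p <- a + b
  xm <- m[, 1]; ym <- m[, 2]; zm <- m[, 3]
  xp <- p[, 1]; yp <- p[, 2]; zp <- p[, 3]
  K <- matrix(c(
    sum(xm^2 + ym^2 + zm^2), sum(yp*zm - ym*zp),      sum(xm*zp - xp*zm),      sum(xp*ym - xm*yp),
    sum(yp*zm - ym*zp),      sum(xm^2 + yp^2 + zp^2), sum(xm*ym - xp*yp),      sum(xm*zm - xp*zp),
    sum(xm*zp - xp*zm),      sum(xm*ym - xp*yp),      sum(xp^2 + ym^2 + zp^2), sum(ym*zm - yp*zp),
    sum(xp*ym - xm*yp),      sum(xm*zm - xp*zp),      sum(ym*zm - yp*zp),      sum(xp^2 + yp^2 + zm^2)
  ), 4, 4)
  ev <- eigen(K, symmetric = TRUE)$values
  sqrt(max(min(ev), 0) / nrow(a))
}

# plain double-loop RMSD, no linear algebra shared with rmsd_fixed
brute_rmsd <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (k in 1:3) s <- s + (a[i, k] - b[i, k])^2
  }
  sqrt(s / nrow(a))
}

# all permutations of 1..n (n <= 6 here)
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

# exhaustive like-element permutation RMSD: every per-element atom
# assignment, Kabsch fit per candidate, global minimum
exhaustive_perm_rmsd <- function(el, xa, xb) {
  groups <- split(seq_along(el), el)
  cand <- list(integer(length(el)))
  for (g in groups) {
    pg <- perms(length(g))
    cand <- unlist(lapply(cand, function(base) {
      lapply(seq_len(nrow(pg)), function(r) {
        base[g] <- g[pg[r, ]]; base
      })
    }), recursive = FALSE)
  }
  min(vapply(cand, function(p) {
    qcensemble::kabsch(xa, xb, cbind(seq_along(el), p))$rmsd
  }, numeric(1)))
}

# CBS coefficients by Cramer's rule (explicit 3x3 determinants)
cramer_cbs <- function(e, n = 2:4, p = c(4, 5)) {
  M <- cbind(1, n^(-p[1]), n^(-p[2]))
  det3 <- function(A) {
    A[1,1]*(A[2,2]*A[3,3]-A[2,3]*A[3,2]) -
    A[1,2]*(A[2,1]*A[3,3]-A[2,3]*A[3,1]) +
    A[1,3]*(A[2,1]*A[3,2]-A[2,2]*A[3,1])
  }
  d <- det3(M)
  vapply(1:3, function(j) { Mj <- M; Mj[, j] <- e; det3(Mj) / d }, numeric(1))
}

# closed-form Sackur-Tetrode Gibbs energy for a structureless particle,
# written from scratch in SI and converted at the end
closed_form_particle_g <- function(mass_u, T, p_pa) {
  kB <- 1.380649e-23; h <- 6.62607015e-34; NAv <- 6.02214076e23
  m <- mass_u * 1.66053906660e-27
  lam <- h / sqrt(2 * pi * m * kB * T)      # thermal wavelength
  s_per_molecule <- kB * (log(kB * T / (p_pa * lam^3)) + 2.5)
  h_per_mol <- 2.5 * kB * T * NAv
  (h_per_mol - T * s_per_molecule * NAv) / 4184  # J -> kcal
}

# tiny PDB writer for fixtures
pdb_lines <- function(df, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, seq_len(nrow(df)),
          paste0(ifelse(nchar(df$name) < 4, " ", ""), df$name),
          if (!is.null(df$alt)) df$alt else "",
          df$resid, df$chain, df$resno,
          if (!is.null(df$icode)) df$icode else "",
          df$x, df$y, df$z, 1, 0, df$element)
}

random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# helical toy protein with backbone + one side-chain + hydrogen per residue
toy_protein <- function(resno, chain = "A", jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(resno), function(i) {
    base <- c(2.3 * cos(i / 1.7), 2.3 * sin(i / 1.7), 1.5 * i)
    data.frame(
      element = c("N", "C", "C", "O", "C", "H"),
      name = c("N", "CA", "C", "O", "CB", "HA"),
      resid = "ALA", resno = resno[i], chain = chain,
      x = base[1] + c(0, .5, 1.0, 1.2, .6, .4),
      y = base[2] + c(0, .4, .2, 1.0, -.9, .8),
      z = base[3] + c(0, .3, .8, .9, .5, .1))
  }))
  if (jitter > 0) {
    rows$x <- rows$x + stats::rnorm(nrow(rows), sd = jitter)
    rows$y <- rows$y + stats::rnorm(nrow(rows), sd = jitter)
    rows$z <- rows$z + stats::rnorm(nrow(rows), sd = jitter)
  }
  structure3d(rows$element, cbind(rows$x, rows$y, rows$z),
              name = rows$name, resid = rows$resid,
              resno = rows$resno, chain = rows$chain)
}
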