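test_that("Kabsch removes rigid motion and matches the quaternion oracle", {
  set.seed(21)
  x <- matrix(rnorm(30, sd = 3), ncol = 3)
  self <- kabsch(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sweep(x %*% Rz, 2, -c(1, 2, 3))
  fit <- kabsch(x, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  for (rep in 1:10) {
    a <- matrix(rnorm(12, sd = 2), ncol = 3)
    b <- a + matrix(rnorm(12, sd = 0.4), ncol = 3)
    fit <- kabsch(a, b)
    expect_equal(fit$rmsd, quaternion_rmsd(a, b), tolerance = 1e-6)
    # symmetry and the fitted-vs-raw bound
    expect_equal(kabsch(b, a)$rmsd, fit$rmsd, tolerance = 1e-9)
    expect_lte(fit$rmsd, brute_rmsd(a, b) + 1e-12)
    # invariance under a common rigid motion
    R <- random_rotation(); t <- rnorm(3)
    expect_equal(kabsch(sweep(a %*% R, 2, -t), sweep(b %*% R, 2, -t))$rmsd,
                 fit$rmsd, tolerance = 1e-9)
  }
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "3 atom pairs")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 0.0), "collinear")
})

test_that("fixed-frame RMSD matches its definition and a brute-force loop", {
  a <- matrix(0, 1, 3); b <- matrix(c(2, 0, 0), 1, 3)
  expect_equal(rmsd_fixed(rbind(a, a, a), rbind(b, b, b)), 2.0)
  set.seed(8)
  x <- matrix(rnorm(30), ncol = 3); y <- matrix(rnorm(30), ncol = 3)
  expect_equal(rmsd_fixed(x, y), brute_rmsd(x, y), tolerance = 1e-12)
  expect_equal(rmsd_fixed(x, x), 0)
  expect_error(rmsd_fixed(x, y, pairing = matrix(0, 0, 2)), "empty")
})

test_that("residue renumbering shifts numbers and nothing else", {
  s <- toy_protein(140:150)
  expect_identical(renumber_offset(s, 0), s)
  s2 <- renumber_offset(s, 2)
  expect_equal(unique(s2$atoms$resno), 142:152)  # 145 -> 147 among them
  expect_identical(coords(s2), coords(s))
  expect_identical(renumber_offset(s2, -2), s)
})

test_that("per-region RMSD uses one global fit and localises planted signal", {
  ranges <- list(whole = c(1, 30), r1 = c(1, 10), r2 = c(11, 20), r3 = c(21, 30))
  # globular fold: a coherent sub-domain shift cannot be soaked up by
  # the global fit the way it can on an elongated template
  set.seed(2)
  n <- 30
  base <- matrix(rnorm(n * 3, sd = 6), ncol = 3)
  rows <- do.call(rbind, lapply(1:n, function(i) {
    cbind(base[i, 1] + c(0, .5, 1, 1.2), base[i, 2] + c(0, .4, .2, 1),
          base[i, 3] + c(0, .3, .8, .9))
  }))
  a <- structure3d(rep(c("N", "C", "C", "O"), n), rows,
                   name = rep(c("N", "CA", "C", "O"), n),
                   resno = rep(1:n, each = 4))
  self <- region_rmsd_report(a, a, ranges, fit_region = "whole")
  expect_lt(max(self$rmsd_angstrom), 1e-9)

  # displace only r3 rigidly by 2 A and measure in the global frame
  b <- a
  xyz <- coords(b)
  move <- b$atoms$resno >= 21
  xyz[move, 1] <- xyz[move, 1] + 2
  coords(b) <- xyz
  rep <- region_rmsd_report(a, b, ranges, fit_region = "whole")
  r <- setNames(rep$rmsd_angstrom, rep$region)
  expect_gt(r["r3"], r["r1"])
  expect_gt(r["r3"], r["r2"])
  expect_gt(r["r3"], 1)
  # fitting on the stable sub-structure isolates the shift completely
  rep2 <- region_rmsd_report(a, b, c(ranges, list(stable = c(1, 20))),
                             fit_region = "stable")
  r2 <- setNames(rep2$rmsd_angstrom, rep2$region)
  expect_equal(unname(r2["r3"]), 2, tolerance = 1e-9)
  expect_lt(max(r2[c("r1", "r2")]), 1e-9)
})

test_that("per-region RMSD equals a brute-force evaluation after the fit", {
  set.seed(31)
  ranges <- list(all = c(1, 15), a = c(1, 5), b = c(6, 10), c = c(11, 15))
  s1 <- toy_protein(1:15, jitter = 0.2, seed = 2)
  s2 <- toy_protein(1:15, jitter = 0.2, seed = 3)
  rep <- region_rmsd_report(s1, s2, ranges, fit_region = "all")
  # recompute each region by hand from the stored global fit
  fit <- attr(rep, "fit")
  a_bb <- select_atoms(s1, "backbone"); b_bb <- select_atoms(s2, "backbone")
  xa <- fit$transform(coords(a_bb)); xb <- coords(b_bb)
  for (nm in names(ranges)) {
    sel <- a_bb$atoms$resno >= ranges[[nm]][1] &
      a_bb$atoms$resno <= ranges[[nm]][2]
    expect_equal(rep$rmsd_angstrom[rep$region == nm],
                 brute_rmsd(xa[sel, , drop = FALSE], xb[sel, , drop = FALSE]),
                 tolerance = 1e-9)
  }
  # union identity: weighted root-mean-square over disjoint regions
  sub <- rep[rep$region != "all", ]
  pooled <- sqrt(sum(sub$n_atoms * sub$rmsd_angstrom^2) / sum(sub$n_atoms))
  expect_equal(pooled, rep$rmsd_angstrom[rep$region == "all"],
               tolerance = 1e-9)
})

test_that("regions with no paired residues are reported absent, not fatal", {
  a <- toy_protein(1:10)
  rep <- region_rmsd_report(a, a, list(fit = c(1, 10), gone = c(500, 510)),
                            fit_region = "fit")
  expect_true(is.na(rep$rmsd_angstrom[rep$region == "gone"]))
  expect_equal(rep$n_atoms[rep$region == "gone"], 0)
})

test_that("unresolved residues are dropped from the pairing with a note", {
  a <- toy_protein(1:12)
  b <- toy_protein(c(1:5, 8:12))  # residues 6-7 unresolved in b
  expect_message(
    rep <- region_rmsd_report(a, b, list(all = c(1, 12)), fit_region = "all"),
    "dropped")
  expect_equal(rep$n_residues[rep$region == "all"], 10)
})

test_that("Hungarian assignment matches brute-force enumeration", {
  set.seed(14)
  for (n in c(2, 3, 5, 6)) {
    cost <- matrix(runif(n * n), n)
    sol <- solve_assignment(cost)
    best <- min(apply(perms(n), 1, function(p) sum(cost[cbind(1:n, p)])))
    expect_equal(attr(sol, "cost"), best, tolerance = 1e-12)
    expect_true(all(sort(sol) == 1:n))
  }
})

test_that("like-element matching recovers permutations and rigid motions", {
  set.seed(77)
  el <- c("C", "C", "C", "N", "O", "O")
  xyz <- matrix(rnorm(18, sd = 2), ncol = 3)
  a <- structure3d(el, xyz)
  p <- c(2, 3, 1, 4, 6, 5)
  b <- structure3d(el[p], xyz[p, ])
  expect_equal(as.numeric(ligand_heavy_rmsd(a, b)), 0, tolerance = 1e-9)

  moved <- structure3d(el[p], sweep(xyz[p, ] %*% random_rotation(), 2, -c(4, 5, 6)))
  expect_equal(as.numeric(ligand_heavy_rmsd(a, moved)), 0, tolerance = 1e-9)

  bad <- structure3d(c("C", "C", "N", "N", "O", "O"), xyz)
  expect_error(ligand_heavy_rmsd(a, bad), "element multisets differ")
})

test_that("like-element matching attains the exhaustive-permutation optimum", {
  set.seed(55)
  el <- c("C", "C", "C", "N", "O", "O")
  for (rep in 1:8) {
    xa <- matrix(rnorm(18, sd = 2), ncol = 3)
    xb <- xa[sample(6), , drop = FALSE] + matrix(rnorm(18, sd = 0.3), ncol = 3)
    # note: the permutation above scrambles coordinates but not
    # elements, so the element multiset is preserved
    a <- structure3d(el, xa); b <- structure3d(el, xb)
    got <- as.numeric(ligand_heavy_rmsd(a, b))
    oracle <- exhaustive_perm_rmsd(el, xa, xb)
    expect_equal(got, oracle, tolerance = 1e-6)
    # never worse than the identity assignment
    expect_lte(got, kabsch(a, b)$rmsd + 1e-9)
  }
})

test_that("hydrogens are excluded before ligand matching", {
  el <- c("C", "N", "O", "H", "H")
  xyz <- matrix(rnorm(15), ncol = 3)
  a <- structure3d(el, xyz)
  # different hydrogen positions must not affect the heavy-atom RMSD
  xyz2 <- xyz; xyz2[4:5, ] <- xyz2[4:5, ] + 10
  b <- structure3d(el, xyz2)
  expect_equal(as.numeric(ligand_heavy_rmsd(a, b)), 0, tolerance = 1e-9)
})
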