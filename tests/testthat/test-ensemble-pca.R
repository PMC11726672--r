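test_that("sequence identity counts matches and mismatch positions", {
  a <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  expect_equal(sequence_identity(a, a)$identity, 1)
  expect_length(sequence_identity(a, a)$mismatch_positions, 0)

  b <- a; substr(b, 37, 37) <- "W"
  r <- sequence_identity(a, b)
  expect_equal(r$identity, 0.99)
  expect_equal(r$mismatch_positions, 37)
  # restricted to a region not containing the substitution
  expect_equal(sequence_identity(a, b, region = c(50, 100))$identity, 1)
  expect_error(sequence_identity(a, b, region = c(10, 5)), "empty region")
  # numbering offset: residue numbers shift with start_a
  r2 <- sequence_identity(a, b, start_a = 66)
  expect_equal(r2$mismatch_positions, 37 + 65)
})

test_that("gapped positions are removed when building the ensemble", {
  s1 <- toy_protein(1:20); s2 <- toy_protein(c(1:10, 13:20))
  s3 <- toy_protein(2:20)
  ens <- align_ensemble(list(s1, s2, s3), method = "resno")
  expect_equal(ens$positions, c(2:10, 13:20))
  expect_equal(dim(ens$coords), c(17, 3, 3))
  expect_equal(ens$n_gap_positions, 3)
})

test_that("sequence-based alignment tolerates shifted numbering", {
  sim <- gen_structure_ensemble(4, n_positions = 30, n_structures = 4,
                                mode_sd = 1, noise_sigma = 0.01)
  st <- sim$structures
  st[[2]] <- renumber_offset(st[[2]], 250)  # numbering disagrees
  expect_error(align_ensemble(st, method = "resno"), "shared")
  ens <- align_ensemble(st, method = "sequence")
  expect_equal(dim(ens$coords)[1], 30)
})

test_that("invariant core finding keeps rigid positions, drops noisy ones", {
  # identical structures: everything is core
  s <- toy_protein(1:35)
  ens <- align_ensemble(list(s, s, s, s), method = "resno")
  core <- find_invariant_core(ens, volume_cutoff = 0.5, min_core = 10)
  expect_equal(core$core, 1:35)
  expect_true(all(core$volumes < 1e-12))

  # 20 rigid + 5 noisy (sigma = 3 A) positions
  sim <- gen_structure_ensemble(9, n_positions = 25, n_structures = 12,
                                mode_sd = 0.01, noise_sigma = 0.02)
  ens <- align_ensemble(sim$structures, method = "resno")
  set.seed(1)
  noisy <- 21:25
  for (j in seq_len(12)) {
    ens$coords[noisy, j, ] <- ens$coords[noisy, j, ] +
      matrix(rnorm(15, sd = 3), ncol = 3)
  }
  core <- find_invariant_core(ens, volume_cutoff = 0.5, min_core = 5)
  expect_setequal(core$core, 1:20)

  # rigid motion of a single input does not change the core
  ens2 <- ens
  R <- random_rotation()
  ens2$coords[, 3, ] <- sweep(ens2$coords[, 3, ] %*% R, 2, -c(30, -12, 5))
  core2 <- find_invariant_core(ens2, volume_cutoff = 0.5, min_core = 5)
  expect_equal(core2$core, core$core)

  expect_error(find_invariant_core(ens, min_core = 26), "min_core")
})

test_that("pairwise RMSD clustering recovers a planted two-group split", {
  sim <- gen_structure_ensemble(17, n_positions = 40, n_structures = 14,
                                mode_sd = 0.2,
                                group_offsets = list(c(0, 0, 0), c(5, 0, 0)),
                                noise_sigma = 0.2)
  ens <- superpose_ensemble(align_ensemble(sim$structures, sim$labels,
                                           method = "resno"))
  ct <- pairwise_rmsd_and_cluster(ens, k = 2)
  expect_true(all(ct$rmsd_matrix == t(ct$rmsd_matrix)))
  expect_true(all(diag(ct$rmsd_matrix) == 0))
  # perfect recovery up to label swap
  agree <- (ct$groups == ct$groups[1]) == (sim$truth$groups == sim$truth$groups[1])
  expect_true(all(agree))
  expect_error(pairwise_rmsd_and_cluster(ens, k = 15), "exceeds")
})

test_that("an all-identical ensemble clusters stably with a zero matrix", {
  s <- toy_protein(1:12)
  ens <- superpose_ensemble(align_ensemble(list(s, s, s), method = "resno"))
  ct <- pairwise_rmsd_and_cluster(ens, k = 2)
  expect_true(all(ct$rmsd_matrix == 0))
  expect_length(ct$groups, 3)
})

test_that("Cartesian PCA satisfies its spectral identities", {
  sim <- gen_structure_ensemble(23, n_positions = 20, n_structures = 15,
                                mode_sd = c(1.5, 0.7), noise_sigma = 0.05)
  ens <- superpose_ensemble(align_ensemble(sim$structures, method = "resno"))
  p <- pca_cartesian(ens)
  expect_length(p$eigenvalues, 3 * 20)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  expect_true(all(p$eigenvalues >= -1e-9))
  expect_equal(sum(p$variance_proportions), 1, tolerance = 1e-9)
  # trace identity: eigenvalue sum = total positional variance
  X <- t(apply(ens$coords, 2, function(x) as.numeric(t(x))))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(p$eigenvalues), sum(Xc^2) / (nrow(X) - 1),
               tolerance = 1e-6 * sum(p$eigenvalues))
  # full reconstruction of the centered coordinates from all scores
  expect_equal(p$projections %*% t(p$mode_vectors), Xc,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PCA proportions recover planted mode variances", {
  # single planted mode, no noise, alignment-free: PC1 carries everything
  sim1 <- gen_structure_ensemble(31, n_positions = 15, n_structures = 10,
                                 mode_sd = 2, noise_sigma = 0,
                                 rigid_motion = FALSE)
  ens1 <- align_ensemble(sim1$structures, method = "resno")
  ens1$superposed <- TRUE
  p1 <- pca_cartesian(ens1)
  expect_equal(p1$variance_proportions[1], 1, tolerance = 1e-6)

  # two modes with 4:1 variance at n = 50: proportions within 3%
  # absolute of the planted expected spectrum
  sim2 <- gen_structure_ensemble(37, n_positions = 50, n_structures = 50,
                                 mode_sd = c(2, 1), noise_sigma = 0.05)
  ens2 <- superpose_ensemble(align_ensemble(sim2$structures, method = "resno"))
  p2 <- pca_cartesian(ens2)
  truth <- sim2$truth$realized_variance_fractions
  expect_lt(abs(p2$variance_proportions[1] - truth[1]), 0.03)
  expect_lt(abs(p2$variance_proportions[2] - truth[2]), 0.03)
  # and the expected 4:1 shape survives in the leading eigenvalues
  expect_equal(p2$eigenvalues[1] / p2$eigenvalues[2], 4, tolerance = 0.35)

  # identical structures: degenerate flag, no NaN proportions
  s <- toy_protein(1:10)
  pd <- pca_cartesian(superpose_ensemble(align_ensemble(list(s, s, s),
                                                        method = "resno")))
  expect_true(pd$degenerate)
  expect_true(all(is.na(pd$variance_proportions)))
  expect_false(any(is.nan(pd$variance_proportions)))
})

test_that("PCA results are invariant to input order and rigid motions", {
  sim <- gen_structure_ensemble(41, n_positions = 20, n_structures = 12,
                                mode_sd = c(2, 1), noise_sigma = 0.05)
  ens <- superpose_ensemble(align_ensemble(sim$structures, sim$labels,
                                           method = "resno"))
  p <- pca_cartesian(ens)
  ct <- pairwise_rmsd_and_cluster(ens, k = 2)

  ord <- rev(seq_along(sim$structures))
  st2 <- sim$structures[ord]
  # push one structure through an extra rigid motion
  R <- random_rotation()
  coords(st2[[3]]) <- sweep(coords(st2[[3]]) %*% R, 2, -c(8, -3, 11))
  ens2 <- superpose_ensemble(align_ensemble(st2, sim$labels[ord],
                                            method = "resno"))
  p2 <- pca_cartesian(ens2)
  expect_equal(p2$variance_proportions[1:5], p$variance_proportions[1:5],
               tolerance = 1e-6)
  ct2 <- pairwise_rmsd_and_cluster(ens2, k = 2)
  # same partition of the labels, up to group relabelling
  part <- function(g) unname(lapply(split(names(g), g), sort))
  expect_setequal(part(ct2$groups), part(ct$groups))
})

test_that("planted two-group ensembles separate along PC1", {
  sim <- gen_structure_ensemble(53, n_positions = 40, n_structures = 20,
                                mode_sd = 0.3,
                                group_offsets = list(c(0, 0, 0), c(5, 0, 0)),
                                noise_sigma = 0.2)
  ens <- superpose_ensemble(align_ensemble(sim$structures, method = "resno"))
  p <- pca_cartesian(ens)
  s1 <- p$projections[sim$truth$groups == 1, 1]
  s2 <- p$projections[sim$truth$groups == 2, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("mode trajectories sweep the mean along the chosen component", {
  sim <- gen_structure_ensemble(61, n_positions = 12, n_structures = 8,
                                mode_sd = c(1.5, 0.5), noise_sigma = 0.02)
  ens <- superpose_ensemble(align_ensemble(sim$structures, method = "resno"))
  p <- pca_cartesian(ens)

  still <- export_mode_trajectory(p, 1, amplitude = 0, n_frames = 5)
  for (fr in still) expect_equal(coords(fr), p$mean_coords, tolerance = 1e-12,
                                 ignore_attr = TRUE)

  traj <- export_mode_trajectory(p, 1, amplitude = 3, n_frames = 7)
  d <- as.numeric(t(coords(traj[[7]]) - coords(traj[[1]])))
  expect_equal(sqrt(sum(d^2)), 2 * 3, tolerance = 1e-9)
  expect_equal(abs(sum(d / sqrt(sum(d^2)) * p$mode_vectors[, 1])), 1,
               tolerance = 1e-9)

  # PCA of the exported trajectory recovers the mode direction
  ens_t <- align_ensemble(traj, method = "resno")
  ens_t$superposed <- TRUE  # frames are already in the mean frame
  p_t <- pca_cartesian(ens_t)
  expect_gt(abs(sum(p_t$mode_vectors[, 1] * p$mode_vectors[, 1])), 0.999)

  expect_error(export_mode_trajectory(p, 9999, 1), "out of range")
})
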