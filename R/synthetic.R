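#' Generate a synthetic conformer ensemble with planted truths
#'
#' Emulates the per-conformer tables produced by a conformational
#' search followed by frequency and correlated-energy calculations:
#' each unique conformer gets harmonic frequencies, rotational
#' constants, and DZ/TZ/QZ electronic energies generated exactly from a
#' planted inverse-polynomial basis-set limit chosen so that the
#' assembled Gibbs free energies reproduce a requested relative-energy
#' spectrum. Duplicate records jitter rotational constants by at most
#' 0.5\% and energies upward by at most 0.05 kcal/mol around their
#' group head, i.e. safely inside the 1\%/0.1 kcal/mol uniqueness
#' tolerances while leaving the head the lowest-energy member.
#'
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @param n_unique number of distinct conformers.
#' @param n_dup_per_group records per duplicate group (1 = no
#'   duplicates).
#' @param dg_spectrum planted relative Gibbs energies, kcal/mol
#'   (length \code{n_unique}; first value need not be 0).
#' @param cbs_truth optional list of \code{c(e_cbs, a, b)} per
#'   conformer; random when NULL.
#' @param mass_u molecular mass (default 336.47, a fentanyl-like
#'   ligand).
#' @param n_modes harmonic modes per conformer.
#' @param temperature,scale conditions under which the planted spectrum
#'   holds (defaults 310.15 K and 0.971, the analysis defaults).
#' @return list: \code{table} (an \code{energy_table}) and
#'   \code{truth} (planted ids, group map, relative energies,
#'   populations at \code{temperature}, CBS coefficients).
#' @export
gen_conformer_ensemble <- function(seed, n_unique, n_dup_per_group = 1,
                                   dg_spectrum = NULL, cbs_truth = NULL,
                                   mass_u = 336.47, n_modes = 12,
                                   temperature = 310.15, scale = 0.971) {
  if (n_unique < 1 || n_dup_per_group < 1) stop("counts must be positive")
  if (is.null(dg_spectrum)) dg_spectrum <- seq(0, by = 0.75, length.out = n_unique)
  if (length(dg_spectrum) != n_unique) {
    stop("dg_spectrum length must equal n_unique")
  }
  set.seed(seed)
  pc <- physical_constants
  rows <- list(); truth_cbs <- list()
  # well-separated rotational-constant triples (> 2% apart across
  # conformers so only planted duplicates can merge)
  base_rc <- lapply(seq_len(n_unique), function(i) {
    sort(stats::runif(3, 0.4, 4.0) * (1 + 0.05 * i), decreasing = TRUE)
  })
  for (i in seq_len(n_unique)) {
    freqs <- sort(stats::runif(n_modes, 80, 3400))
    rc <- base_rc[[i]]
    tc <- rrho_corrections(freqs, rc, mass_u, temperature = temperature,
                           scale = scale)
    if (is.null(cbs_truth)) {
      ab <- c(stats::runif(1, 0.5, 2), stats::runif(1, 0.2, 1))
      # pick the basis-set limit so the assembled G hits the spectrum
      e_cbs <- (-250000 + dg_spectrum[i] - tc$g_corr) / pc$hartree_to_kcal
      ct <- c(e_cbs, ab)
    } else ct <- cbs_truth[[i]]
    truth_cbs[[i]] <- ct
    e_n <- ct[1] + ct[2] * (2:4)^-4 + ct[3] * (2:4)^-5
    for (d in seq_len(n_dup_per_group)) {
      if (d == 1) {
        rc_d <- rc; shift <- 0
      } else {
        rc_d <- rc * (1 + stats::runif(3, -0.005, 0.005))
        shift <- stats::runif(1, 0.005, 0.05) / pc$hartree_to_kcal
      }
      rows[[length(rows) + 1]] <- list(
        conformer_id = sprintf("c%02d_%02d", i, d),
        group = i, is_head = d == 1,
        e_dz = e_n[1] + shift, e_tz = e_n[2] + shift, e_qz = e_n[3] + shift,
        freqs = freqs, rotconst = rc_d)
    }
  }
  tab <- data.frame(
    conformer_id = vapply(rows, `[[`, "", "conformer_id"),
    e_dz = vapply(rows, `[[`, 0, "e_dz"),
    e_tz = vapply(rows, `[[`, 0, "e_tz"),
    e_qz = vapply(rows, `[[`, 0, "e_qz"),
    stringsAsFactors = FALSE)
  tab$freqs <- lapply(rows, `[[`, "freqs")
  tab$rotconst <- lapply(rows, `[[`, "rotconst")
  tab$mass_u <- mass_u
  tab$cbs_eligible <- TRUE
  class(tab) <- c("energy_table", "data.frame")
  pops <- boltzmann_populations(dg_spectrum, temperature = temperature,
                                ids = sprintf("c%02d_01", seq_len(n_unique)))
  truth <- list(
    seed = seed, kind = "conformer_ensemble",
    n_unique = n_unique, n_dup_per_group = n_dup_per_group,
    head_ids = sprintf("c%02d_01", seq_len(n_unique)),
    group = vapply(rows, `[[`, 0, "group"),
    dg_spectrum = dg_spectrum,
    populations = pops,
    cbs = truth_cbs,
    temperature = temperature, scale = scale, mass_u = mass_u)
  list(table = tab, truth = truth)
}

#' Generate a synthetic C-alpha structure ensemble with planted modes
#'
#' Builds a smooth helical template, adds a small number of orthonormal
#' collective displacement modes with chosen standard deviations, an
#' optional rigid sub-domain offset per group (mimicking, e.g., an
#' outward helix swing separating active from inactive states), and
#' isotropic Gaussian coordinate noise. Each structure is additionally
#' given a random rigid motion, which downstream superposition must
#' remove.
#'
#' @param seed integer RNG seed.
#' @param n_positions C-alpha count per structure.
#' @param n_structures ensemble size.
#' @param mode_sd standard deviations (A) of the planted mode scores;
#'   one mode per entry.
#' @param group_offsets list of 3-vectors (A), one rigid sub-domain
#'   shift per group; \code{NULL} for a single group.
#' @param subdomain_fraction fraction of trailing positions forming the
#'   shifted sub-domain.
#' @param noise_sigma isotropic coordinate noise, A.
#' @param rigid_motion give every member a random rigid motion that
#'   downstream superposition must remove (default TRUE; disable for
#'   alignment-free constructions).
#' @return list: \code{structures} (list of C-alpha
#'   \code{structure3d}), \code{labels}, and \code{truth} (modes,
#'   scores, group labels, planted variance fractions, template). The
#'   planted \code{variance_fractions} are the expected eigenvalue
#'   proportions of the generative model, i.e. each mode variance over
#'   the total including the isotropic noise floor 3 n_positions
#'   noise_sigma^2; \code{realized_variance_fractions} use the sample
#'   variances of the scores and noise actually drawn, which is what a
#'   correct estimator should report for one finite ensemble.
#' @export
gen_structure_ensemble <- function(seed, n_positions = 50, n_structures = 50,
                                   mode_sd = c(2, 1), group_offsets = NULL,
                                   subdomain_fraction = 0.3,
                                   noise_sigma = 0.05, rigid_motion = TRUE) {
  set.seed(seed)
  if (n_positions < 3) stop("degenerate template: need >= 3 positions")
  t <- seq_len(n_positions)
  template <- cbind(2.3 * cos(t / 1.8), 2.3 * sin(t / 1.8), 1.5 * t)
  k <- length(mode_sd)
  # modes are drawn orthogonal to the template's rigid-body subspace
  # (3 translations + 3 infinitesimal rotations) so that planted
  # collective displacements are not absorbed by superposition
  ctr <- sweep(template, 2, colMeans(template))
  rigid <- cbind(
    as.numeric(t(matrix(rep(c(1, 0, 0), n_positions), ncol = 3, byrow = TRUE))),
    as.numeric(t(matrix(rep(c(0, 1, 0), n_positions), ncol = 3, byrow = TRUE))),
    as.numeric(t(matrix(rep(c(0, 0, 1), n_positions), ncol = 3, byrow = TRUE))),
    as.numeric(t(cbind(0, -ctr[, 3], ctr[, 2]))),
    as.numeric(t(cbind(ctr[, 3], 0, -ctr[, 1]))),
    as.numeric(t(cbind(-ctr[, 2], ctr[, 1], 0))))
  raw <- matrix(stats::rnorm(3 * n_positions * k), ncol = k)
  modes <- qr.Q(qr(cbind(rigid, raw)))[, 6 + seq_len(k), drop = FALSE]
  scores <- matrix(stats::rnorm(n_structures * k), ncol = k) %*% diag(mode_sd, k)
  noise_mat <- matrix(stats::rnorm(n_structures * 3 * n_positions,
                                   sd = noise_sigma), nrow = n_structures)
  n_groups <- if (is.null(group_offsets)) 1L else length(group_offsets)
  groups <- rep(seq_len(n_groups), length.out = n_structures)
  sub_idx <- if (n_groups > 1) {
    seq.int(floor(n_positions * (1 - subdomain_fraction)) + 1, n_positions)
  } else integer(0)
  structures <- vector("list", n_structures)
  for (j in seq_len(n_structures)) {
    disp <- matrix(modes %*% scores[j, ], ncol = 3, byrow = TRUE)
    xyz <- template + disp
    if (n_groups > 1) {
      xyz[sub_idx, ] <- sweep(xyz[sub_idx, , drop = FALSE], 2,
                              -group_offsets[[groups[j]]])
    }
    xyz <- xyz + matrix(noise_mat[j, ], ncol = 3, byrow = TRUE)
    if (rigid_motion) {
      R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      xyz <- sweep(xyz %*% R, 2, -stats::runif(3, -20, 20))
    }
    structures[[j]] <- structure3d(
      rep("C", n_positions), xyz, name = "CA", resid = "ALA",
      resno = t, title = sprintf("synthetic member %d", j))
  }
  labels <- sprintf("synth_%02d", seq_len(n_structures))
  mode_var <- mode_sd^2
  noise_var <- 3 * n_positions * noise_sigma^2
  # realized spectrum: sample variances of the scores actually drawn
  # plus the realized noise floor (meaningful when group_offsets are
  # absent; offsets contribute variance not accounted for here)
  realized_mode_var <- apply(scores, 2, stats::var)
  realized_noise_var <- sum(apply(noise_mat, 2, stats::var))
  truth <- list(
    seed = seed, kind = "structure_ensemble",
    n_positions = n_positions, n_structures = n_structures,
    modes = modes, scores = scores, groups = groups,
    variance_fractions = mode_var / (sum(mode_var) + noise_var),
    realized_variance_fractions =
      realized_mode_var / (sum(realized_mode_var) + realized_noise_var),
    noise_sigma = noise_sigma, template = template,
    subdomain = sub_idx)
  list(structures = structures, labels = labels, truth = truth)
}

#' Generate a synthetic pKa thermodynamic cycle with a planted answer
#'
#' Samples plausible component free energies, then adjusts the
#' solvation free energy of the acid so the cycle closes exactly on
#' the requested pKa.
#'
#' @param seed integer RNG seed.
#' @param target_pka the planted pKa.
#' @param temperature temperature in K.
#' @return list: \code{cycle} (a \code{\link{pka_cycle}}) and
#'   \code{truth} (target pKa and the implied aqueous dissociation
#'   free energy).
#' @export
gen_pka_inputs <- function(seed, target_pka = 9.2, temperature = 310.15) {
  stopifnot(temperature > 0)
  set.seed(seed)
  pc <- physical_constants
  dg_target <- target_pka * pc$R_kcal * temperature * log(10)
  g_gas_ha <- stats::runif(1, -9e5, -8e5)
  g_gas_a <- g_gas_ha + stats::runif(1, 150, 250)  # deprotonation costs
  dg_sol_a <- stats::runif(1, -20, -5)
  g_gas_h <- proton_gas_free_energy(temperature)
  dg_sol_h <- -265.6
  # close the cycle on the target
  dg_sol_ha <- (g_gas_a + g_gas_h - g_gas_ha) + dg_sol_a + dg_sol_h - dg_target
  cyc <- pka_cycle(g_gas_ha = g_gas_ha, g_gas_a = g_gas_a,
                   dg_sol_ha = dg_sol_ha, dg_sol_a = dg_sol_a,
                   dg_sol_h = dg_sol_h, g_gas_h = g_gas_h,
                   temperature = temperature)
  list(cycle = cyc,
       truth = list(seed = seed, kind = "pka_cycle",
                    target_pka = target_pka, dg_aq = dg_target,
                    temperature = temperature))
}

#' Write a generator truth record as a JSON sidecar
#'
#' @param truth a truth list from one of the generators.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_truth_json <- function(truth, path) {
  truth <- lapply(truth, function(x) {
    if (is.matrix(x)) unclass(as.data.frame(x)) else if (is.data.frame(x)) unclass(x) else x
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
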