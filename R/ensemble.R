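#' Global sequence identity over a residue interval
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap -1 via
#' \code{Biostrings::pairwiseAlignment}) of two one-letter amino-acid
#' sequences, then identity = matches / aligned columns restricted to a
#' residue interval in the first sequence's numbering.
#'
#' @param a,b one-letter amino-acid strings.
#' @param region inclusive residue interval \code{c(start, end)} in
#'   \code{a}'s numbering, or \code{NULL} for the full alignment.
#' @param start_a,start_b residue number of the first character of each
#'   sequence (default 1).
#' @return list: \code{identity} (fraction), \code{n_matches},
#'   \code{n_columns}, \code{mismatch_positions} (residue numbers in
#'   \code{a}'s numbering where aligned residues differ).
#' @export
sequence_identity <- function(a, b, region = NULL, start_a = 1L, start_b = 1L) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (!is.null(region)) {
    stopifnot(length(region) == 2)
    if (region[2] < region[1]) stop("empty region")
  }
  alpha <- unique(c(strsplit(paste0(a, b), "")[[1]], "X"))
  subst <- matrix(0, length(alpha), length(alpha),
                  dimnames = list(alpha, alpha))
  diag(subst) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = subst,
    gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  resno_a <- cumsum(pa != "-") + start_a - 1L
  in_region <- if (is.null(region)) rep(TRUE, length(pa)) else {
    pa != "-" & resno_a >= region[1] & resno_a <= region[2]
  }
  if (!any(in_region)) stop("empty region: no aligned columns fall in it")
  match_col <- pa == pb & pa != "-"
  mism <- in_region & pa != "-" & pb != "-" & pa != pb
  list(identity = sum(match_col & in_region) / sum(in_region),
       n_matches = sum(match_col & in_region),
       n_columns = sum(in_region),
       mismatch_positions = resno_a[mism])
}

# one-letter sequence of a C-alpha structure
ca_sequence <- function(s) {
  paste(bio3d::aa321(s$atoms$resid), collapse = "")
}

#' Build a gap-free aligned C-alpha ensemble
#'
#' Maps every structure onto a common set of positions and keeps only
#' positions present in all structures (gaps removed). With
#' \code{method = "resno"} residues are matched by residue number
#' (appropriate once structures share a numbering); with
#' \code{method = "sequence"} each structure is aligned progressively
#' against the first by global sequence alignment, which tolerates
#' differing numbering at high identity.
#'
#' @param structures list of \code{structure3d}; non-C-alpha atoms are
#'   dropped (structures with no atom named CA, e.g. XYZ point sets,
#'   are used as-is, one position per atom).
#' @param labels structure labels (e.g. "8EF5_R").
#' @param method \code{"resno"} or \code{"sequence"}.
#' @return an \code{aligned_ensemble}: \code{coords} (n_positions x
#'   n_structures x 3 array), \code{positions} (reference residue
#'   numbers), \code{labels}, \code{n_gap_positions}.
#' @export
align_ensemble <- function(structures, labels = NULL,
                           method = c("resno", "sequence")) {
  method <- match.arg(method)
  if (length(structures) < 2) stop("need at least 2 structures")
  if (is.null(labels)) labels <- sprintf("structure_%02d", seq_along(structures))
  cas <- lapply(structures, function(s) {
    if (any(s$atoms$name == "CA")) s <- select_atoms(s, "calpha")
    # bare point sets (e.g. XYZ frames) carry no numbering: index them
    if (nrow(s$atoms) > 1 && length(unique(s$atoms$resno)) == 1) {
      s$atoms$resno <- seq_len(nrow(s$atoms))
    }
    s
  })
  for (s in cas) if (anyDuplicated(s$atoms$resno)) {
    stop("duplicated C-alpha residue numbers within one chain")
  }
  if (method == "resno") {
    resnos <- lapply(cas, function(s) s$atoms$resno)
    common <- Reduce(intersect, resnos)
    if (length(common) < 3) stop("fewer than 3 positions shared by all structures")
    common <- sort(common)
    n_gap <- length(unique(unlist(resnos))) - length(common)
    coords_arr <- array(NA_real_, c(length(common), length(cas), 3))
    for (j in seq_along(cas)) {
      idx <- match(common, resnos[[j]])
      coords_arr[, j, ] <- coords(cas[[j]])[idx, ]
    }
    positions <- common
  } else {
    ref <- cas[[1]]
    ref_n <- nrow(ref$atoms)
    # map[i, j] = row of structure j aligned to reference position i
    map <- matrix(NA_integer_, ref_n, length(cas))
    map[, 1] <- seq_len(ref_n)
    ref_seq <- ca_sequence(ref)
    alpha <- c(LETTERS, "-")
    subst <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS)); diag(subst) <- 1
    for (j in seq_along(cas)[-1]) {
      sj <- ca_sequence(cas[[j]])
      aln <- Biostrings::pairwiseAlignment(
        ref_seq, sj, type = "global", substitutionMatrix = subst,
        gapOpening = 0, gapExtension = 1)
      pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
      both <- pa != "-" & pb != "-"
      map[ia[both], j] <- ib[both]
    }
    keep <- rowSums(is.na(map)) == 0
    if (sum(keep) < 3) stop("fewer than 3 positions shared by all structures")
    n_gap <- sum(!keep)
    coords_arr <- array(NA_real_, c(sum(keep), length(cas), 3))
    for (j in seq_along(cas)) {
      coords_arr[, j, ] <- coords(cas[[j]])[map[keep, j], ]
    }
    positions <- ref$atoms$resno[keep]
  }
  out <- list(coords = coords_arr, positions = positions,
              labels = labels, n_gap_positions = n_gap,
              superposed = FALSE, core = NULL)
  class(out) <- "aligned_ensemble"
  out
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat("aligned_ensemble:", dim(x$coords)[2], "structures x",
      dim(x$coords)[1], "gap-free C-alpha positions",
      sprintf("(%d gap positions removed)\n", x$n_gap_positions))
  if (x$superposed) {
    cat("  superposed on", if (is.null(x$core)) "all positions" else
        paste(length(x$core), "core positions"), "\n")
  }
  invisible(x)
}

#' Superpose all ensemble members onto a common frame
#'
#' Fits every structure onto the first, then iteratively re-fits onto
#' the ensemble mean until the mean stabilises. The fit uses the
#' positions in \code{core} (default: all positions).
#'
#' @param ens an \code{aligned_ensemble}.
#' @param core integer position indices to fit on, or \code{NULL}.
#' @param max_iter mean-refit iterations.
#' @return the ensemble with superposed coordinates.
#' @export
superpose_ensemble <- function(ens, core = NULL, max_iter = 10) {
  stopifnot(inherits(ens, "aligned_ensemble"))
  idx <- if (is.null(core)) seq_len(dim(ens$coords)[1]) else core
  if (length(idx) < 3) stop("need at least 3 fit positions")
  x <- ens$coords
  ref <- x[, 1, ]
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(dim(x)[2])) {
      sup <- kabsch(x[, j, ][idx, , drop = FALSE], ref[idx, , drop = FALSE])
      x[, j, ] <- sup$transform(x[, j, ])
    }
    new_ref <- apply(x, c(1, 3), mean)
    if (max(abs(new_ref - ref)) < 1e-8) { ref <- new_ref; break }
    ref <- new_ref
  }
  ens$coords <- x
  ens$superposed <- TRUE
  ens$core <- core
  ens
}

#' Detect the structural invariant core of an ensemble
#'
#' Iteratively superposes the ensemble on the current candidate core,
#' scores every position by the volume of its positional variance
#' ellipsoid across structures, and drops the worst position until all
#' remaining volumes fall below \code{volume_cutoff} or only
#' \code{min_core} positions remain. Deterministic; rigid motions of
#' individual inputs do not change the result.
#'
#' @param ens an \code{aligned_ensemble}.
#' @param volume_cutoff maximum tolerated ellipsoid volume per core
#'   position, Angstrom^3 (default 0.5).
#' @param min_core minimum core size (default 30).
#' @return list: \code{core} (position indices into the ensemble),
#'   \code{volumes} (final per-position volumes over all positions),
#'   \code{positions} (residue numbers of the core).
#' @export
find_invariant_core <- function(ens, volume_cutoff = 0.5, min_core = 30) {
  stopifnot(inherits(ens, "aligned_ensemble"))
  n_pos <- dim(ens$coords)[1]
  if (dim(ens$coords)[2] < 3) stop("need at least 3 structures")
  if (n_pos < min_core) {
    stop("only ", n_pos, " common positions but min_core = ", min_core)
  }
  core <- seq_len(n_pos)
  repeat {
    sup <- superpose_ensemble(ens, core = core)
    vols <- position_volumes(sup)
    if (max(vols[core]) <= volume_cutoff || length(core) <= min_core) {
      return(list(core = core, volumes = vols,
                  positions = ens$positions[core]))
    }
    core <- core[-which.max(vols[core])]
  }
}

# volume of the variance ellipsoid (4/3 pi sqrt(det covariance)) of
# each position across structures
position_volumes <- function(ens) {
  apply(ens$coords, 1, function(p) {
    cv <- stats::cov(p)  # p: n_structures x 3
    d <- det(cv)
    4 / 3 * pi * sqrt(max(d, 0))
  })
}

#' Pairwise C-alpha RMSD matrix and hierarchical clustering
#'
#' All-pairs RMSD over the superposed coordinates (no per-pair refit by
#' default), agglomerative clustering with complete linkage, and a cut
#' into \code{k} groups.
#'
#' @param ens a superposed \code{aligned_ensemble}.
#' @param k number of groups.
#' @param refit_pairs superpose each pair before its RMSD.
#' @param linkage linkage passed to \code{\link[stats]{hclust}}
#'   (default \code{"complete"}).
#' @return a \code{cluster_tree} list: \code{rmsd_matrix},
#'   \code{hclust}, \code{groups} (named integer vector), \code{k}.
#' @export
pairwise_rmsd_and_cluster <- function(ens, k, refit_pairs = FALSE,
                                      linkage = "complete") {
  stopifnot(inherits(ens, "aligned_ensemble"))
  if (!ens$superposed) ens <- superpose_ensemble(ens)
  n <- dim(ens$coords)[2]
  if (k > n) stop("k = ", k, " exceeds the ", n, " structures")
  m <- matrix(0, n, n, dimnames = list(ens$labels, ens$labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- if (refit_pairs) {
      kabsch(ens$coords[, i, ], ens$coords[, j, ])$rmsd
    } else {
      rmsd_fixed(ens$coords[, i, ], ens$coords[, j, ])
    }
  }
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  groups <- stats::cutree(hc, k = k)
  out <- list(rmsd_matrix = m, hclust = hc, groups = groups, k = k)
  class(out) <- "cluster_tree"
  out
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", nrow(x$rmsd_matrix), "structures in", x$k, "groups\n")
  print(split(names(x$groups), x$groups))
  invisible(x)
}

#' Write a clustering dendrogram as Newick
#'
#' @param ct a \code{cluster_tree}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_dendrogram_newick <- function(ct, path) {
  stopifnot(inherits(ct, "cluster_tree"))
  phy <- ape::as.phylo(ct$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
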