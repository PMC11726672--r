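#' Screen a conformer ensemble for uniqueness
#'
#' Two conformers are deemed identical when their rotational constants
#' and energies are within 1\% and 0.1 kcal/mol of one another: all
#' three descending-sorted rotational constants must agree within
#' \code{rel_tol} (relative) \emph{and} the comparison energies within
#' \code{e_tol}. Records are processed in ascending energy order and
#' compared greedily against the already-kept set, so each duplicate
#' group is represented by its lowest-energy member (pairwise similarity
#' is not transitive, so the greedy order is part of the definition).
#'
#' @param et an \code{energy_table} (see \code{\link{read_energy_table}}).
#' @param rel_tol relative tolerance on each rotational constant
#'   (default 0.01).
#' @param e_tol energy tolerance in kcal/mol (default 0.1).
#' @param energy_col which electronic-energy column to screen on; by
#'   default the best available of \code{e_dft}, \code{e_qz},
#'   \code{e_tz}, \code{e_dz}.
#' @return a list with \code{unique} (the kept \code{energy_table},
#'   ascending energy) and \code{duplicate_map} (data.frame
#'   \code{conformer_id}, \code{duplicate_of}).
#' @export
dedup_conformers <- function(et, rel_tol = 0.01, e_tol = 0.1,
                             energy_col = NULL) {
  stopifnot(inherits(et, "data.frame"), rel_tol > 0, e_tol > 0)
  if (is.null(energy_col)) {
    energy_col <- intersect(c("e_dft", "e_qz", "e_tz", "e_dz"), names(et))[1]
    if (is.na(energy_col)) stop("no electronic-energy column found")
  }
  e <- et[[energy_col]]
  if (is.null(e)) stop("energy column '", energy_col, "' not found")
  if (anyNA(e)) {
    stop("missing '", energy_col, "' for conformer(s): ",
         paste(et$conformer_id[is.na(e)], collapse = ", "))
  }
  no_rc <- vapply(et$rotconst, length, 1L) != 3L
  if (any(no_rc)) {
    stop("missing rotational constants for conformer(s): ",
         paste(et$conformer_id[no_rc], collapse = ", "))
  }
  ord <- order(e)
  et <- et[ord, , drop = FALSE]
  e_kcal <- et[[energy_col]] * physical_constants$hartree_to_kcal
  rc <- t(vapply(et$rotconst, function(v) sort(v, decreasing = TRUE), numeric(3)))

  kept <- integer(0)
  dup_of <- character(0); dup_id <- character(0)
  for (i in seq_len(nrow(et))) {
    match_j <- 0L
    for (j in kept) {
      same_rc <- all(abs(rc[i, ] - rc[j, ]) <= rel_tol * abs(rc[j, ]))
      same_e <- abs(e_kcal[i] - e_kcal[j]) <= e_tol
      if (same_rc && same_e) { match_j <- j; break }
    }
    if (match_j > 0L) {
      dup_id <- c(dup_id, et$conformer_id[i])
      dup_of <- c(dup_of, et$conformer_id[match_j])
    } else {
      kept <- c(kept, i)
    }
  }
  uniq <- et[kept, , drop = FALSE]
  rownames(uniq) <- NULL
  class(uniq) <- class(et)
  list(unique = uniq,
       duplicate_map = data.frame(conformer_id = dup_id,
                                  duplicate_of = dup_of,
                                  stringsAsFactors = FALSE))
}
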