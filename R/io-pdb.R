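#' Read one chain of a PDB file into a structure
#'
#' Wraps \code{bio3d::read.pdb}. Only the first MODEL is used; alternate
#' locations other than blank or "A" are discarded; residues bearing
#' insertion codes are rejected (none occur in the transmembrane ranges
#' of the receptor structures this package targets).
#'
#' @param path PDB file path.
#' @param chain single chain identifier.
#' @param selection atom selection, see \code{\link{select_atoms}}.
#' @param hetatm if \code{TRUE}, read HETATM records instead of ATOM
#'   records (ligand extraction); default \code{FALSE}.
#' @return a \code{\link{structure3d}}.
#' @export
read_pdb_chain <- function(path, chain,
                           selection = c("all", "backbone", "calpha", "heavy"),
                           hetatm = FALSE) {
  selection <- match.arg(selection)
  # bio3d warns about repeated serial numbers across MODEL blocks,
  # which is standard in multi-model files
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == if (hetatm) "HETATM" else "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ", if (hetatm) "HETATM" else "ATOM",
                      " records in '", path, "'")
  avail <- unique(at$chain)
  if (!chain %in% avail) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ins <- !(is.na(at$insert) | at$insert == "")
  if (any(ins)) {
    stop("residue(s) with insertion codes are not supported: ",
         paste(unique(paste0(at$resno[ins], at$insert[ins])), collapse = ", "))
  }
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el)))) {
    el <- substr(trimws(at$elety), 1, 1)  # fall back to first letter of atom name
  } else {
    miss <- is.na(el) | !nzchar(trimws(el))
    el[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  }
  s <- structure3d(el, cbind(at$x, at$y, at$z),
                   name = trimws(at$elety), resid = at$resid,
                   resno = at$resno, chain = at$chain,
                   title = basename(path))
  select_atoms(s, selection)
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of one-letter sequences.
#' @export
read_fasta_seqs <- function(path) {
  aln <- bio3d::read.fasta(path, rm.dup = FALSE)
  seqs <- apply(aln$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  stats::setNames(toupper(seqs), aln$id)
}
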