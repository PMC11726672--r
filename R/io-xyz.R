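#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' \code{element x y z} line per atom; frames may be concatenated.
#'
#' @param path file path.
#' @return a list of \code{\link{structure3d}} objects, one per frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop("malformed atom-count line at line ", i, ": '", lines[i], "'")
    }
    if (i + 1L + n > length(lines)) {
      stop("frame starting at line ", i, " declares ", n,
           " atoms but the file ends early")
    }
    title <- lines[i + 1L]
    rec <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rec), "\\s+")
    bad <- which(vapply(tok, length, 1L) < 4L)
    if (length(bad)) {
      stop("malformed coordinate line at line ", i + 1L + bad[1], ": '",
           rec[bad[1]], "'")
    }
    el <- vapply(tok, `[[`, "", 1L)
    if (!all(is_known_element(el))) {
      stop("unknown element at line ",
           i + 1L + which(!is_known_element(el))[1])
    }
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (!all(is.finite(xyz))) {
      stop("non-numeric coordinate in frame starting at line ", i)
    }
    frames[[length(frames) + 1L]] <- structure3d(el, xyz, title = title)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in '", path, "'")
  frames
}

#' Write structures to a (multi-frame) XYZ file
#'
#' @param structures a \code{structure3d} or list of them.
#' @param path output file path.
#' @param digits coordinate precision (decimal places).
#' @return invisibly, the path.
#' @export
write_xyz <- function(structures, path, digits = 8) {
  if (inherits(structures, "structure3d")) structures <- list(structures)
  out <- unlist(lapply(structures, function(s) {
    xyz <- coords(s)
    c(sprintf("%d", n_atoms(s)),
      s$title,
      sprintf(paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f"),
              s$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}
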