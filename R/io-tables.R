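#' Read a per-conformer energy/frequency table
#'
#' The table is delimited text (comma or tab, auto-detected from the
#' header) with columns \code{conformer_id}, one or more electronic
#' energy columns in hartree (\code{e_dz_hartree}, \code{e_tz_hartree},
#' \code{e_qz_hartree}, \code{e_dft_hartree}), and optionally
#' \code{freqs_cm1} (semicolon-joined harmonic frequencies, negative
#' values marking imaginary modes), \code{rotconst_ghz} (three
#' semicolon-joined rotational constants) and \code{mass_u}.
#'
#' A row with an empty cell in one of the DZ/TZ/QZ columns is kept but
#' flagged ineligible for basis-set extrapolation (\code{cbs_eligible}).
#'
#' @param path file path.
#' @return an \code{energy_table}: a data.frame with list-columns
#'   \code{freqs} and \code{rotconst}.
#' @export
read_energy_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE, quote = "\"")
  if (!"conformer_id" %in% names(df)) stop("missing required column: conformer_id")
  e_cols <- intersect(c("e_dz_hartree", "e_tz_hartree", "e_qz_hartree",
                        "e_dft_hartree"), names(df))
  if (!length(e_cols)) {
    stop("missing required column: at least one of e_dz_hartree, ",
         "e_tz_hartree, e_qz_hartree, e_dft_hartree")
  }
  if (anyDuplicated(df$conformer_id)) {
    stop("duplicated conformer_id: ",
         paste(unique(df$conformer_id[duplicated(df$conformer_id)]), collapse = ", "))
  }
  num <- function(x, col) {
    blank <- is.na(x) | !nzchar(trimws(x))
    v <- suppressWarnings(as.numeric(x))
    bad <- !blank & is.na(v)
    if (any(bad)) {
      stop("non-numeric value in column '", col, "' for conformer '",
           df$conformer_id[which(bad)[1]], "'")
    }
    v
  }
  out <- data.frame(conformer_id = trimws(df$conformer_id),
                    stringsAsFactors = FALSE)
  for (col in e_cols) {
    out[[sub("_hartree$", "", col)]] <- num(df[[col]], col)
  }
  split_num <- function(x, col) {
    lapply(seq_along(x), function(i) {
      if (is.na(x[i]) || !nzchar(trimws(x[i]))) return(numeric(0))
      v <- suppressWarnings(as.numeric(strsplit(trimws(x[i]), ";")[[1]]))
      if (anyNA(v)) stop("non-numeric value in column '", col,
                         "' for conformer '", out$conformer_id[i], "'")
      v
    })
  }
  out$freqs <- if ("freqs_cm1" %in% names(df)) {
    split_num(df$freqs_cm1, "freqs_cm1")
  } else rep(list(numeric(0)), nrow(out))
  out$rotconst <- if ("rotconst_ghz" %in% names(df)) {
    rc <- split_num(df$rotconst_ghz, "rotconst_ghz")
    for (i in seq_along(rc)) {
      if (length(rc[[i]]) && length(rc[[i]]) != 3) {
        stop("rotconst_ghz must hold 3 values for conformer '",
             out$conformer_id[i], "'")
      }
      if (any(rc[[i]] < 0)) {
        stop("negative rotational constant for conformer '",
             out$conformer_id[i], "'")
      }
    }
    rc
  } else rep(list(numeric(0)), nrow(out))
  out$mass_u <- if ("mass_u" %in% names(df)) num(df$mass_u, "mass_u") else NA_real_
  if (any(!is.na(out$mass_u) & out$mass_u <= 0)) stop("mass_u must be positive")
  has_e <- rowSums(!is.na(as.matrix(out[, sub("_hartree$", "", e_cols),
                                        drop = FALSE]))) > 0
  if (any(!has_e)) {
    stop("conformer '", out$conformer_id[which(!has_e)[1]],
         "' has no electronic energy")
  }
  out$cbs_eligible <- if (all(c("e_dz", "e_tz", "e_qz") %in% names(out))) {
    !is.na(out$e_dz) & !is.na(out$e_tz) & !is.na(out$e_qz)
  } else rep(FALSE, nrow(out))
  class(out) <- c("energy_table", "data.frame")
  out
}

#' Write an energy table in the dialect read_energy_table reads
#'
#' @param et an \code{energy_table}.
#' @param path output path (.csv or .tsv; extension selects the delimiter).
#' @return invisibly, the path.
#' @export
write_energy_table <- function(et, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  join <- function(l) vapply(l, function(v) paste(sprintf("%.10g", v), collapse = ";"), "")
  df <- data.frame(conformer_id = et$conformer_id, stringsAsFactors = FALSE)
  for (col in intersect(c("e_dz", "e_tz", "e_qz", "e_dft"), names(et))) {
    df[[paste0(col, "_hartree")]] <- sprintf("%.10f", et[[col]])
    df[[paste0(col, "_hartree")]][is.na(et[[col]])] <- ""
  }
  df$freqs_cm1 <- join(et$freqs)
  df$rotconst_ghz <- join(et$rotconst)
  if (!all(is.na(et$mass_u))) df$mass_u <- et$mass_u
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table as CSV with unit-bearing column names
#'
#' Writes atomically: the data is written to a temporary file in the
#' target directory and then renamed into place.
#'
#' @param df a data.frame.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_result_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
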