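# CSV readers/writers. Dialect: UTF-8, comma-separated, header row required,
# '.' decimal separator. Floats are serialized with 6 significant digits and
# column order is deterministic, so identical runs give byte-identical files.

#' Read a chemicals CSV
#'
#' Requires columns `chem_id` and `smiles`; `casrn`, `name`, `mw`,
#' `bp_celsius` and `vp_mmHg` are carried through when present. Rows with an
#' empty SMILES are split off into the `rejects` attribute rather than
#' aborting the run (unparsable-but-nonempty SMILES are caught later, at
#' classification). CASRN is never used as a join key.
#'
#' @param path CSV file path.
#' @return Data frame of chemical records with a `rejects` attribute.
#' @export
read_chemicals <- function(path) {
  if (!file.exists(path)) stop("chemicals file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("chem_id", "smiles")) {
    if (!col %in% names(df)) {
      stop("chemicals file is missing required column '", col, "'")
    }
  }
  df$chem_id <- as.character(df$chem_id)
  bad <- is.na(df$smiles) | !nzchar(trimws(df$smiles))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- df[bad, , drop = FALSE]
  out
}

#' Read a generic input table
#'
#' @param path CSV file path.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_table_csv <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Write a table as CSV with deterministic formatting
#'
#' @param df Data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(df, path, digits = 6) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- signif(out[[col]], digits)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
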