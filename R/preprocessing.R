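# Dataset input, cleaning and record handling.

#' Read a compound dataset
#'
#' Reads a delimited text file (CSV, TSV, or whitespace-separated SMILES
#' file) of molecules with identifiers and pIC50 activities. Records whose
#' SMILES cannot be parsed are skipped with a warning; all other records are
#' returned in file order, including those still lacking an activity value
#' (those are removed later by [clean_dataset()]).
#'
#' @param path Path to the input file. `.tsv`/`.tab` are read tab-separated,
#'   `.smi` as whitespace-separated `SMILES ID [pIC50]` lines, anything else
#'   comma-separated with a header.
#' @param smiles_col,id_col,activity_col Column names (header files only).
#' @return A tibble with columns `compound_id`, `smiles`, `pic50`.
#' @export
read_dataset <- function(path, smiles_col = "smiles", id_col = "id",
                         activity_col = "pic50") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "smi") {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("smiles", "id", "pic50")[1:3],
                             fill = TRUE)
    df <- data.frame(compound_id = as.character(raw$id), smiles = raw$smiles,
                     pic50 = suppressWarnings(as.numeric(raw$pic50)),
                     stringsAsFactors = FALSE)
  } else {
    sep <- if (ext %in% c("tsv", "tab")) "\t" else ","
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, comment.char = "")
    for (col in c(smiles_col, id_col, activity_col)) {
      if (!col %in% names(raw))
        stop("column '", col, "' not found in ", path, call. = FALSE)
    }
    df <- data.frame(compound_id = as.character(raw[[id_col]]),
                     smiles = as.character(raw[[smiles_col]]),
                     pic50 = suppressWarnings(as.numeric(raw[[activity_col]])),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) stop("empty dataset: ", path, call. = FALSE)
  percs <- perceive_molecules(df$smiles)
  bad <- vapply(percs, function(p) !is.null(p$error), logical(1))
  for (i in which(bad)) {
    warning("skipping ", df$compound_id[i], ": ", percs[[i]]$error, call. = FALSE)
  }
  tibble::as_tibble(df[!bad, , drop = FALSE])
}

#' Clean a compound dataset
#'
#' For each record the largest fragment is kept (salt stripping), formal
#' charges are neutralised where a valence-consistent neutral form exists,
#' and the structure is canonicalised (stereochemistry preserved). Records
#' without a pIC50 value are removed, as are exact duplicate structures
#' (identical canonical SMILES; the first occurrence survives). Input order
#' is preserved and the operation is idempotent.
#'
#' @param records A tibble from [read_dataset()] (or with the same columns).
#' @param config An [rg_config()] (SMARTS settings reach the backend cache).
#' @return A cleaned tibble with canonical SMILES in the `smiles` column.
#' @export
clean_dataset <- function(records, config = rg_config()) {
  if (nrow(records) == 0) return(records)
  percs <- perceive_molecules(records$smiles, config)
  ok <- vapply(percs, function(p) is.null(p$error), logical(1))
  records <- records[ok, , drop = FALSE]
  percs <- percs[ok]
  records$smiles <- vapply(percs, `[[`, character(1), "smiles")
  records <- records[!is.na(records$pic50), , drop = FALSE]
  records <- records[!duplicated(records$smiles), , drop = FALSE]
  records <- records[!duplicated(records$compound_id), , drop = FALSE]
  tibble::as_tibble(records)
}
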