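#' Read a permeability table
#'
#' Reads a delimited table of peptide permeability measurements (one row
#' per peptide: identifier, SMILES, assay type, experimental log10
#' permeability in cm/s). Rows whose SMILES does not parse are dropped and
#' reported.
#'
#' @param path CSV file path.
#' @param columns named character vector mapping the canonical names
#'   `id`, `smiles`, `assay`, `logP` to the file's column names.
#' @param validate check SMILES parse (needs the chemistry helper).
#' @return a tibble of class `permeability_records` with columns `id`,
#'   `smiles`, `assay`, `logP_exp`; attribute `n_rejected` counts dropped
#'   rows.
#' @export
read_permeability_table <- function(path,
                                    columns = c(id = "id", smiles = "SMILES",
                                                assay = "assay", logP = "logP"),
                                    validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing) > 0L) {
    stop("permeability table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- tibble::tibble(
    id = as.character(df[[columns[["id"]]]]),
    smiles = as.character(df[[columns[["smiles"]]]]),
    assay = as.character(df[[columns[["assay"]]]]),
    logP_exp = as.numeric(df[[columns[["logP"]]]])
  )
  bad <- !is.finite(out$logP_exp) | !nzchar(out$smiles)
  if (validate && any(!bad)) {
    bad[!bad] <- !smiles_is_valid(out$smiles[!bad])
  }
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (unparsable SMILES or non-finite logP): lines ",
            paste(utils::head(which(bad) + 1L, 10L), collapse = ", "))
  }
  out <- out[!bad, , drop = FALSE]
  attr(out, "n_rejected") <- sum(bad)
  class(out) <- c("permeability_records", class(out))
  out
}

#' Write a permeability table
#'
#' @param records a `permeability_records` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_permeability_table <- function(records, path) {
  df <- data.frame(id = records$id, SMILES = records$smiles,
                   assay = records$assay, logP = records$logP_exp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter permeability records for regression finetuning
#'
#' Keeps only records from the passive-diffusion assay (PAMPA) and removes
#' the "undetectable" marker value (logP_exp = -10), which flags
#' measurements that may reflect aggregation or collection error rather
#' than true permeability.
#'
#' @param records a `permeability_records` tibble (or any data frame with
#'   `assay` and `logP_exp`).
#' @param assay assay to keep.
#' @param undetectable marker value to drop.
#' @return the filtered tibble.
#' @export
filter_records <- function(records, assay = "PAMPA", undetectable = -10) {
  dplyr::filter(records, .data$assay == !!assay, .data$logP_exp != !!undetectable)
}
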