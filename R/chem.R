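#' Canonicalize SMILES strings
#'
#' Converts SMILES to RDKit canonical form through a batched call to the
#' bundled python helper. Invalid strings map to `NA_character_`.
#' Canonicalization is idempotent: applying it to its own output returns
#' the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  chem_tool("canon", smiles)
}

#' Test whether SMILES strings parse as valid chemistry
#'
#' @param smiles character vector.
#' @return logical vector, `TRUE` where the string parses.
#' @export
smiles_is_valid <- function(smiles) {
  !is.na(canonicalize_smiles(smiles))
}

#' Canonical SMILES of linear natural peptides, by one-letter sequence
#'
#' Independent reference builder (RDKit's FASTA/sequence reader), used to
#' cross-check the residue-by-residue SMILES assembler on natural L
#' peptides.
#'
#' @param sequences character vector of one-letter amino-acid sequences.
#' @return canonical SMILES, `NA` where the sequence was not readable.
#' @export
peptide_sequence_smiles <- function(sequences) {
  stopifnot(is.character(sequences))
  chem_tool("sequence", sequences)
}

chem_tool <- function(mode, lines) {
  n <- length(lines)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(lines) & nzchar(trimws(lines))
  if (!any(ok)) return(out)
  script <- system.file("python", "chem_tool.py", package = "peplm", mustWork = TRUE)
  fin <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  writeLines(lines[ok], fin)
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) stop("no python interpreter found on PATH")
  status <- system2(python, c(script, mode, fin, fout), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("chemistry helper failed (mode ", mode, ", status ", status, ")")
  res <- readLines(fout, warn = FALSE)
  if (length(res) != sum(ok)) stop("chemistry helper returned misaligned output")
  res[!nzchar(res)] <- NA_character_
  out[ok] <- res
  out
}
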