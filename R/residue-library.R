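#' Load a residue library
#'
#' Reads a tab-separated residue library: one residue per line with columns
#' `code`, `fragment` (side-chain SMILES branch from the alpha carbon, `-`
#' for hydrogen), `natural` (0/1), `reactive` (comma-separated tags from
#' thiol, sidechain_amine, sidechain_carboxyl; `-` for none), `stereo`
#' (1 if the alpha carbon is a stereocenter), and `bridge` (side-chain
#' SMILES bridging the backbone N to the alpha carbon for proline-like
#' residues, `-` otherwise). Lines starting with `#` are comments.
#'
#' @param path path to the library file; defaults to the packaged library of
#'   the 20 proteinogenic residues plus 12 unnatural ones.
#' @return a tibble of class `residue_library` with columns `code`,
#'   `fragment`, `natural`, `reactive` (list of character), `stereo`,
#'   `bridge`.
#' @export
load_residue_library <- function(path = default_residue_library_path()) {
  if (!file.exists(path)) {
    stop("residue library file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  valid_tags <- c("thiol", "sidechain_amine", "sidechain_carboxyl")
  rows <- lapply(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 6L) {
      stop("malformed residue library line ", i, ": expected 6 tab-separated fields, got ",
           length(fields))
    }
    tags <- if (fields[4] == "-") character(0) else strsplit(fields[4], ",", fixed = TRUE)[[1]]
    bad <- setdiff(tags, valid_tags)
    if (length(bad) > 0L) {
      stop("malformed residue library line ", i, ": unknown reactive tag ", bad[1])
    }
    if (!fields[3] %in% c("0", "1") || !fields[5] %in% c("0", "1")) {
      stop("malformed residue library line ", i, ": natural/stereo flags must be 0 or 1")
    }
    tibble::tibble(
      code = fields[1],
      fragment = if (fields[2] == "-") "" else fields[2],
      natural = fields[3] == "1",
      reactive = list(tags),
      stereo = fields[5] == "1",
      bridge = if (fields[6] == "-") "" else fields[6]
    )
  })
  lib <- dplyr::bind_rows(rows)
  dup <- lib$code[duplicated(lib$code)]
  if (length(dup) > 0L) {
    stop("duplicate residue code in library: ", dup[1])
  }
  # reactive tags require a terminal atom the cyclization chemistry can bond
  for (j in seq_len(nrow(lib))) {
    tags <- lib$reactive[[j]]
    frag <- lib$fragment[j]
    if ("thiol" %in% tags && !grepl("S$", frag)) {
      stop("residue ", lib$code[j], ": thiol fragment must end in S")
    }
    if ("sidechain_amine" %in% tags && !grepl("N$", frag)) {
      stop("residue ", lib$code[j], ": sidechain_amine fragment must end in N")
    }
    if ("sidechain_carboxyl" %in% tags && !grepl("C\\(=O\\)O$", frag)) {
      stop("residue ", lib$code[j], ": sidechain_carboxyl fragment must end in C(=O)O")
    }
    if (nzchar(lib$bridge[j]) && nzchar(frag)) {
      stop("residue ", lib$code[j], ": bridged residues carry the side chain in the bridge")
    }
  }
  class(lib) <- c("residue_library", class(lib))
  lib
}

#' @rdname load_residue_library
#' @export
default_residue_library_path <- function() {
  system.file("extdata", "residues.tsv", package = "peplm", mustWork = TRUE)
}

residue_entry <- function(library, code) {
  j <- match(code, library$code)
  if (is.na(j)) stop("residue code not in library: ", code)
  library[j, ]
}
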