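#' Structural descriptors computed from SMILES
#'
#' Four descriptors recomputable from the SMILES string alone (RDKit
#' substructure matching): `n_residues` (count of N-CA-C=O backbone
#' motifs), `n_methyl` (methylated backbone amide nitrogens), `has_peg`
#' (an N-CH2-CH2-O attachment, the PEG signature; serine-like side chains
#' do not match because the alpha carbon is not a CH2), and `is_cyclic`
#' (a macrocycle: any ring of seven or more atoms, or a
#' diketopiperazine-sized six-ring with two non-aromatic nitrogens).
#'
#' @param smiles character vector.
#' @return tibble with columns `n_residues`, `n_methyl`, `has_peg`,
#'   `is_cyclic`; `NA` rows where the SMILES did not parse.
#' @export
compute_descriptors <- function(smiles) {
  res <- chem_tool("descriptors", smiles)
  parts <- strsplit(res, "\t", fixed = TRUE)
  get <- function(i, as_lgl = FALSE) {
    v <- vapply(parts, function(p) {
      if (length(p) == 4L) as.integer(p[i]) else NA_integer_
    }, integer(1))
    if (as_lgl) v == 1L else v
  }
  tibble::tibble(n_residues = get(1), n_methyl = get(2),
                 has_peg = get(3, TRUE), is_cyclic = get(4, TRUE))
}

#' Default planted permeability coefficients
#'
#' Linear weights of the toy structure-to-permeability relation, on the
#' log10 cm/s scale: each residue lowers permeability, each backbone
#' N-methyl raises it, PEGylation lowers it sharply, cyclization raises
#' it. Magnitudes are chosen so that a batch of generated peptides spans
#' roughly -8..-4 with classes balanced near the -5.5 permeability cutoff,
#' emulating the spread of curated PAMPA databases.
#'
#' @return named numeric vector with elements `intercept`, `n_residues`,
#'   `n_methyl`, `has_peg`, `is_cyclic`.
#' @export
toy_coefficients <- function() {
  c(intercept = -4.3, n_residues = -0.3, n_methyl = 0.5,
    has_peg = -1.2, is_cyclic = 0.8)
}

#' Synthetic permeability dataset with a planted linear relation
#'
#' Generates peptides with the stochastic generator, computes the four
#' structural descriptors, and emits experimental-style log permeability
#' as the planted linear combination plus Gaussian noise. A configurable
#' fraction of rows is marked "undetectable" (logP = -10) and another
#' fraction is assigned a cell-based assay label, so the cleaning filter
#' has work to do. Descriptors are taken from the symbolic specs; they
#' coincide with [compute_descriptors()] on the emitted SMILES.
#'
#' @param n number of peptides.
#' @param library a `residue_library`.
#' @param config a `generator_config`; the default emulates a cyclic
#'   peptide permeability panel (up to 10 residues).
#' @param coefficients named vector as in [toy_coefficients()].
#' @param noise_sd Gaussian noise standard deviation on logP.
#' @param undetectable_fraction share of rows replaced by the -10 marker.
#' @param other_assay_fraction share of rows labelled with a cell-based
#'   assay instead of PAMPA.
#' @param seed integer seed.
#' @param path optional CSV path to write the table to.
#' @return list of class `toy_permeability_fixture`: `records` (a
#'   `permeability_records` tibble with extra descriptor columns),
#'   `coefficients`, `noise_sd`.
#' @export
make_toy_permeability_dataset <- function(n,
                                          library = load_residue_library(),
                                          config = generator_config(max_length = 10L),
                                          coefficients = toy_coefficients(),
                                          noise_sd = 0.3,
                                          undetectable_fraction = 0.05,
                                          other_assay_fraction = 0.05,
                                          seed = 1L,
                                          path = NULL) {
  stopifnot(n >= 1)
  need <- c("intercept", "n_residues", "n_methyl", "has_peg", "is_cyclic")
  if (!all(need %in% names(coefficients))) {
    stop("coefficients must be named: ", paste(need, collapse = ", "))
  }
  peps <- generate_peptides(n, library, config, seed = seed, smiles = TRUE)
  X <- cbind(1, peps$length, peps$n_methyl, as.integer(peps$pegylated),
             as.integer(peps$cyclization != "linear"))
  signal <- as.vector(X %*% coefficients[need])
  # seed + 1: the generator consumed the stream under `seed`
  set.seed(seed + 1L)
  logP <- signal + stats::rnorm(n, sd = noise_sd)
  assay <- rep("PAMPA", n)
  n_other <- round(other_assay_fraction * n)
  if (n_other > 0L) {
    assay[sample.int(n, n_other)] <- sample(c("Caco2", "MDCK", "RRCK"),
                                            n_other, replace = TRUE)
  }
  undet <- rep(FALSE, n)
  pampa_idx <- which(assay == "PAMPA")
  n_undet <- round(undetectable_fraction * length(pampa_idx))
  if (n_undet > 0L) {
    undet[sample(pampa_idx, n_undet)] <- TRUE
    logP[undet] <- -10
  }
  records <- tibble::tibble(
    id = sprintf("pep%05d", seq_len(n)),
    smiles = peps$smiles,
    assay = assay,
    logP_exp = logP,
    n_residues = peps$length,
    n_methyl = peps$n_methyl,
    has_peg = peps$pegylated,
    is_cyclic = peps$cyclization != "linear",
    undetectable = undet
  )
  class(records) <- c("permeability_records", class(records))
  if (!is.null(path)) {
    write_permeability_table(records, path)
  }
  structure(list(records = records,
                 coefficients = coefficients[need],
                 noise_sd = noise_sd),
            class = "toy_permeability_fixture")
}

#' @export
print.toy_permeability_fixture <- function(x, ...) {
  cat("<toy_permeability_fixture> ", nrow(x$records), " records; planted ",
      "logP = ", paste(sprintf("%+.2f*%s", x$coefficients,
                               sub("intercept", "1", names(x$coefficients))),
                       collapse = " "),
      " + N(0, ", x$noise_sd, ")\n", sep = "")
  invisible(x)
}
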