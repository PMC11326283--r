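#' Generator configuration
#'
#' Parameters of the stochastic peptide generator. Defaults mirror the
#' generation recipe used to build the pretraining corpus: peptide length
#' uniform on 1..`max_length`, 10% unnatural residues, 10% D stereocenters,
#' N-methylation of 20% of backbone amides on 20% of peptides (4% overall),
#' PEGylation of 20% of peptides with 1-4 ethylene glycol monomers, and a
#' cyclization reaction drawn uniformly from five chemistries (degrading to
#' linear when infeasible).
#'
#' @param max_length maximum residue count (length is uniform on 1..max_length).
#' @param unnatural_fraction per-residue probability of drawing from the
#'   unnatural partition of the library.
#' @param d_fraction per-stereocenter probability of the D configuration.
#' @param nmeth_peptide_fraction probability that a peptide is selected for
#'   N-methylation.
#' @param nmeth_amine_fraction per-amide methylation probability within a
#'   selected peptide.
#' @param peg_fraction probability that a peptide receives a PEG chain.
#' @param peg_monomers integer range (min, max) of PEG monomer counts.
#' @param cyclization_types character vector of enabled cyclization
#'   chemistries.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(max_length = 100L,
                             unnatural_fraction = 0.10,
                             d_fraction = 0.10,
                             nmeth_peptide_fraction = 0.20,
                             nmeth_amine_fraction = 0.20,
                             peg_fraction = 0.20,
                             peg_monomers = c(1L, 4L),
                             cyclization_types = c("head_to_tail",
                                                   "sidechain_to_sidechain",
                                                   "sidechain_to_head",
                                                   "sidechain_to_tail",
                                                   "disulfide")) {
  probs <- c(unnatural_fraction, d_fraction, nmeth_peptide_fraction,
             nmeth_amine_fraction, peg_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (max_length < 1L) stop("max_length must be >= 1")
  if (length(peg_monomers) != 2L || peg_monomers[1] < 1L || peg_monomers[2] < peg_monomers[1]) {
    stop("peg_monomers must be an increasing integer range with min >= 1")
  }
  known <- c("head_to_tail", "sidechain_to_sidechain", "sidechain_to_head",
             "sidechain_to_tail", "disulfide")
  bad <- setdiff(cyclization_types, known)
  if (length(bad) > 0L) stop("unknown cyclization type: ", bad[1])
  structure(list(
    max_length = as.integer(max_length),
    unnatural_fraction = unnatural_fraction,
    d_fraction = d_fraction,
    nmeth_peptide_fraction = nmeth_peptide_fraction,
    nmeth_amine_fraction = nmeth_amine_fraction,
    peg_fraction = peg_fraction,
    peg_monomers = as.integer(peg_monomers),
    cyclization_types = cyclization_types
  ), class = "generator_config")
}

#' Sample a symbolic peptide
#'
#' Draws a linear, unmodified peptide: length uniform on 1..max_length, each
#' residue independently unnatural with probability `unnatural_fraction`
#' (uniform within its partition), and each alpha stereocenter independently
#' D with probability `d_fraction`. Uses the current RNG stream.
#'
#' @param library a `residue_library`.
#' @param config a `generator_config`.
#' @return a `peptide_spec`: residues (tibble of code, stereo), cyclization
#'   (`linear` at this stage), empty modification slots.
#' @export
sample_peptide_spec <- function(library, config = generator_config()) {
  nat <- library$code[library$natural]
  unnat <- library$code[!library$natural]
  if (config$unnatural_fraction > 0 && length(unnat) == 0L) {
    stop("unnatural_fraction > 0 but the library has no unnatural residues")
  }
  if (length(nat) == 0L) stop("library has no natural residues")
  len <- sample.int(config$max_length, 1L)
  is_unnat <- stats::runif(len) < config$unnatural_fraction
  codes <- character(len)
  n_u <- sum(is_unnat)
  if (n_u > 0L) codes[is_unnat] <- unnat[sample.int(length(unnat), n_u, replace = TRUE)]
  if (n_u < len) codes[!is_unnat] <- nat[sample.int(length(nat), len - n_u, replace = TRUE)]
  has_st <- library$stereo[match(codes, library$code)]
  stereo <- ifelse(has_st, ifelse(stats::runif(len) < config$d_fraction, "D", "L"), "none")
  structure(list(
    residues = tibble::new_tibble(list(code = codes, stereo = stereo), nrow = len),
    cyclization = list(type = "linear", sites = integer(0)),
    n_methyl_sites = integer(0),
    peg = NULL
  ), class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  st <- ifelse(x$residues$stereo == "D", "d", "")
  cat("<peptide_spec> ", paste0(st, x$residues$code, collapse = "-"), "\n", sep = "")
  cat("  cyclization: ", x$cyclization$type,
      if (length(x$cyclization$sites)) paste0(" (", paste(x$cyclization$sites, collapse = ","), ")"),
      "\n", sep = "")
  if (length(x$n_methyl_sites)) {
    cat("  N-methyl sites: ", paste(x$n_methyl_sites, collapse = ","), "\n", sep = "")
  }
  if (!is.null(x$peg)) {
    cat("  PEG: ", x$peg$n_monomers, " monomer(s) at ",
        if (identical(x$peg$site, "nterm")) "N-terminus" else paste0("residue ", x$peg$site),
        "\n", sep = "")
  }
  invisible(x)
}

# Plain-vector view of the library rows for a spec (tibble row slicing is
# far too slow inside the generation loop).
spec_entries <- function(spec, library) {
  j <- match(spec$residues$code, library$code)
  list(
    fragment = library$fragment[j],
    natural = library$natural[j],
    reactive = library$reactive[j],
    stereo = library$stereo[j],
    bridge = library$bridge[j]
  )
}

# Backbone amide positions eligible for N-methylation: every residue after the
# first whose backbone N is a secondary amide (proline-like bridged residues
# are already tertiary). The N-terminal alpha-amine is not a backbone amide.
backbone_amide_sites <- function(spec, library) {
  L <- nrow(spec$residues)
  if (L < 2L) return(integer(0))
  ent <- spec_entries(spec, library)
  setdiff(which(!nzchar(ent$bridge)), 1L)
}

# Free amines available for PEGylation: the N-terminal alpha-amine (unless the
# first residue is proline-like or the head was consumed by cyclization) plus
# side-chain amines not consumed by a side-chain cyclization bond.
free_amine_sites <- function(spec, library) {
  ent <- spec_entries(spec, library)
  cyc <- spec$cyclization
  sites <- list()
  head_used <- cyc$type %in% c("head_to_tail", "sidechain_to_head")
  if (!head_used && !nzchar(ent$bridge[1])) sites <- c(sites, list("nterm"))
  amine_idx <- which(vapply(ent$reactive, function(t) "sidechain_amine" %in% t, logical(1)))
  if (cyc$type %in% c("sidechain_to_sidechain", "sidechain_to_tail")) {
    amine_idx <- setdiff(amine_idx, cyc$sites[1])
  }
  c(sites, as.list(amine_idx))
}

#' Assign a cyclization reaction
#'
#' Draws one cyclization type uniformly from the configured set and applies
#' it when the residues support the required chemistry; otherwise the
#' peptide is left linear. Head-to-tail closes a backbone amide, disulfide
#' bridges two thiol side chains, and the sidechain variants form lactam
#' bonds between a side-chain amine or carboxyl and a side chain or
#' terminus. Attachment sites are chosen uniformly among candidates.
#'
#' @param spec a linear, unmodified `peptide_spec`.
#' @param library a `residue_library`.
#' @param config a `generator_config`.
#' @return the spec with its `cyclization` slot filled.
#' @export
assign_cyclization <- function(spec, library, config = generator_config()) {
  if (spec$cyclization$type != "linear" || length(spec$n_methyl_sites) ||
      !is.null(spec$peg)) {
    stop("assign_cyclization expects a linear, unmodified spec")
  }
  types <- config$cyclization_types
  if (length(types) == 0L) return(spec)
  type <- types[[sample.int(length(types), 1L)]]
  L <- nrow(spec$residues)
  ent <- spec_entries(spec, library)
  has_tag <- function(tag) {
    which(vapply(ent$reactive, function(t) tag %in% t, logical(1)))
  }
  sites <- switch(type,
    head_to_tail = if (L >= 2L) c(1L, L) else NULL,
    disulfide = {
      th <- has_tag("thiol")
      if (length(th) >= 2L) sort(th[sample.int(length(th), 2L)]) else NULL
    },
    sidechain_to_sidechain = {
      am <- has_tag("sidechain_amine")
      cx <- has_tag("sidechain_carboxyl")
      if (length(am) >= 1L && length(cx) >= 1L) {
        a <- am[sample.int(length(am), 1L)]
        x <- cx[sample.int(length(cx), 1L)]
        c(a, x)
      } else NULL
    },
    sidechain_to_head = {
      # lactam between a side-chain carboxyl and the N-terminal amine
      cx <- setdiff(has_tag("sidechain_carboxyl"), 1L)
      if (L >= 2L && length(cx) >= 1L && !nzchar(ent$bridge[1])) {
        c(1L, cx[sample.int(length(cx), 1L)])
      } else NULL
    },
    sidechain_to_tail = {
      # lactam between a side-chain amine and the C-terminal carboxyl
      am <- setdiff(has_tag("sidechain_amine"), L)
      if (L >= 2L && length(am) >= 1L) c(am[sample.int(length(am), 1L)], L) else NULL
    }
  )
  if (!is.null(sites)) spec$cyclization <- list(type = type, sites = sites)
  spec
}

#' Apply backbone N-methylation
#'
#' With probability `nmeth_peptide_fraction` the peptide is selected; within
#' a selected peptide every eligible backbone amide nitrogen is methylated
#' independently with probability `nmeth_amine_fraction`.
#'
#' @inheritParams assign_cyclization
#' @return the spec with `n_methyl_sites` filled.
#' @export
apply_n_methylation <- function(spec, library, config = generator_config()) {
  if (stats::runif(1) >= config$nmeth_peptide_fraction) return(spec)
  cand <- backbone_amide_sites(spec, library)
  if (length(cand) == 0L) return(spec)
  hit <- stats::runif(length(cand)) < config$nmeth_amine_fraction
  spec$n_methyl_sites <- cand[hit]
  spec
}

#' Apply PEGylation
#'
#' With probability `peg_fraction` a polyethylene-glycol chain of uniform
#' length `peg_monomers[1]..peg_monomers[2]` is attached at a uniformly
#' chosen free amine. Peptides without a free amine are left unmodified.
#'
#' @inheritParams assign_cyclization
#' @return the spec with the `peg` slot possibly filled.
#' @export
apply_pegylation <- function(spec, library, config = generator_config()) {
  if (stats::runif(1) >= config$peg_fraction) return(spec)
  cand <- free_amine_sites(spec, library)
  if (length(cand) == 0L) return(spec)
  site <- cand[[sample.int(length(cand), 1L)]]
  rng <- config$peg_monomers
  n_mono <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  spec$peg <- list(site = site, n_monomers = n_mono)
  spec
}

# Ring-closure bond labels reserved for the assembler; residue fragments may
# freely use plain digits 1-9 for their own rings.
RING_BACKBONE <- "%11"
RING_SIDECHAIN <- "%12"
RING_BRIDGE <- "%13"

#' Realize a peptide spec as SMILES
#'
#' Assembles the molecule residue by residue (backbone N, alpha carbon with
#' side chain, carbonyl), realizing stereo flags as `@`/`@@` tetrahedral
#' annotations, cyclization as ring-closure bonds (backbone amide,
#' disulfide, or lactam), N-methylation as a methyl branch on the backbone
#' N, and PEG as a `(CCO)n` chain on the chosen amine.
#'
#' @param spec a fully assigned `peptide_spec`.
#' @param library a `residue_library`.
#' @param canonical return OpenBabel canonical SMILES (default) or the raw
#'   assembled string.
#' @return a single SMILES string.
#' @export
build_smiles <- function(spec, library, canonical = TRUE) {
  L <- nrow(spec$residues)
  cyc <- spec$cyclization
  ent <- spec_entries(spec, library)
  peg_chain <- if (!is.null(spec$peg)) strrep("CCO", spec$peg$n_monomers) else ""
  parts <- character(L)
  for (i in seq_len(L)) {
    sc <- ent$fragment[i]
    # side-chain ends of cyclization bonds
    if (cyc$type == "disulfide" && i %in% cyc$sites) {
      sc <- paste0(sc, RING_SIDECHAIN)
    }
    if (cyc$type %in% c("sidechain_to_sidechain", "sidechain_to_tail") &&
        i == cyc$sites[1]) {
      sc <- paste0(sc, RING_SIDECHAIN)
    }
    if (cyc$type %in% c("sidechain_to_sidechain", "sidechain_to_head") &&
        i == cyc$sites[2]) {
      sc <- sub("C\\(=O\\)O$", paste0("C", RING_SIDECHAIN, "=O"), sc)
    }
    # PEG on a side-chain amine (fragment ends in N)
    if (!is.null(spec$peg) && identical(spec$peg$site, i)) sc <- paste0(sc, peg_chain)
    # backbone nitrogen
    n <- "N"
    if (i == 1L) {
      if (cyc$type == "head_to_tail") n <- paste0(n, RING_BACKBONE)
      if (cyc$type == "sidechain_to_head") n <- paste0(n, RING_SIDECHAIN)
      if (identical(spec$peg$site, "nterm")) n <- paste0(n, "(", peg_chain, ")")
    } else if (i %in% spec$n_methyl_sites) {
      n <- "N(C)"
    }
    bridged <- nzchar(ent$bridge[i])
    if (bridged) n <- paste0(n, RING_BRIDGE, ent$bridge[i])
    # alpha carbon; in this writing order L is @@ for ordinary residues and
    # flips for bridged ones (the N arrives via the ring closure)
    st <- spec$residues$stereo[i]
    ca <- if (st == "none") "C" else if (bridged) {
      if (st == "L") "[C@H]" else "[C@@H]"
    } else {
      if (st == "L") "[C@@H]" else "[C@H]"
    }
    if (bridged) ca <- paste0(ca, RING_BRIDGE)
    if (!bridged && nzchar(sc)) ca <- paste0(ca, "(", sc, ")")
    # carbonyl
    co <- if (i < L) {
      "C(=O)"
    } else if (cyc$type == "head_to_tail") {
      paste0("C", RING_BACKBONE, "=O")
    } else if (cyc$type == "sidechain_to_tail") {
      paste0("C", RING_SIDECHAIN, "=O")
    } else {
      "C(=O)O"
    }
    parts[i] <- paste0(n, ca, co)
  }
  raw <- paste(parts, collapse = "")
  if (!canonical) return(raw)
  can <- canonicalize_smiles(raw)
  if (is.na(can)) {
    stop("chemically unrealizable spec (assembled SMILES did not parse): ", raw)
  }
  can
}

#' Generate a batch of modified peptides
#'
#' Runs the full sampling pipeline (residues and stereo, cyclization,
#' N-methylation, PEGylation, SMILES realization) `n` times.
#'
#' @param n number of peptides.
#' @param library a `residue_library`.
#' @param config a `generator_config`.
#' @param seed integer seed; the run is fully reproducible from it.
#' @param smiles build SMILES strings (set `FALSE` to keep only symbolic
#'   specs, much faster for rate studies).
#' @return a tibble with one row per peptide: `smiles` (if built), `length`,
#'   `n_unnatural`, `n_stereocenters`, `n_d`, `cyclization`, `n_amides`,
#'   `n_methyl`, `has_free_amine`, `pegylated`, `peg_monomers`, and a
#'   list-column `spec`.
#' @export
generate_peptides <- function(n, library = load_residue_library(),
                              config = generator_config(), seed = 1L,
                              smiles = TRUE) {
  stopifnot(n >= 0)
  set.seed(seed)
  specs <- vector("list", n)
  len <- n_unnat <- n_st <- n_d <- n_am <- n_me <- peg_k <- integer(n)
  cyc_type <- character(n)
  free_am <- pegd <- logical(n)
  for (r in seq_len(n)) {
    spec <- sample_peptide_spec(library, config)
    spec <- assign_cyclization(spec, library, config)
    spec <- apply_n_methylation(spec, library, config)
    spec <- apply_pegylation(spec, library, config)
    ent <- spec_entries(spec, library)
    specs[[r]] <- spec
    len[r] <- nrow(spec$residues)
    n_unnat[r] <- sum(!ent$natural)
    n_st[r] <- sum(spec$residues$stereo != "none")
    n_d[r] <- sum(spec$residues$stereo == "D")
    cyc_type[r] <- spec$cyclization$type
    n_am[r] <- length(backbone_amide_sites(spec, library))
    n_me[r] <- length(spec$n_methyl_sites)
    free_am[r] <- length(free_amine_sites(spec, library)) > 0 || !is.null(spec$peg)
    pegd[r] <- !is.null(spec$peg)
    peg_k[r] <- if (is.null(spec$peg)) NA_integer_ else spec$peg$n_monomers
  }
  out <- tibble::tibble(
    length = len, n_unnatural = n_unnat, n_stereocenters = n_st, n_d = n_d,
    cyclization = cyc_type, n_amides = n_am, n_methyl = n_me,
    has_free_amine = free_am, pegylated = pegd, peg_monomers = peg_k,
    spec = specs
  )
  if (n == 0L) {
    out$smiles <- character(0)
    return(dplyr::relocate(out, "smiles"))
  }
  if (smiles) {
    raw <- vapply(out$spec, function(s) build_smiles(s, library, canonical = FALSE),
                  character(1))
    can <- canonicalize_smiles(raw)
    if (anyNA(can)) {
      bad <- which(is.na(can))[1]
      stop("generated spec did not realize as valid chemistry: ", raw[bad])
    }
    out$smiles <- can
    out <- dplyr::relocate(out, "smiles")
  }
  out
}

#' Generate a SMILES corpus file
#'
#' Writes `n` generated peptide SMILES, one per line, and returns a summary
#' of empirical modification fractions.
#'
#' @inheritParams generate_peptides
#' @param output path of the corpus file to write.
#' @return invisibly, a one-row tibble: counts and empirical fractions per
#'   modification class.
#' @export
generate_corpus <- function(n, library = load_residue_library(),
                            config = generator_config(), seed = 1L,
                            output) {
  peps <- generate_peptides(n, library, config, seed = seed, smiles = TRUE)
  con <- file(output, open = "wb")
  on.exit(close(con))
  if (n > 0L) writeLines(peps$smiles, con, sep = "\n")
  summary <- corpus_summary(peps)
  invisible(summary)
}

#' Summarize modification rates of a generated batch
#'
#' @param peptides a tibble from [generate_peptides()].
#' @return a one-row tibble of counts and empirical fractions.
#' @export
corpus_summary <- function(peptides) {
  n <- nrow(peptides)
  tibble::tibble(
    n = n,
    n_residues = sum(peptides$length),
    frac_unnatural = sum(peptides$n_unnatural) / max(1, sum(peptides$length)),
    frac_d = sum(peptides$n_d) / max(1, sum(peptides$n_stereocenters)),
    frac_cyclic = if (n) mean(peptides$cyclization != "linear") else NA_real_,
    frac_nmethyl_amides = sum(peptides$n_methyl) / max(1, sum(peptides$n_amides)),
    frac_pegylated_of_free = sum(peptides$pegylated) /
      max(1, sum(peptides$has_free_amine)),
    max_peg_monomers = if (any(peptides$pegylated)) {
      max(peptides$peg_monomers, na.rm = TRUE)
    } else NA_integer_
  )
}
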