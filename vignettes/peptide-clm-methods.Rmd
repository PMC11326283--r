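---
title: "Methods: generating, tokenizing, modeling and evaluating modified peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generating, tokenizing, modeling and evaluating modified peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(peplm)
```

`peplm` implements a complete desk-scale method stack for chemical language
modeling of therapeutically modified peptides: a stochastic generator of
modified, optionally cyclic peptide SMILES; an n-gram SMILES tokenizer; a
BERT-style encoder with rotary position embeddings trained under the
masked-language-model (MLM) objective; and a leave-one-cluster-out
membrane-permeability regression benchmark built on a synthetic
structure-permeability fixture. This vignette records the model, the
tunable parameters, the design decisions taken where the design was
genuinely open, and what the synthetic experiments do and do not show.

## 1. The peptide generator

Peptides are sampled symbolically first and realized as chemistry second.
A `peptide_spec` holds an ordered residue list with stereo flags, one
cyclization assignment, the set of N-methylated backbone amides, and an
optional PEG attachment; `build_smiles()` then assembles the molecule
residue by residue and returns the RDKit canonical SMILES.

The sampling distribution mirrors the recipe used to build large synthetic
pretraining corpora for peptide language models:

* **Length** is uniform on `1..max_length` (default 100). The sources that
  motivate this toolkit state only an upper bound; uniform is the simplest
  defensible choice and is configurable.
* **Residue identity**: each position is independently unnatural with
  probability `unnatural_fraction` (default 0.10), uniform within the
  natural (20 entries) or unnatural (12 entries) partition of the residue
  library. The packaged library stands in for the much larger
  SwissSidechain-style collections, which require a download; entries are
  side-chain SMILES fragments with attachment-point conventions
  (`inst/extdata/residues.tsv` documents the format).
* **Stereochemistry**: every alpha stereocenter is independently D with
  probability `d_fraction` (default 0.10). We chose per-carbon Bernoulli
  draws over exactly-10%-without-replacement: the aggregate statement
  "10% of the alpha carbons" holds in expectation either way, and
  independent draws match the "uniformly sampled" framing of the
  generation procedure. Glycine has no alpha stereocenter and is never
  flagged.
* **Cyclization**: one type is drawn uniformly from {head-to-tail,
  sidechain-to-sidechain, sidechain-to-head, sidechain-to-tail,
  disulfide}. If the drawn chemistry is infeasible for the sampled
  residues (disulfide needs two thiols; the sidechain variants need a
  side-chain amine and/or carboxyl at valid positions; head-to-tail needs
  length at least 2) the peptide stays linear rather than being redrawn,
  so the cyclic fraction is an emergent property of residue composition.
  The sidechain-to-head and sidechain-to-tail reactions are realized as
  lactam (amide) bonds, the common synthetic chemistry for those
  closures.
* **N-methylation** is applied after cyclization: with probability
  `nmeth_peptide_fraction` (default 0.20) a peptide is selected, and each
  eligible backbone amide nitrogen within it is independently methylated
  with probability `nmeth_amine_fraction` (default 0.20), so about 4% of
  all backbone amides are methylated. Eligible amides are positions
  2..L; the N-terminal alpha-amine is not an amide, and proline-like
  bridged residues are already tertiary and excluded.
* **PEGylation**: with probability `peg_fraction` (default 0.20) a chain
  of 1-4 ethylene-glycol monomers (uniform) is attached at a uniformly
  chosen free amine - the N-terminal alpha-amine if not consumed by
  cyclization, plus side-chain amines not consumed by a side-chain bond.
  A peptide with no free amine is left unmodified. Amines consumed by
  cyclization are excluded from the candidate set.

Stereo conventions: written N-first, the L configuration is `[C@@H]` for
ordinary residues and flips to `[C@H]` for proline-like residues, whose
backbone N arrives through the ring-closure bond; both conventions were
fixed by comparing InChI stereo descriptors of the assembled monomers
against the literature structures. The assembler is cross-checked in the
test suite against RDKit's independent peptide builder
(`MolFromSequence`): natural L peptides agree exactly on canonical SMILES
(up to the beta stereocenters of Thr/Ile, which the packaged library
deliberately omits).

All chemistry validation and canonicalization go through RDKit via a
batched python helper (`inst/python/chem_tool.py`); canonicalization is
idempotent and every emitted molecule must survive it.

## 2. The tokenizer

SMILES strings are pretokenized atom-aware: `Cl` and `Br` stay whole
(distinct from C and B), bracket atoms `[...]` are single units, and
every other character is its own token. Vocabulary training counts all
contiguous atomic-token runs of up to `max_ngram_chars` characters
(default 5; the sources disagree between 4 and 5, and we follow the
procedural description, keeping the limit configurable) and retains the
most frequent ones up to `budget` total non-special tokens (default 581,
for parity with the published vocabulary size; with the 5 fixed special
tokens `[PAD] [UNK] [CLS] [SEP] [MASK]` at ids 0-4 this gives 586).
Because no selection rule is published for the vocabulary cut, we rank by
raw frequency with lexicographic tie-breaks from a single pooled
candidate list; category flags (plain runs, bracketed runs, full balanced
`(...)` motifs) can restrict the candidate pool but no per-category
quotas are imposed. Encoding is greedy longest-match left to right - the
standard choice for fixed-vocabulary subword schemes - with `[CLS]`/`[SEP]`
framing, tail truncation, and `[PAD]` to the context length.
`decode_ids()` inverts `encode_smiles()` whenever no truncation or
`[UNK]` occurred, and flags lossy sequences.

## 3. The encoder and the MLM objective

The model is a bidirectional post-layer-norm transformer with rotary
position embeddings (RoPE): queries and keys are rotated by
position-dependent angles so attention scores depend only on relative
offsets. The full-size configuration (6 layers, 12 heads, hidden 768,
feed-forward 3072, context 768, vocabulary 586) instantiates at about
43.5M trainable parameters; the package verifies the 42-46M range by
instantiation. There is no learned absolute-position table, and the test
suite asserts the shift-invariance property directly.

Masking follows the BERT recipe: each non-special, non-padding position
is independently selected with probability 0.15; selected positions
become `[MASK]` with probability 0.80, a uniformly random non-special
token with probability 0.10, and stay unchanged otherwise. Labels record
originals only at selected positions; unselected positions contribute no
gradient.

Training uses AdamW with linear warmup (the published recipe states only
the learning rate, 5e-5, and batch size, 64; the optimizer family and
schedule are our choice and are exposed as arguments), evaluates on a
held-out split at a fixed interval, and reports cross-entropy both
summed over masked positions and per-position (the mean is what the
training curves show; the sum is retained for comparability with loss
formulas written as sums) together with macro-averaged accuracy:
per-token-class accuracy averaged unweighted over the classes observed
among the evaluation labels, so rare tokens weigh as much as common
ones.

Numerical notes: layer-norm uses eps 1e-5; GELU is the tanh
approximation; softmax subtracts row maxima; weight decay exempts biases
and layer-norm parameters, as is conventional. The canonical
implementation of the encoder and both backward passes is plain R matrix
algebra (`R/model.R`), verified against central finite differences; a
compiled RcppArmadillo fast path (`src/encoder.cpp`) mirrors it operation
for operation, is asserted equivalent to 1e-10 in the test suite, and is
used by default (`options(peplm.use_compiled = FALSE)` forces the R
path). Dropout masks are drawn from R's RNG in both paths, so every run
is reproducible from its seed.

## 4. Permeability data, clustering, and leave-one-cluster-out

`read_permeability_table()` ingests CycPeptMPDB-style CSVs (id, SMILES,
assay, log10 permeability in cm/s; column mapping configurable).
`filter_records()` keeps the passive-diffusion assay (PAMPA) only and
removes the "-10 undetectable" marker rows, which flag measurements that
may reflect aggregation rather than true permeability.

Molecules are embedded as the mean of final-layer hidden states over
non-special positions. Published descriptions do not say whether the
`[CLS]` state or a pooled state was used; mean pooling is the common
default and keeps the embedding well-defined for arbitrarily truncated
inputs. The embedding matrix is centered (not scaled - the
variance-retention criterion is scale-dependent and the hidden units
share a scale by construction) and projected onto the smallest principal
subspace holding at least 99% of the variance. k-means (10 restarts,
fixed seed) runs for each candidate k (default 2..6); the selected k
maximizes mean silhouette width, with the Davies-Bouldin and
Calinski-Harabasz indices computed alongside as confirmation. The two
confirmation indices are implemented in the package (no pre-installed R
package provides them); both are exercised against obviously-good versus
shuffled partitions in the tests.

The evaluation schedule holds out each cluster exactly once. The
remaining records form 5 train/validation folds: at cluster granularity
when exactly 5 clusters remain (each remaining cluster is one validation
fold - the natural reading of "five models trained on the remaining
clusters with 5-fold cross-validation" when six clusters exist), at
seeded record granularity otherwise. Record ids never cross from a test
cluster into any train or validation fold of the same iteration, and the
suite asserts this on ids.

Finetuning replaces the LM head with one fully connected layer of the
hidden width producing a scalar from the mean-pooled final hidden
states. All weights train under MSE with AdamW (published recipe:
lr 5e-6, dropout 0.15, weight decay 0.001, batch 16, at most 10,000
steps - these are the function defaults); validation MSE is scored every
epoch and the best checkpoint is returned. The head bias is initialized
at the training-set mean so optimization starts from the
constant-predictor baseline; an optional early-stopping patience
(disabled by default, enabled in the desk-scale pipeline) stops training
after a fixed number of epochs without validation improvement. Test
predictions are the arithmetic mean over the 5 fold models. Scoring
binarizes the experimental values at log10 P = -5.5 (the
oral-bioavailability-motivated cutoff that balances the classes better
than -6), computes ROC-AUC (trapezoidal, via pROC) and PR-AUC
(step-wise interpolation over tied-score groups, implemented here and
tested against a brute-force threshold walk), plus RMSE. Single-class
test clusters yield undefined AUCs, reported as NA and excluded from the
AUC aggregate with a warning; RMSE is always computed.

## 5. The synthetic permeability fixture

Because the curated cyclic-peptide permeability database cannot be
bundled, `make_toy_permeability_dataset()` plants a known
structure-permeability relation in generated peptides:

log10 P = -4.3 - 0.3 x (residue count) + 0.5 x (N-methyl count)
- 1.2 x (PEG present) + 0.8 x (cyclic) + N(0, 0.3).

The signs follow the medicinal-chemistry expectations the literature
records (backbone N-methylation tends to increase passive permeability;
PEGylation strongly decreases it; cyclization increases it; size
decreases it), and the magnitudes were chosen once, before any testing,
so that a generated panel spans roughly -8..-4 with both classes well
populated around the -5.5 cutoff - the spread observed in curated PAMPA
collections. The noise level (sd 0.3) approximates inter-laboratory
assay variability. A configurable fraction of rows receives the -10
undetectable marker and a cell-based assay label so the cleaning filter
is exercised end to end.

All four descriptors are recomputable from the SMILES alone via RDKit
substructure matching (`compute_descriptors()`): residue count as
N-CA-C=O backbone motifs, N-methyl count as methylated amide nitrogens,
PEG presence as an N-CH2-CH2-O attachment (serine-like side chains do
not match because their alpha carbon is not a CH2), and cyclization as a
macrocycle (ring of 7+, or a diketopiperazine-sized six-ring with two
non-aromatic nitrogens). The tests assert exact agreement between the
spec-derived and SMILES-derived descriptors, and that ordinary least
squares on the noiseless fixture recovers the planted coefficients to
machine precision.

What passing these experiments shows: the harness faithfully expresses
the experiment shape - generation, tokenization, pretraining,
embedding-based splitting, ensemble finetuning, cluster-held-out
scoring - and can recover a planted signal of realistic magnitude
through that entire path. What it does not show: performance on real
PAMPA data, whose structure-activity landscape is nonlinear,
conformation-dependent and assay-heterogeneous in ways a four-descriptor
linear fixture does not emulate; nor anything about the 23M-molecule
pretraining regime, which is orders of magnitude beyond desk scale.

## 6. Desk-scale problem sizes

The default `pipeline_config()` is sized so the full stack runs in
minutes on one CPU while leaving every stage scientifically meaningful:
2,000 generated molecules of at most 10 residues for pretraining; a
581-token budget; a 2-layer, 4-head, hidden-96 encoder trained 500 steps
at batch 32 and lr 1e-3; an 800-record fixture; k candidates 2..6; and
finetuning at lr 1e-3, batch 16, at most 200 steps per fold with
patience 4. The tiny model needs a learning rate three orders of
magnitude above the published finetuning value because it is small and
trained from a short pretraining run rather than a converged
44M-parameter checkpoint; the published values remain the documented
function defaults. Every stage persists its artifact with a hash of the
configuration that produced it, so interrupted runs resume and stale
artifacts are regenerated with a warning.

## 7. Known limitations

* The residue library covers 32 residues, not the hundreds of known
  non-natural side chains; thiol-mediated sidechain-to-head/tail
  closures and beta stereocenters (Thr, Ile) are not modeled.
* The generator excludes N-methylation of the N-terminal alpha-amine by
  construction (it is an amine, not an amide) and does not model
  PEGylation of secondary amines.
* Greedy longest-match segmentation is not guaranteed optimal for a
  frequency-ranked vocabulary, only standard.
* Embedding-based clusters on a desk-scale model can be few and
  unbalanced; single-class or near-single-class held-out clusters make
  ranking metrics noisy, which is a property of the protocol, not a bug.
* The compiled and interpreted encoders are numerically equivalent, but
  only the interpreted path is written for readability; treat it as the
  specification of the math.
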