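# peplm

Chemical language modeling for therapeutically modified peptides, in R.

Peptide drugs increasingly carry chemistry that sequence-based models
cannot express: non-natural side chains, D-stereocenters, backbone
N-methylation, PEGylation, and cyclizations (head-to-tail lactams,
side-chain lactams, disulfide bridges). `peplm` treats such molecules as
SMILES strings and provides the full method stack for modeling them:

1. **Generator** — stochastic sampling of modified, optionally cyclic
   peptides and residue-by-residue realization as canonical SMILES
   (90/10 natural/unnatural residues, 10% D-α-carbons, N-methylation of
   20% of backbone amides on 20% of peptides, PEGylation of 20% of
   peptides with 1–4 ethylene-glycol monomers, five cyclization
   chemistries with graceful fallback to linear).
2. **Tokenizer** — atom-aware pretokenization (Cl/Br and `[...]` kept
   whole) plus a frequency-ranked n-gram vocabulary of up to 5-character
   motifs, with the five special tokens `[PAD] [UNK] [CLS] [SEP] [MASK]`
   fixed at ids 0–4 (581 learned/base tokens + 5 specials = 586 by
   default).
3. **Encoder + MLM pretraining** — a post-layer-norm BERT-style
   transformer with rotary position embeddings (RoPE); masked-language
   modeling with the 15% / 80-10-10 corruption scheme, AdamW, held-out
   validation reporting cross-entropy and macro-averaged accuracy. The
   full-size configuration (6 layers, 12 heads, hidden 768, FFN 3072,
   context 768) instantiates at ≈43.5M parameters. Forward/backward are
   written in base-R matrix algebra (gradient-checked) with an
   equivalent RcppArmadillo fast path.
4. **Permeability evaluation** — PAMPA-style table ingestion and
   cleaning (assay filter, removal of the −10 "undetectable" marker),
   mean-pooled embeddings, PCA to 99% variance, k-means with
   silhouette/Davies–Bouldin/Calinski–Harabasz model selection,
   *leave-one-cluster-out* splits with 5-fold ensemble finetuning of a
   scalar regression head (MSE; best-validation checkpoint), and scoring
   as ROC-AUC / PR-AUC at the log10 P = −5.5 permeability cutoff plus
   RMSE, aggregated as mean ± SD over held-out clusters.
5. **Synthetic fixture** — a permeability panel with a planted linear
   structure→permeability relation over SMILES-recomputable descriptors
   (residue count, N-methyl count, PEG flag, macrocycle flag) plus
   Gaussian noise, so the entire pipeline is testable without any
   download.

Everything runs at desk scale on one CPU; all randomness is seeded.

## Worked example

```r
library(peplm)

lib  <- load_residue_library()                      # 20 natural + 12 unnatural residues
peps <- generate_peptides(500, lib, generator_config(max_length = 8), seed = 7)
peps[1:3, c("smiles", "length", "cyclization", "n_methyl", "pegylated")]
#> 1 N=C(N)NCCC[C@H](NC(=O)[C@H](CCC(=O)O)NCCOCCOCCO)C(=O)O        2 linear       0 TRUE
#> 2 CC[C@@H]1NC(=O)[C@@H](CCC(N)=O)NC(=O)[C@H](CC(=O)O)NC(=O)...  8 head_to_tail 0 FALSE
#> 3 CSCC[C@H](N)C(=O)N1CCC[C@H]1C(=O)N[C@@H](Cc1c[nH]cn1)C(=O)... 5 linear       0 FALSE

round(corpus_summary(peps)[, 3:8], 3)
#>   frac_unnatural frac_d frac_cyclic frac_nmethyl_amides frac_pegylated_of_free max_peg_monomers
#> 1          0.086  0.093       0.266               0.036                  0.221                4
```

The first row is a PEGylated Glu–Arg dipeptide (`NCCOCCOCCO` is the
3-monomer PEG chain on the backbone amine); the second closed
head-to-tail into a macrocycle (ring-closure digit `1` spanning the
backbone). Over the batch, the empirical modification rates sit at their
configured values — 8.6% unnatural residues (target 10%), 9.3% D
stereocenters (10%), 3.6% methylated amides (4%), 22.1% PEGylation among
peptides with a free amine (20%) — within binomial noise for n = 500.

```r
vocab <- train_vocabulary(peps$smiles, tokenizer_config(budget = 581))
vocab
#> <smiles_vocabulary> 231 tokens (5 special, 15 base, 211 learned)
enc <- encode_smiles(peps$smiles[1], vocab, context_len = 64)
identical(as.character(decode_ids(enc, vocab)), peps$smiles[1])
#> TRUE
```

A 500-molecule corpus only supports 211 learned n-grams (the budget is a
ceiling, not a quota); encoding compresses the 55-character first
molecule to 19 tokens and decoding reproduces it exactly.

The full experiment — generate a corpus, train the tokenizer, pretrain
the encoder, plant a permeability panel, cluster its embeddings, and run
leave-one-cluster-out ensemble finetuning — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
res$report          # per-cluster and aggregate ROC-AUC / PR-AUC / RMSE
autoplot(res$report)  # predicted vs experimental logP per held-out cluster
```

`tidy()`/`glance()` methods cover the fitted objects (`mlm_fit`,
`cluster_plan`, `locv_eval_report`), and `autoplot()` draws the training
curve, the PCA cluster map, and the held-out prediction panels.

A command-line front end wrapping the same functions lives at
`inst/cli/peplm.R` (subcommands `generate`, `tokenize`, `pretrain`,
`split`, `finetune`, `evaluate`, `run-all`, `make-fixture`).

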