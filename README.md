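# ncidta

Explainable protein–ligand binding-affinity regression in R, built around a
cross-modal attention mechanism that is *regularized by non-covalent
interactions* (NCIs).

## The problem and the model

Predicting how tightly a small molecule binds a protein is a core task in
drug discovery, and attention-based deep models are popular because their
attention maps promise interpretability. In practice unconstrained
attention rarely aligns with the physical contacts (hydrogen bonds, salt
bridges, π-stacking, ...) that actually stabilize a complex. `ncidta`
implements an architecture that makes the alignment explicit:

* A protein is a set of `m` residue embeddings `R ∈ R^{m×d}` (a trainable
  21-symbol fallback encoder, or embeddings from a protein language model
  supplied offline).
* A ligand is the set of `n` chemical substructures marked by the set bits
  of its 1024-bit hashed circular (Morgan-type) fingerprint; each bit owns
  a trainable embedding, giving `S ∈ R^{n×d}`.
* A trainable **pseudo-substructure** vector `p` is appended as the last
  key/value row, `S+ = [S; p]`. Multi-head *additive* attention
  (`score = wᵀ tanh(W_q q + W_k k)`, 4 heads) from residues onto `S+`
  refines the residues:

  `H = LN(R + RFF1(MultiAttn(R, S+, S+)))`, `R* = LN(H + RFF2(R))`

* Pooling by multihead attention (`u = 2` trainable seed vectors)
  aggregates `R*` into one complex embedding, and a two-layer MLP outputs
  the predicted log-affinity (pK units: `-log10` molar).

The head-averaged attention map `Ā ∈ R^{m×(n+1)}` is row-stochastic, and
the **NCI score** of residue `i` is its mass on real substructures,
`k̂_i = Σ_{c≤n} Ā_{ic} = 1 − Ā_{i,n+1}`. Training minimizes

```
L = MSE(ŷ, y) + α · BCE(k̂, k)
```

where `k` are binary residue labels ("has ≥1 NCI with the ligand",
collapsed from an interaction profiler's residue×atom matrix). The BCE
term steers non-interacting residues onto the pseudo key, so the fitted
attention map separates interacting from non-interacting residues and can
be read as an NCI probability track. `α = 0` is the no-regularization
ablation; `freeze_encoder` freezes the protein encoder.

The package provides the full surrounding workflow: curation filters
(≤1000 residues, exact values only), pK normalization, NCI label
conversion, 5-fold and holdout splits with Bemis–Murcko unseen-scaffold
subsets, padded batch collation, a seeded Adam training engine with early
stopping and fine-tuning, regression metrics (RMSE/MAE/Pearson/
concordance index) plus residue-level AUROC, attention-map truncation and
TSV/JSON export, and a synthetic-data generator with planted
residue-motif ↔ substructure interaction rules for end-to-end validation
without any external data.

## Worked example

Train a small model on a synthetic world with planted interaction rules,
and check that the attention recovers them:

```r
library(ncidta)

world <- generate_world(n_motifs = 4, seed = 7)
train <- generate_dataset(world, 600, seed = 8)
test  <- generate_dataset(world, 150, seed = 9)

cfg <- dta_config(d = 32, heads = 4, u = 2, alpha = 5, lr = 6e-3,
                  batch_size = 32, max_epochs = 8, seed = 1)
fit <- dta_fit(train, cfg)
fit
evaluate(fit, test)[c("rmse", "ci", "residue_auroc")]
```

```
Cross-attention affinity model
  d=32 heads=4 u=2 alpha=5 (KIKD), encoder: fallback
  trained 8 epochs (best 6), val RMSE 1.4507, 570 train / 30 val instances
$rmse
[1] 1.378793

$ci
[1] 0.7210738

$residue_auroc
[1] 0.9598487
```

The held-out RMSE (1.38 pK units, against a predict-the-mean baseline of
1.89) and concordance index (0.72: the probability that the predicted
ordering of two complexes matches the true ordering) show the affinity
signal being learned from a short run on 600 instances; the residue AUROC
of 0.96 is the probability that an interacting residue outranks a
non-interacting one by NCI score — values near 1 mean the attention map
has located the planted motifs. The larger, seeded experiment in
`scripts/acceptance.R` (2000 instances, 12 epochs) reaches residue AUROC
≈ 0.98 and RMSE ≈ 0.27 × baseline. Inspect one complex:

```r
e <- extract_map(fit, test[[1]])
tr <- truncate_map(e$map, e$scores, test[[1]]$nci_labels, threshold = 0.5)
export_map(tr$map, "map_example", scores = tr$scores, labels = tr$labels,
           positions = tr$positions)
```

which writes `map_example.tsv` (substructure × residue table with "NCI
Score" and "Actual NCI Label" rows) and `map_example.json` (full-precision
weights).

Real data enter through `read_dataset()` (FASTA + affinity TSV + NCI pair
TSV in the layout `write_dataset()` emits), `curate()` and
`smiles_to_substructure_indices()`. A thin CLI covering
`synth|train|finetune|evaluate|explain` is installed at
`inst/cli/ncidta`.

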