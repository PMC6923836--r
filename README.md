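# sigunet

Signal peptides are short N-terminal sequences (roughly 11–27 residues)
that commit a protein to the secretory pathway and are cleaved from the
mature protein. Recognizing them from sequence alone is a first step in
locating and characterizing proteins, and the classic failure mode is
mistaking an N-terminal transmembrane helix — which is also hydrophobic —
for a signal peptide.

`sigunet` approaches the problem as **per-residue semantic segmentation**
rather than whole-sequence classification. A fully convolutional 1D
U-Net (SigUNet) maps the first 96 residues of a protein, one-hot encoded
as a 96 × 20 matrix, to a 96 × 3 matrix of per-position probabilities
over the classes

* **S** — the residue lies in a signal peptide,
* **T** — the residue lies in a transmembrane region,
* **N** — neither.

The whole-sequence call is then made by a consecutive-residue rule: the
protein is called a signal peptide when every residue of some window of
4 consecutive positions has S-probability above a threshold τ, i.e. when

```
score = max_i  min( p_S[i], p_S[i+1], p_S[i+2], p_S[i+3] )  >  τ
```

The package is a complete desk-scale implementation of the method:

* the 96 × 20 / 96 × 3 encodings with zero rows for unknown residues and
  zero padding (`encode_sequence()`, `encode_labels()`);
* the SigUNet architecture family — linear channel schedule (starting at
  *m*, increasing by *n* per pooling level), average pooling, skip
  concatenation, transposed-convolution upsampling — plus the reduced
  SigUNet-light and the U-Net-1D ablation baseline with the doubling
  schedule and max pooling (`build_network()`, `count_parameters()`);
* training by the amino-acid-level cross entropy
  `Loss(x, y) = −Σᵢ₌₁⁹⁶ Σⱼ₌₁³ yᵢⱼ ln h(x)ᵢⱼ` with Adam and early
  stopping (`train_model()`); the forward pass, backpropagation and the
  optimizer are implemented in R over BLAS matrix products, and the
  gradients are verified against finite differences in the test suite;
* the nested cross-validation protocol (outer k = 5; hyper-parameters
  selected by an inner (k−1)-fold loop; the k−1 inner models ensembled
  by averaging their probability matrices on the outer test partition)
  (`nested_cv()`);
* the evaluation indices MCC, FPR_TM, precision, recall and F1
  (`evaluate_predictions()`);
* a synthetic benchmark generator emulating the n/h/c-region grammar of
  signal peptides, N-terminal transmembrane helices and soluble
  negatives (`generate_dataset()`), so the whole method is trainable and
  testable without any external data.

## Worked example

Generate a labeled synthetic benchmark, train SigUNet-light, and
evaluate the held-out proteins:

```r
library(sigunet)

recs    <- generate_dataset(synthetic_spec(n_sp = 400, n_tm = 300,
                                           n_other = 300, seed = 42))
samples <- encode_records(recs)

fit <- train_model(samples[1:800], samples[801:900],
                   sigunet_light_config(),
                   train_config(max_epochs = 20, patience = 5, seed = 1))

held  <- samples[901:1000]
preds <- predict_records(fit, held, decision_config(threshold = 0.5))
head(preds[, c("id", "score", "is_sp", "sp_end")], 5)
#>        id        score is_sp sp_end
#> 1 tm_0294 0.1513833923 FALSE     NA
#> 2 sp_0247 0.9920354398  TRUE     24
#> 3 tm_0223 0.0006089331 FALSE     NA
#> 4 tm_0154 0.1237660632 FALSE     NA
#> 5 bg_0202 0.0002278275 FALSE     NA
```

`score` is the max–min window statistic above; `sp_end` is the last
residue of the predicted leading S-run — the predicted cleavage
position (here residue 24 for `sp_0247`). Training stops early (epoch
15, best validation epoch 10) and the held-out evaluation

```r
truth <- data.frame(id = sapply(held, `[[`, "source_id"),
                    true_is_sp = sapply(held, `[[`, "true_is_sp"),
                    true_is_tm = sapply(held, `[[`, "true_is_tm"))
ev <- evaluate_predictions(truth, preds[, c("id", "is_sp")])
```

prints `MCC 100.0%  FPR_TM 0.0%  Precision 100.0%  Recall 100.0%
F1 100.0%` — the synthetic classes are cleanly separable at this size.
A transmembrane protein miscalled as a signal peptide would raise
`FPR_TM`, the index that specifically tracks that confusion.

The same workflows are scriptable from a shell via the installed
wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "sigunet.R", package = "sigunet"))')" \
    generate --n-sp 100 --n-tm 50 --n-other 50 --seed 1 --out data/
```

with subcommands `generate`, `train`, `predict`, `evaluate` and
`nested-cv`; every run writes a `manifest.json` with the resolved
configuration and seed.

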