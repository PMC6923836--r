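---
title: "Signal peptide recognition by per-residue segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal peptide recognition by per-residue segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigunet)
```

## The problem and the modeling idea

A signal peptide is an N-terminal targeting sequence of roughly 11–27
residues, organized as a positively charged n-region (about 1–5
residues), a hydrophobic h-region (about 7–15) and a polar c-region
(about 3–7) ending at the cleavage site, with a preference for small
residues at the −3 and −1 positions. Its main impostor is the
N-terminal transmembrane helix, which shares the hydrophobic core but
has no cleavage site and is typically longer.

`sigunet` treats recognition as semantic segmentation: instead of one
label per protein, the network emits a class for *every* residue of the
N-terminus — signal peptide (S), transmembrane (T) or neither (N). The
protein-level decision is then a simple, interpretable rule on the
S-probability track. Segmenting rather than classifying exposes the
transmembrane class explicitly, which is what lets the model keep the
transmembrane false-positive rate low.

## Input and output encodings

Only the first 96 residues are used; signal peptides live at the
N-terminus, so nothing of interest is lost and the input becomes a fixed
96 × 20 matrix. Row *i* is the one-hot vector of residue *i* in the
fixed alphabetical column order `ACDEFGHIKLMNPQRSTVWY`; this order is a
package convention (any fixed order works) and is stable across
versions. Unknown or ambiguous residues (X, and likewise B, Z, U, O)
become all-zero rows, as do padding rows beyond the sequence length.
Labels are a 96 × 3 one-hot matrix in channel order (S, T, N).

Padded positions are labeled N rather than left unlabeled, so every row
of the label matrix is a valid one-hot vector and the loss below is a
well-defined sum of exactly 96 terms. An optional mask (`n_valid` /
`mask_padding`) excludes padded positions instead; it is off by default
because the fixed-length sum is the simpler contract and teaches the
network to emit N on padding, which is harmless at decision time. For
sequences at least 96 residues long the two choices coincide.

## Architecture

The network is a 1D U-Net: an encoder of `depth` resolution levels, each
with `convs_per_level` length-preserving (same-padded) convolutions with
ReLU followed by a size-2 pooling; a bottleneck; and a mirrored decoder
that doubles the resolution with size-2 stride-2 transposed convolutions
and concatenates the same-resolution encoder output (skip connection)
before its convolutions. A final 1 × 1 convolution maps to 3 channels
and a per-position softmax normalizes each row. Because all
convolutions are same-padded, skip connections need no cropping and the
output length equals the input length, 96 — one probability row per
residue.

Two choices distinguish SigUNet from a naive 1D transcription of U-Net:

* **Channel schedule.** The original U-Net starts at 64 channels and
  doubles after every pooling, which makes the weight count grow
  exponentially and overfits small protein datasets. SigUNet's channel
  count starts at *m* and grows *linearly* by *n* per level; *m* and
  *n* are ordinary hyper-parameters.
* **Average pooling.** Max pooling can erase a residue's contribution
  entirely when a neighbor dominates; on the hypothesis that every
  amino acid carries information, SigUNet pools by averaging. The max
  variant is retained as a configuration (`pooling = "max"`), and the
  `unet1d` variant (doubling schedule + max pooling) reproduces the
  ablation baseline.

Repository defaults, chosen so the closed-form weight counts land inside
the published size bands for the two models:

```{r}
count_parameters(sigunet_config())        # m = 24, n = 24, depth 3
count_parameters(sigunet_light_config())  # m = 20, n = 20, depth 3
```

SigUNet (m = 24, n = 24, depth 3, kernel 3, two convolutions per level)
has 184,443 trainable weights, inside the 100,000–300,000 band;
SigUNet-light (m = 20, n = 20) has 128,423, inside 60,000–200,000. The
exact per-figure layer counts of the original description are not
recoverable from text, so these bands are the binding constraint; both
configurations are fully overridable. `count_parameters()` is a closed
form (k·c_in·c_out + c_out per convolution, 2·c_in·c_out + c_out per
transposed convolution, c_in·3 + 3 for the final layer) and is checked
against exhaustive enumeration of the built model's arrays in the test
suite.

Other architectural defaults where the source is silent: kernel size 3
(the 1D analog of U-Net's 3 × 3 convolutions); transposed convolution
with ReLU as the upsampling operator (the "up-conv 2 × 2" analog);
He-uniform weight initialization for ReLU layers with zero biases; no
batch normalization or dropout.

## Loss and training

Training minimizes the amino-acid-level cross entropy

$$\mathrm{Loss}(x, y) = -\sum_{i=1}^{96} \sum_{j=1}^{3} y_{ij}
\ln h(x)_{ij},$$

averaged over the mini-batch, where $h(x)$ is the 96 × 3 network output.
Probabilities are clipped to $[10^{-7}, 1]$ before the logarithm — pure
numerical safety, far below any reportable precision. The per-residue
(rather than per-protein) loss provides 96 gradient terms per sequence
and is part of why training is stable.

The optimizer is Adam (β₁ = 0.9, β₂ = 0.999), learning rate 10⁻³, batch
size 64, at most 200 epochs, stopping when the validation loss has not
improved for 10 consecutive epochs and restoring the best-epoch weights.
None of these values are prescribed by the method description; they are
conventional defaults and all are configurable. All randomness — weight
initialization and batch shuffling — derives from the single
`train_config()` seed, so a fit is exactly reproducible.

The forward and backward passes are implemented directly in R: a batch
is a sample-blocked (B·L) × C matrix, convolutions are im2col plus one
BLAS matrix product, and the backward pass is exact (a finite-difference
test in the suite checks every layer type; the only caveat is the ReLU
kink, where the subgradient is arbitrary).

## The decision rule

The 96 × 3 output is reduced to a protein-level call by the
consecutive-residue rule: the protein is a signal peptide when the
probability of **any four consecutive residues** being signal peptide
exceeds a threshold. The package reads "any four consecutive amino
acids" as *each residue individually*, i.e. the window minimum must
clear the bar, so

$$\mathrm{score} = \max_i \; \min_{0 \le d < 4} \; p_S[i + d], \qquad
\text{call} \iff \mathrm{score} > \tau \;(\text{strict}).$$

The min reading is the stricter, more literal interpretation; a
window-mean statistic is available (`statistic = "mean"`) for
comparison, and the window length (4) is exposed for ablation. The
threshold τ is a hyper-parameter on the same footing as *m* and *n*,
selected by nested cross validation in the full protocol; 0.5 is the
neutral default elsewhere. The score is monotone in both threshold and
window length (property-tested against exhaustive window enumeration).

Per-residue segmentation labels each position by its argmax channel with
ties broken S > T > N (so a maximally uncertain model errs on the side
of the positive class, which the protein-level rule can still reject),
and reports the end of the leading S-run as the predicted cleavage
position.

## Nested cross validation

The evaluation protocol is an outer k = 5 cross validation whose
hyper-parameters are chosen without peeking at the test partition: for
each outer fold, the remaining k − 1 partitions serve as the folds of an
inner (k−1)-fold cross validation; every candidate (network
configuration, threshold) is trained k − 1 times and scored by its mean
inner-validation MCC at its own threshold; the winning candidate's k − 1
inner models are applied to the outer test partition and their
probability matrices are arithmetically averaged **before** the decision
rule. The package reads the protocol literally: the inner models are
reused as the ensemble, with no retraining on the full outer training
set.

Interpretation choices: the inner selection metric (unstated in the
protocol description) is MCC, the headline index, with ties broken by
smaller weight count, then smaller threshold — preferring the simpler
model and the more conservative rule. Fold assignment is stratified by
protein-level class (SP / TM / other) under the plan seed so that the
rare transmembrane class reaches every fold; homology-aware partitioning
belongs to dataset construction, which is out of scope. Leakage freedom
(outer test ids never appear in any inner training or validation set)
is asserted at run time and property-tested with stub models.

## Evaluation indices

With signal peptide as the positive class:

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}, \qquad
FPR_{TM} = \frac{FP_{TM}}{N_{TM}},$$

plus precision TP/(TP+FP), recall TP/(TP+FN) and
F1 = 2TP/(2TP+FN+FP) (identical to the harmonic mean of precision and
recall; both forms are computed and compared in the tests). FPR_TM is
tallied only over the transmembrane negatives and isolates the
signal-peptide/transmembrane confusion that overall indices dilute.
Degenerate denominators (no predicted positives, no transmembrane
proteins) map to 0 rather than NaN, keeping reports total; this is the
common MCC convention. The command-line reports print all indices as
percentages to one decimal.

## The synthetic benchmark generator

The generator emulates exactly the structure the recognizer exploits:

* **sp** records: M, then an n-region of 1–5 residues biased to K/R
  (70% charged, 30% polar), an h-region of 7–15 uniformly hydrophobic
  residues {A,I,L,F,V,W,M}, a c-region of 3–7 polar residues
  {S,T,G,N,Q} with A forced at −3 and −1 before the cleavage site, then
  a mature region of 30–150 background residues. Labels are S through
  the cleavage site, N after; the S-run is thus 12–28 positions
  including the initiator M.
* **tm** records: M, a background prefix, one hydrophobic helix of
  15–25 residues starting within the first 70 positions labeled T, and
  a background tail; no S labels anywhere.
* **other** records: M plus background composition, all N.

Background composition is uniform over the 20 residues, and region
compositions are fixed alphabets — deliberate simplifications, since
no residue frequencies are prescribed for the method, chosen once to
make the classes learnable and the generator fully documentable.
`generate_dataset()` is a pure function of its spec (including the
seed).

What the generator does **not** emulate: real organism-specific residue
frequencies, homology structure between sequences, mixed SP+TM
topologies, and cleavage-site sequence diversity beyond the fixed A at
−3/−1. Passing the end-to-end test therefore shows that the
implementation learns and recovers the class structure it was built
for — near-perfect separation of sharply drawn classes is expected, and
published benchmark performance on real proteomes is *not* implied.

## Problem sizes and numerical choices in the shipped tests

The end-to-end parameter-recovery test trains SigUNet-light on 2,000
synthetic records (40% SP / 30% TM / 30% other; 1,700/300 train/val)
and evaluates 500 held-out proteins, requiring protein-level MCC ≥ 0.9
and FPR_TM ≤ 0.1. It runs 15 epochs with patience 5 — at this dataset
size the validation loss plateaus within ten epochs, so the short
schedule is the package's desk-scale choice, not a tuned quantity; the
shipped run reaches MCC ≈ 1 with margin. Unit tests use a miniature
configuration (m = 4, n = 4, depth 2, one convolution per level) for
speed; the gradient check uses an even smaller network with jittered
weights and dense inputs to stay off ReLU kinks.

## Known limitations

* Pure-R training is CPU-bound; desk-scale datasets (a few thousand
  96-residue sequences) train in minutes, but proteome-scale training
  would want a compiled backend.
* The fixed 96-residue horizon means a signal peptide is only ever
  sought in the N-terminal window — by design, but it makes the tool
  inapplicable to internal targeting signals.
* The generator's sharply separable classes make absolute synthetic
  metrics optimistic; they validate the machinery, not biological
  accuracy.
* Only single-label topologies are modeled: proteins that have both a
  signal peptide and downstream transmembrane helices are outside the
  generator (though the network itself can represent them).
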