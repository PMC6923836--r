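Package: sigunet
Title: Signal Peptide Recognition by 1D U-Net Semantic Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recognizes signal peptides in protein N-termini by per-residue
    semantic segmentation with a fully convolutional 1D U-Net (SigUNet).
    Each of the first 96 residues is classified as signal peptide (S),
    transmembrane (T) or neither (N), and a whole-sequence call is made by a
    consecutive-residue threshold rule. Includes the amino-acid-level
    cross-entropy training loop with early stopping, a nested
    cross-validation protocol with inner-model ensembling, the MCC and
    transmembrane false-positive-rate evaluation indices, and a synthetic
    benchmark generator that emulates the n/h/c-region grammar of signal
    peptides and N-terminal transmembrane helices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
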