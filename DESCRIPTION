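Package: chromexpr
Title: Accessibility-Augmented Sequence-to-Expression Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-cell-type gene expression probability (GEx, the
    proportion of cells of a cell type expressing a gene) from promoter DNA
    sequence augmented with a pooled, smoothed and min-max normalized
    ATAC-seq accessibility track supplied as a fifth input channel to a 1D
    convolutional neural network. Includes promoter extraction from
    FASTA/GTF, fragment-to-track pooling with Gaussian smoothing, GEx and
    auATAC computation from single-cell UMI matrices, gene-holdout
    cross-validated training with seed replicates, channel ablation and
    input-scrambling experiments, fine-tuning from sequence-only models,
    integrated-gradient attributions against dinucleotide-preserving
    shuffled backgrounds, k-mer attribution ranking, and a synthetic
    multiome generator for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
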