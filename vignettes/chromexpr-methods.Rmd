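---
title: "Accessibility-augmented sequence-to-expression modelling with chromexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accessibility-augmented sequence-to-expression modelling with chromexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sequence-to-expression models predict a gene's transcriptional output from
its promoter DNA alone. Chromatin accessibility is a rate-limiting context
that plain sequence models cannot see: the same promoter sequence is active
in one cell type and silent in another depending on whether it is open.
`chromexpr` implements the augmentation strategy of supplying a pooled,
cell-type-specific ATAC-seq track as a fifth input channel next to the
four-row one-hot DNA encoding of a TSS-centered promoter window, and the
evaluation machinery needed to quantify what that extra channel buys:
channel ablations, input scrambling controls, cross-cell-type and
highly-variable-gene evaluation, fine-tuning from a sequence-only model,
attribution analysis, and k-mer attribution ranking.

## Input representations

**Promoter windows.** One window per protein-coding gene, centered on the
TSS of the annotated canonical transcript, `flank` bases on each side
(default 1000, so 2 kb). Coordinates are 0-based half-open internally;
GTF input is 1-based inclusive and converted on read. On the minus strand
the window is reverse-complemented so the model always sees the coding
strand with the TSS at index `flank`. Genes whose window would cross a
chromosome end are dropped and logged, never padded. When the canonical
tag is missing, the transcript with the 5'-most TSS is used (ties broken
by transcript ID) and the fallback is logged.

**Accessibility tracks.** Per cell type, raw ATAC fragments are pooled
into per-base full-fragment coverage over each window (a cut-site counting
mode is available), smoothed with a Gaussian kernel (sd 20 bases,
truncated at 4 sd, half-sample-symmetric boundaries so total signal is
conserved), then min-max normalized with a *single* global minimum and
maximum across all windows of the cell type. Global rather than per-gene
normalization is essential: per-track scaling would erase between-gene
accessibility differences and make the auATAC summary (the per-base sum
of the normalized track) uninformative.

**Expression target (GEx).** The proportion of cells of the cell type with
a nonzero UMI count for the gene — a probability of expression in [0, 1],
robust to depth and comparable across cell types. The sigmoid output of
the model lives on the same scale.

## Model

A compact 1D CNN: conv blocks (convolution, optional per-filter batch
normalization, ReLU, max-pool), then either a flatten or a global
mean-pool, dense layers with ReLU and dropout, and a single sigmoid
output. The default configuration (two blocks of 128x6/pool4 and
32x9/pool4, dense 256 and 64, dropout 0.1) follows the compact
promoter-CNN family; every width, pooling and head choice is a
`model_config()` argument. Channel ablation never touches the
architecture beyond the first convolution's input channels, so the
parameter count difference between the DNA+ATAC and DNA-only models is
exactly `n_filters_1 * kernel_width_1` — an auditable invariant.

The engine (forward, backward, AdamW with decoupled weight decay,
batch-norm running statistics) is implemented in the package, with the
convolution/pooling/batch-norm hot paths in C++ (RcppArmadillo) and the
dense algebra on BLAS. Gradients are verified against finite differences
in the test suite.

## Training protocol

Five-fold gene-holdout cross-validation over the autosomal protein-coding
gene set; the test folds partition the genes and are identical for every
seed, while each replicate seed redraws the inner train/validation split
(10% validation), the weight initialization, the batch order and the
dropout masks. The reference recipe is MSE loss, AdamW with learning rate
5e-5 and weight decay 1e-3, batch size 512, 500 epochs, validation every 4
epochs. Fine-tuning initializes a 5-channel model from a trained DNA-only
model — every tensor copied except the first convolution's ATAC slice,
which is freshly initialized — and trains with learning rate 1e-5 and
weight decay 1e-4 for up to 200 epochs.

**Checkpoint selection.** Among the periodic validation evaluations the
package keeps the fully trained model whenever its validation MSE is
within one standard error of the minimum, and the minimizer otherwise
(the one-SE convention familiar from penalized regression). With small
validation sets the MSE differences between converged checkpoints are far
below their standard error, so a plain argmin amounts to picking a random
checkpoint — including barely-trained early ones whose outputs still carry
initialization artifacts. The selection rule is recorded in every
checkpoint.

## Desk-scale study configuration

The synthetic studies (below) need thirty-odd trainings on one CPU, so
they use a reduced configuration, exposed as
`reduced_model_config()`/`desk_train_config()` and used identically in
every arm of every study: window length 500, conv blocks 16x8/pool4 and
16x9/pool4 with batch normalization, a global mean-pool head, one dense
layer of 16, dropout 0.1; AdamW at learning rate 2e-3 with cosine decay,
weight decay 1e-3, batch size 128, 20 epochs, validation every 2 epochs.
Three choices deserve comment:

* *Global mean pooling* suits the synthetic signal, which is an
  occurrence-count times accessibility quantity, and cuts parameters
  roughly a hundredfold; the flatten head remains the default for
  full-scale runs.
* *Zero-initialized output head*: the untrained network then starts as
  exactly the constant predictor, so any input dependence of its output
  is learned, never inherited. Without it, models trained on scrambled
  (information-free) data retain a random projection of their
  initialization that can masquerade as correlation with accessibility.
* *Cosine decay* lets the weights settle; at a constant step size the
  output weights jitter at a scale set by the learning rate, which again
  contaminates the scrambled-control arms.

## The synthetic multiome generator

`synth_config()`/`synth_generate()` produce a dataset with known ground
truth so every claim the package makes can be checked without downloads:

* **Sequences**: i.i.d. background bases with per-gene GC content coupled
  to a latent basal openness (CpG-island-like promoters are broadly open
  — in real data, sequence composition is the dominant sequence-only
  correlate of expression, which is exactly the signal a DNA-only model
  learns first). Three real promoter motifs are planted (AP-1 TGACTC,
  E-box CACGTG, GC-box GGGCGG; near-consensus PWMs), Poisson counts per
  motif (rate 1.2), TSS-biased placement (Gaussian, sd 0.2 L), without
  overlaps.
* **Accessibility**: one or two Gaussian bumps near the window center,
  scaled by a per-gene, per-cell-type openness drawn around the basal
  openness (Beta-coupled, concentration 20, so accessibility correlates
  across cell types as in real multiome data), plus half-normal noise.
  Tracks then run through the *same* smoothing/normalization pipeline as
  real fragments.
* **Expression**:
  `GEx = logistic(w0 + wA * auATAC + sum_m beta_mc * sum_i abar_i)` where
  `abar_i` is the mean normalized accessibility over motif instance i's
  footprint — a motif-times-accessibility model: a motif only acts where
  chromatin is open. Defaults `w0 = -3`, `wA = 12/L`, `beta = 4`,
  Gaussian observation noise sd 0.05 (clipped to [0, 1]); a binomial mode
  (`Binomial(n_cells, GEx)/n_cells`) gives integer-consistent proportions
  matching a rendered UMI matrix.

Effect sizes were calibrated once so that the relative strengths of the
three input modalities mirror the real-data profile (accessibility a
strong predictor, sequence alone a moderate one, the combination best),
and not revisited. `render_raw_formats()` inverse-renders a synthetic
dataset as FASTA + fragments TSV + Matrix Market UMI counts so the real
input pipelines are exercised end to end.

What the generator does **not** emulate: nucleosome positioning and Tn5
bias, enhancer action at a distance, batch effects, doublets, and any
nonlinear motif grammar beyond additive motif-times-accessibility
effects. Passing the synthetic studies therefore demonstrates that the
machinery recovers a known signal of this shape at this noise level; it
does not by itself establish performance on real multiome data.

## The desk-scale studies

Run by `run_ablation_study()`, `run_scrambling_study()` and
`run_attribution_alignment()` on a default synthetic dataset of 3000
genes, L = 500, five replicates (one per fold):

* **Ablation**: held-out Pearson correlation ordering
  DNA+ATAC > ATAC-only > DNA-only, each gap tested by a one-sided
  Wilcoxon signed-rank test on per-gene squared errors (the held-out gene
  sets are preserved across model variants, so errors pair gene by gene).
* **Scrambling**: training/validation inputs permuted against their
  targets (test genes untouched). DNA-scrambled training degrades the
  augmented model to roughly ATAC-only performance, ATAC-scrambled to
  roughly DNA-only, and scrambling both leaves approximately no held-out
  correlation.
* **Attribution alignment**: integrated-gradient attributions against
  dinucleotide-preserving shuffled backgrounds (position-permuted ATAC
  rows), aggregated seed-then-gene as three stages; the DNA-channel
  positional profiles of the augmented model correlate with the ATAC
  input track more strongly than those of the DNA-only model.

## Attributions

Backgrounds preserve the dinucleotide composition of each sequence
exactly (uniform-random Eulerian rearrangements, Altschul–Erickson;
sequences containing N are shuffled segment-wise with N positions fixed)
and permute the ATAC track's positions independently per background.
Scores are background-averaged integrated gradients along the straight
path from each background to the sample (midpoint rule), which satisfies
the completeness identity — the scores sum to
`f(x) - mean_b f(b)` — and equals exact Shapley values for linear models.
`attribute(refine_tol =)` doubles the path resolution until the relative
completeness gap passes the tolerance. k-mer scores average the per-base
DNA attribution (summed over the four DNA channels) across each
instance's bases; forward-strand k-mers only, since orientation carries
signal.

## Numerical choices and edge cases

* Min-max normalization of an all-constant track set returns zeros.
* One-hot columns for N are all-zero (no 0.25 smearing); windows with
  other characters are rejected with the offending position.
* Spearman uses average ranks; undefined correlations (constant vectors)
  are reported as NaN with a warning, never imputed.
* The signed-rank test drops zero differences, computes exact p-values by
  dynamic programming over the sign-flip distribution for n <= 25 (exact
  under ties as well), and uses the tie-corrected normal approximation
  with continuity correction beyond.
* auROC counts ties as one half (Mann–Whitney normalization).
* k-mer rank ties break lexicographically; NaN-scored k-mers rank last
  and are flagged; top-fraction sizes use the ceiling.
* All randomness descends from one master seed through named substreams
  (`derive_seed`), so each stage is independently reproducible.

## Known limitations

The CNN engine is single-threaded CPU code: adequate for the reduced
configuration and for fine-tuning experiments, but full-scale runs (19k
genes, 2 kb windows, 500 epochs, 25 replicates) are an overnight affair
rather than an interactive one. The attribution backend is integrated
gradients rather than a learned-baseline SHAP variant; both satisfy the
completeness contract that the tests enforce, but per-position values can
differ from other attribution families. The highly-variable-gene selector
is a variance-to-mean dispersion rule, a documented stand-in for
pipeline-specific definitions. Variant-effect prediction reuses the
reference accessibility track for the alternative allele, which ignores
eQTLs that act by changing accessibility itself.
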