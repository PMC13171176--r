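# The synthetic ablation/scrambling/attribution studies are expensive (many
# CNN trainings), so they are run once per test session and shared across
# the test blocks that consume them.

.study_cache <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.study_cache$res)) return(.study_cache$res)
  cfg <- synth_config(n_genes = 3000L, L = 500L, seed = 11L)
  gen <- synth_generate(cfg)
  ds <- synth_dataset(gen)
  folds <- make_folds(ds$gene_ids, k = 5L, seeds = 1:5)
  abl <- run_ablation_study(ds, folds)
  scr <- run_scrambling_study(ds, folds, seed = 5L)
  .study_cache$res <- list(cfg = cfg, gen = gen, ds = ds, folds = folds,
                           abl = abl, scr = scr)
  .study_cache$res
}

alignment_fixture <- function() {
  if (!is.null(.study_cache$ali)) return(.study_cache$ali)
  st <- study_fixture()
  .study_cache$ali <- run_attribution_alignment(
    st$abl$checkpoints$dna_atac, st$abl$checkpoints$dna_only, st$ds,
    st$folds, n_genes_per_fold = 12L, n_backgrounds = 8L, n_steps = 32L,
    seed = 3L)
  .study_cache$ali
}
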