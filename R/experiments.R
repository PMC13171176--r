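# High-level experiment drivers: the ablation, scrambling and
# attribution-alignment studies run at desk scale on synthetic data. These
# are the same code paths a full-scale run would use, with a reduced model
# and training recipe sized for a single CPU.

#' Reduced-scale model and training configurations
#'
#' The desk-scale recipe used for synthetic studies: two conv blocks of 16
#' filters (widths 8 and 9, pool 4), a global-mean-pool head, one dense
#' layer of 16, dropout 0.1, sigmoid output; AdamW with learning rate 2e-3,
#' weight decay 1e-3, batch size 128, 20 epochs with cosine learning-rate decay,
#' validation every 2 epochs.
#' Small batches maximize the number of optimizer updates per unit compute,
#' which is what motif learning is limited by at this scale.
#'
#' @param input_channels 1, 4 or 5.
#' @param input_length window length.
#' @return a [model_config()].
#' @export
reduced_model_config <- function(input_channels, input_length = 500L) {
  model_config(input_channels = input_channels, input_length = input_length,
               conv_specs = list(c(16L, 8L, 4L), c(16L, 9L, 4L)),
               dense_sizes = c(16L), dropout = 0.1,
               output_activation = "sigmoid", global_pool = TRUE,
               batch_norm = TRUE, head_init_scale = 0)
}

#' @rdname reduced_model_config
#' @export
desk_train_config <- function() {
  train_config(lr = 2e-3, weight_decay = 1e-3, batch_size = 128L,
               max_epochs = 20L, val_every = 2L, lr_schedule = "cosine")
}

#' Channel-ablation study over CV folds
#'
#' Trains one replicate per fold (seed = fold index) for each channel mode
#' and evaluates on the unscrambled held-out test genes, collecting
#' per-fold metrics and the per-gene predictions over all folds.
#'
#' @param dataset a 5-channel `gex_dataset`.
#' @param folds a `fold_split`.
#' @param modes channel modes to train.
#' @param train_cfg a [train_config()].
#' @param model_cfg_fn function(input_channels, input_length) returning a
#'   [model_config()].
#' @return list with `per_fold` (data.frame mode/fold/pearson/spearman),
#'   `predictions` (per mode, named vector over all test genes), `truth`
#'   and the trained `checkpoints[[mode]][[fold]]`.
#' @export
run_ablation_study <- function(dataset, folds,
                               modes = c("dna_atac", "atac_only", "dna_only"),
                               train_cfg = desk_train_config(),
                               model_cfg_fn = reduced_model_config) {
  L <- dim(dataset$x)[1]
  rows <- list()
  predictions <- list()
  checkpoints <- list()
  truth <- stats::setNames(dataset$y, dataset$gene_ids)
  for (mode in modes) {
    ds <- ablate_channels(dataset, mode)
    cfg <- model_cfg_fn(dim(ds$x)[2], L)
    preds <- numeric(0)
    cks <- list()
    for (f in seq_len(folds$k)) {
      seed <- folds$seeds[((f - 1L) %% length(folds$seeds)) + 1L]
      ck <- train_model(cfg, train_cfg, ds, folds, f, seed)
      cks[[f]] <- ck
      test_ds <- subset_dataset(ds, ck$test_ids)
      p <- predict(ck$model, test_ds)
      m <- regression_metrics(test_ds$y, p)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, fold = f, n_genes = length(ck$test_ids),
        pearson = m$pearson, spearman = m$spearman, mse = m$mse, r2 = m$r2)
      preds <- c(preds, p)
    }
    predictions[[mode]] <- preds
    checkpoints[[mode]] <- cks
  }
  list(per_fold = do.call(rbind, rows), predictions = predictions,
       truth = truth, checkpoints = checkpoints)
}

#' Paired comparison of two model variants by per-gene squared error
#'
#' The held-out test genes are shared across model variants, so per-gene
#' squared errors are paired; the one-sided Wilcoxon signed-rank test asks
#' whether variant `better` has smaller errors than variant `worse`.
#'
#' @param study result of [run_ablation_study()] (or anything with
#'   `predictions` and `truth`).
#' @param better,worse names in `study$predictions`.
#' @return the [wilcoxon_one_sided()] result.
#' @export
compare_variants <- function(study, better, worse) {
  g <- intersect(names(study$predictions[[better]]),
                 names(study$predictions[[worse]]))
  err_b <- (study$predictions[[better]][g] - study$truth[g])^2
  err_w <- (study$predictions[[worse]][g] - study$truth[g])^2
  wilcoxon_one_sided(err_w, err_b, alternative = "greater")
}

#' Input-scrambling study over CV folds
#'
#' For each fold, the training and validation genes of the 5-channel
#' dataset are scrambled (DNA blocks, ATAC rows, or both pairwise /
#' separately) with respect to their targets; the held-out test genes stay
#' untouched, and evaluation uses the unscrambled test set.
#'
#' @param dataset a 5-channel `gex_dataset`.
#' @param folds a `fold_split`.
#' @param variants named list of `list(what =, mode =)` scrambles to run.
#' @param train_cfg,model_cfg_fn as in [run_ablation_study()].
#' @param seed base seed for the scrambling permutations.
#' @return same layout as [run_ablation_study()].
#' @export
run_scrambling_study <- function(dataset, folds,
                                 variants = list(
                                   dna_scrambled = list(what = "dna", mode = "separate"),
                                   atac_scrambled = list(what = "atac", mode = "separate"),
                                   both_scrambled = list(what = "both", mode = "pairwise")),
                                 train_cfg = desk_train_config(),
                                 model_cfg_fn = reduced_model_config,
                                 seed = 1L) {
  L <- dim(dataset$x)[1]
  cfg <- model_cfg_fn(5L, L)
  rows <- list()
  predictions <- list()
  checkpoints <- list()
  truth <- stats::setNames(dataset$y, dataset$gene_ids)
  for (v in names(variants)) {
    spec <- variants[[v]]
    preds <- numeric(0)
    cks <- list()
    for (f in seq_len(folds$k)) {
      non_test <- setdiff(dataset$gene_ids, folds$test[[f]])
      ds_sc <- scramble(dataset, what = spec$what, mode = spec$mode,
                        seed = derive_seed(seed, v, f), which_ids = non_test)
      sseed <- folds$seeds[((f - 1L) %% length(folds$seeds)) + 1L]
      ck <- train_model(cfg, train_cfg, ds_sc, folds, f, sseed)
      cks[[f]] <- ck
      test_ds <- subset_dataset(dataset, ck$test_ids)  # unscrambled test
      p <- predict(ck$model, test_ds)
      m <- regression_metrics(test_ds$y, p)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = v, fold = f, n_genes = length(ck$test_ids),
        pearson = m$pearson, spearman = m$spearman, mse = m$mse, r2 = m$r2)
      preds <- c(preds, p)
    }
    predictions[[v]] <- preds
    checkpoints[[v]] <- cks
  }
  list(per_fold = do.call(rbind, rows), predictions = predictions,
       truth = truth, checkpoints = checkpoints)
}

#' Positional attribution alignment with the ATAC input
#'
#' For each fold, attributes a deterministic subset of held-out test genes
#' under two model variants (typically DNA+ATAC and DNA-only), aggregates
#' the positional profiles, and reports the mean Spearman correlation of
#' the DNA-channel profiles with the mean ATAC input track of the same
#' genes.
#'
#' @param checkpoints_a,checkpoints_b per-fold checkpoint lists (e.g.
#'   `study$checkpoints$dna_atac` and `$dna_only`).
#' @param dataset the 5-channel `gex_dataset`.
#' @param folds a `fold_split`.
#' @param n_genes_per_fold genes attributed per fold (first by sorted ID).
#' @param n_backgrounds backgrounds per gene.
#' @param n_steps integrated-gradient path steps.
#' @param seed background seed.
#' @return data.frame with fold, dna_spearman_a, dna_spearman_b.
#' @export
run_attribution_alignment <- function(checkpoints_a, checkpoints_b, dataset,
                                      folds, n_genes_per_fold = 12L,
                                      n_backgrounds = 8L, n_steps = 32L,
                                      seed = 1L) {
  score_fold <- function(ck, f, ids) {
    model <- ck$model
    C <- model$config$input_channels
    attrs <- lapply(ids, function(g) {
      x5 <- dataset$x[, , match(g, dataset$gene_ids)]
      x <- if (C == 5L) x5 else x5[, 1:4, drop = FALSE]
      bg <- make_backgrounds(x, n = n_backgrounds,
                             seed = derive_seed(seed, g, f))
      attribute(model, x, bg, n_steps = n_steps, gene_id = g, fold = f,
                seed = ck$seed)
    })
    agg <- aggregate_positional(attrs)
    track <- rowMeans(vapply(ids, function(g)
      dataset$x[, 5L, match(g, dataset$gene_ids)],
      numeric(dim(dataset$x)[1])))
    cors <- channel_track_correlation(agg$profile, track)
    mean(cors[c("A", "C", "G", "T")])
  }
  rows <- lapply(seq_len(folds$k), function(f) {
    ids <- head(sort(intersect(folds$test[[f]], dataset$gene_ids)),
                n_genes_per_fold)
    data.frame(fold = f,
               dna_spearman_a = score_fold(checkpoints_a[[f]], f, ids),
               dna_spearman_b = score_fold(checkpoints_b[[f]], f, ids))
  })
  do.call(rbind, rows)
}
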