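#' Training hyperparameters
#'
#' Defaults follow the headline training recipe: AdamW (decoupled weight
#' decay), learning rate 5e-5, weight decay 1e-3, batch size 512, 500
#' epochs, validation loss every 4 epochs with best-checkpoint selection and
#' MSE loss. [fine_tune_config()] carries the fine-tuning overrides:
#' learning rate 1e-5, weight decay 1e-4, at most 200 epochs.
#'
#' @param lr learning rate.
#' @param weight_decay decoupled (AdamW-style) weight decay.
#' @param batch_size minibatch size.
#' @param max_epochs number of epochs; no early stopping beyond
#'   best-checkpoint selection.
#' @param val_every validation cadence in epochs (must not exceed
#'   `max_epochs`).
#' @param lr_schedule "constant", or "cosine" for a cosine decay of the
#'   learning rate from `lr` to near zero over the run. Decay lets the
#'   weights settle instead of jittering at the initial step size.
#' @return a `train_config` object.
#' @export
train_config <- function(lr = 5e-5, weight_decay = 1e-3, batch_size = 512L,
                         max_epochs = 500L, val_every = 4L,
                         lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1L, max_epochs >= 1L,
            val_every >= 1L, val_every <= max_epochs)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_every = as.integer(val_every),
                 lr_schedule = lr_schedule),
            class = "train_config")
}

#' @rdname train_config
#' @export
fine_tune_config <- function(lr = 1e-5, weight_decay = 1e-4,
                             batch_size = 512L, max_epochs = 200L,
                             val_every = 4L) {
  train_config(lr, weight_decay, batch_size, max_epochs, val_every)
}

#' Build the five-fold gene-holdout cross-validation splits
#'
#' Test folds partition the gene set and are identical for every seed; only
#' the inner train/validation splits vary by seed. The whole object is
#' deterministic given `fold_seed` and `seeds`, and serializes bit-exactly
#' via [save_folds()]/[load_folds()].
#'
#' @param gene_ids unique character gene IDs.
#' @param k number of test folds (>= 2).
#' @param seeds integer vector of replicate seeds for the inner splits.
#' @param val_fraction fraction of non-test genes used for validation.
#' @param fold_seed seed fixing the test-fold assignment.
#' @return a `fold_split` object.
#' @export
make_folds <- function(gene_ids, k = 5L, seeds = 1:5, val_fraction = 0.1,
                       fold_seed = 1L) {
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  stopifnot(k >= 2L, length(gene_ids) >= k, val_fraction > 0, val_fraction < 1)
  shuffled <- with_seed(derive_seed(fold_seed, "fold-assignment"),
                        sample(gene_ids))
  assignment <- rep_len(seq_len(k), length(gene_ids))
  test <- lapply(seq_len(k), function(f) sort(shuffled[assignment == f]))
  inner <- lapply(seq_len(k), function(f) {
    rest <- gene_ids[!gene_ids %in% test[[f]]]
    per_seed <- lapply(seeds, function(s) {
      n_val <- max(1L, round(val_fraction * length(rest)))
      val <- with_seed(derive_seed(s, "val-split", f),
                       sample(rest, n_val))
      list(train = rest[!rest %in% val], val = sort(val))
    })
    names(per_seed) <- as.character(seeds)
    per_seed
  })
  structure(list(k = as.integer(k), seeds = as.integer(seeds),
                 val_fraction = val_fraction, fold_seed = as.integer(fold_seed),
                 gene_ids = gene_ids, test = test, inner = inner),
            class = "fold_split")
}

#' @rdname make_folds
#' @param folds a `fold_split`.
#' @param path JSON file path.
#' @export
save_folds <- function(folds, path) {
  jsonlite::write_json(unclass(folds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_folds
#' @export
load_folds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(k = as.integer(raw$k),
              seeds = vapply(raw$seeds, as.integer, integer(1)),
              val_fraction = as.numeric(raw$val_fraction),
              fold_seed = as.integer(raw$fold_seed),
              gene_ids = vapply(raw$gene_ids, as.character, character(1)),
              test = lapply(raw$test, function(v)
                vapply(v, as.character, character(1), USE.NAMES = FALSE)),
              inner = lapply(raw$inner, function(per_seed)
                lapply(per_seed, function(sp) list(
                  train = vapply(sp$train, as.character, character(1),
                                 USE.NAMES = FALSE),
                  val = vapply(sp$val, as.character, character(1),
                               USE.NAMES = FALSE)))))
  structure(out, class = "fold_split")
}

mse_loss <- function(y, yhat) mean((y - yhat)^2)

#' Train a model on one fold and seed
#'
#' Minimizes MSE with AdamW; batches are reshuffled each epoch from the run
#' seed; validation MSE is computed every `val_every` epochs and the
#' weights with the lowest validation MSE are returned. The initial
#' (untrained) validation loss is logged as epoch 0 in the history but is
#' not a checkpoint candidate. Aborts if the loss turns non-finite.
#'
#' @param model_config a [model_config()] (or a prebuilt `gex_cnn`, e.g.
#'   for fine-tuning).
#' @param train_cfg a [train_config()].
#' @param dataset a `gex_dataset` whose channels match the config.
#' @param folds a `fold_split`.
#' @param fold test-fold index in `1..k`.
#' @param seed replicate seed (must be one of `folds$seeds`); drives weight
#'   initialization, the inner split, batch order and dropout.
#' @return a `gex_checkpoint`: list with the trained `model`, `history`
#'   data.frame (epoch, train_loss, val_loss), `best_val`, `fold`, `seed`
#'   and the id lists used.
#' @export
train_model <- function(model_config, train_cfg, dataset, folds, fold, seed) {
  stopifnot(inherits(folds, "fold_split"), fold >= 1L, fold <= folds$k)
  if (!as.character(seed) %in% names(folds$inner[[fold]]))
    stop("seed ", seed, " has no inner split in the fold object")
  sp <- folds$inner[[fold]][[as.character(seed)]]
  train_ids <- intersect(sp$train, dataset$gene_ids)
  val_ids <- intersect(sp$val, dataset$gene_ids)
  fit_model(model_config, train_cfg, dataset, train_ids, val_ids, seed,
            fold = fold, test_ids = intersect(folds$test[[fold]],
                                              dataset$gene_ids))
}

# Core loop shared by train_model and fine_tune.
fit_model <- function(model_or_config, train_cfg, dataset, train_ids, val_ids,
                      seed, fold = NA_integer_, test_ids = character()) {
  model <- if (inherits(model_or_config, "gex_cnn")) model_or_config
           else build_model(model_or_config, seed)
  if (dim(dataset$x)[2] != model$config$input_channels)
    stop("dataset channels do not match the model config")
  tr <- subset_dataset(dataset, train_ids)
  va <- subset_dataset(dataset, val_ids)
  n <- length(train_ids)
  state <- adamw_init(model$params)
  step <- 0L
  best_val <- Inf
  best_se <- NA_real_
  best_params <- model$params
  best_buffers <- model$buffers
  init_val <- mse_loss(va$y, predict(model, va))
  hist <- list(data.frame(epoch = 0L, train_loss = NA_real_, val_loss = init_val))
  for (epoch in seq_len(train_cfg$max_epochs)) {
    lr_e <- if (identical(train_cfg$lr_schedule, "cosine")) {
      train_cfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / train_cfg$max_epochs))
    } else train_cfg$lr
    ord <- with_seed(derive_seed(seed, "epoch-order", epoch), sample(n))
    ep_loss <- 0
    for (bstart in seq(1L, n, by = train_cfg$batch_size)) {
      bidx <- ord[bstart:min(bstart + train_cfg$batch_size - 1L, n)]
      xb <- tr$x[, , bidx, drop = FALSE]
      yb <- tr$y[bidx]
      fw <- nn_forward(model$params, model$plan, xb, buffers = model$buffers,
                       training = TRUE, keep_cache = TRUE,
                       dropout_seed = derive_seed(seed, "dropout", epoch, bstart))
      model$buffers <- fw$buffers
      if (!all(is.finite(fw$y)))
        stop(sprintf("non-finite loss at epoch %d; reduce the learning rate", epoch))
      dy <- 2 * (fw$y - yb) / length(yb)
      bw <- nn_backward(model$params, model$plan, fw$cache, dy)
      step <- step + 1L
      upd <- adamw_step(model$params, bw$grads, state, step,
                        lr_e, train_cfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + mse_loss(yb, fw$y) * length(yb)
    }
    if (epoch %% train_cfg$val_every == 0L) {
      val_pred <- predict(model, va)
      val_loss <- mse_loss(va$y, val_pred)
      if (!is.finite(val_loss)) stop("non-finite validation loss")
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / n, val_loss = val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_se <- stats::sd((va$y - val_pred)^2) / sqrt(length(va$y))
        if (!is.finite(best_se)) best_se <- 0
        best_params <- model$params
        best_buffers <- model$buffers
      }
      last_val <- val_loss
    }
  }
  # one-SE selection: prefer the fully trained model when its validation
  # loss is within one standard error of the minimum (validation-MSE
  # differences below that are noise); otherwise take the minimum.
  if (is.finite(best_val) && last_val <= best_val + best_se) {
    selected <- "final"
    best_val <- last_val
  } else {
    selected <- "best"
    model$params <- best_params
    model$buffers <- best_buffers
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 best_val = best_val, init_val = init_val,
                 selected = selected, fold = fold, seed = seed,
                 train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids,
                 train_cfg = train_cfg),
            class = "gex_checkpoint")
}

#' Fine-tune a DNA-only model with the ATAC channel added
#'
#' Copies every weight tensor of a pre-trained 4-channel (DNA-only)
#' checkpoint into a fresh 5-channel model; only the first convolution's
#' ATAC-channel slice is freshly initialized from `seed`. The model is then
#' trained under the fine-tuning hyperparameters on the same folds and
#' seeds. With the new ATAC slice zeroed, the initialized model reproduces
#' the pre-trained DNA-only predictions exactly.
#'
#' @param pretrained a 4-channel `gex_checkpoint` (or `gex_cnn`).
#' @param dataset a 5-channel `gex_dataset`.
#' @param folds,fold,seed as in [train_model()].
#' @param train_cfg a [train_config()]; defaults to [fine_tune_config()].
#' @param epochs_zero when TRUE, skip training and return the initialized
#'   model checkpoint (used for weight-copy audits).
#' @return a `gex_checkpoint`.
#' @export
fine_tune <- function(pretrained, dataset, folds, fold, seed,
                      train_cfg = fine_tune_config(), epochs_zero = FALSE) {
  dna_model <- if (inherits(pretrained, "gex_checkpoint")) pretrained$model
               else pretrained
  if (dna_model$config$input_channels != 4L)
    stop("pretrained checkpoint must have 4 input channels")
  cfg5 <- dna_model$config
  cfg5$input_channels <- 5L
  cfg5 <- do.call(model_config, c(unclass(cfg5)))
  model <- build_model(cfg5, derive_seed(seed, "atac-slice"))
  model$buffers <- dna_model$buffers
  for (i in seq_along(model$params)) {
    dna_p <- dna_model$params[[i]]
    if (i == 1L && model$plan[[1]]$type == "conv") {
      if (!all(dim(dna_p$W)[c(1, 3)] == dim(model$params[[1]]$W)[c(1, 3)]))
        stop("first-layer shape mismatch beyond the channel dimension")
      model$params[[1]]$W[, 1:4, ] <- dna_p$W
      model$params[[1]]$b <- dna_p$b
      if (!is.null(dna_p$gamma)) {
        model$params[[1]]$gamma <- dna_p$gamma
        model$params[[1]]$beta <- dna_p$beta
      }
    } else {
      if (!identical(dim(dna_p$W), dim(model$params[[i]]$W)) ||
          !identical(length(dna_p$b), length(model$params[[i]]$b)))
        stop(sprintf("layer %d shape mismatch between pretrained and target", i))
      model$params[[i]] <- dna_p
    }
  }
  if (epochs_zero) {
    sp <- folds$inner[[fold]][[as.character(seed)]]
    va <- subset_dataset(dataset, intersect(sp$val, dataset$gene_ids))
    return(structure(list(model = model, history = NULL,
                          best_val = mse_loss(va$y, predict(model, va)),
                          fold = fold, seed = seed,
                          test_ids = intersect(folds$test[[fold]],
                                               dataset$gene_ids)),
                     class = "gex_checkpoint"))
  }
  stopifnot(inherits(folds, "fold_split"))
  sp <- folds$inner[[fold]][[as.character(seed)]]
  fit_model(model, train_cfg, dataset,
            intersect(sp$train, dataset$gene_ids),
            intersect(sp$val, dataset$gene_ids), seed, fold = fold,
            test_ids = intersect(folds$test[[fold]], dataset$gene_ids))
}

#' Scramble dataset inputs with respect to the target genes
#'
#' Permutes DNA blocks and/or ATAC rows across genes while leaving the
#' targets in place. `what = "both"` with `mode = "pairwise"` applies one
#' permutation jointly (sequence and track of a gene stay together);
#' `mode = "separate"` draws two independent permutations (forced to differ
#' when `n <= 2` so the pairing is actually broken). Permutations are drawn
#' once per call from `seed`. Only the genes in `which_ids` are scrambled.
#'
#' @param dataset a 5-channel `gex_dataset`.
#' @param what "dna", "atac" or "both".
#' @param mode "separate" or "pairwise"; "pairwise" is only defined for
#'   `what = "both"`.
#' @param seed integer seed.
#' @param which_ids gene IDs to scramble among (default: all genes).
#' @return the scrambled `gex_dataset`.
#' @export
scramble <- function(dataset, what = c("dna", "atac", "both"),
                     mode = c("separate", "pairwise"), seed = 1L,
                     which_ids = dataset$gene_ids) {
  what <- match.arg(what)
  mode <- match.arg(mode)
  if (dim(dataset$x)[2] != 5L) stop("scrambling requires a 5-channel dataset")
  if (mode == "pairwise" && what != "both")
    stop("mode 'pairwise' is only defined for what = 'both'")
  idx <- match(which_ids, dataset$gene_ids)
  if (anyNA(idx)) stop("unknown gene id(s) in which_ids")
  n <- length(idx)
  perm1 <- with_seed(derive_seed(seed, "scramble", what, mode, 1L), sample(n))
  out <- dataset
  if (what == "dna") {
    out$x[, 1:4, idx] <- dataset$x[, 1:4, idx[perm1], drop = FALSE]
  } else if (what == "atac") {
    out$x[, 5L, idx] <- dataset$x[, 5L, idx[perm1], drop = FALSE]
  } else if (mode == "pairwise") {
    out$x[, , idx] <- dataset$x[, , idx[perm1], drop = FALSE]
  } else {
    perm2 <- with_seed(derive_seed(seed, "scramble", what, mode, 2L), sample(n))
    if (n <= 2L) {
      tries <- 0L
      while (identical(perm1, perm2) && tries < 100L) {
        tries <- tries + 1L
        perm2 <- with_seed(derive_seed(seed, "scramble", what, mode, 2L + tries),
                           sample(n))
      }
    }
    out$x[, 1:4, idx] <- dataset$x[, 1:4, idx[perm1], drop = FALSE]
    out$x[, 5L, idx] <- dataset$x[, 5L, idx[perm2], drop = FALSE]
  }
  out
}

#' Chromosome-holdout train/test split
#'
#' Used for input-length sweeps, where gene-level folds could let long
#' windows overlap between train and test: all genes on the held-out
#' chromosomes form the single test set.
#'
#' @param promoters promoter data.frame with gene_id and chrom.
#' @param held_out chromosomes to hold out (default chr2 and chr9).
#' @return list with `train` and `test` character vectors of gene IDs.
#' @export
chromosome_holdout_split <- function(promoters, held_out = c("chr2", "chr9")) {
  test <- promoters$gene_id[promoters$chrom %in% held_out]
  if (length(test) == 0L)
    warning("no genes on held-out chromosomes; test set is empty")
  list(train = promoters$gene_id[!promoters$chrom %in% held_out],
       test = test)
}

#' Save / load a checkpoint with a JSON manifest sidecar
#'
#' Weights go to an RDS file; a small JSON manifest (config, seed, fold,
#' package version, best validation loss) sits next to it for audit.
#'
#' @param checkpoint a `gex_checkpoint`.
#' @param path RDS path; the manifest is written to `<path>.json`.
#' @export
save_checkpoint <- function(checkpoint, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(checkpoint, path)
  manifest <- list(
    input_channels = checkpoint$model$config$input_channels,
    input_length = checkpoint$model$config$input_length,
    seed = checkpoint$seed, fold = checkpoint$fold,
    best_val = checkpoint$best_val,
    n_parameters = count_parameters(checkpoint$model),
    package_version = as.character(utils::packageVersion("chromexpr")))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
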