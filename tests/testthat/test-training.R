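test_that("folds partition the genes and inner splits vary only by seed", {
  ids <- sprintf("g%02d", 1:10)
  folds <- make_folds(ids, k = 5, seeds = 1:2, val_fraction = 0.2)
  expect_equal(sort(unlist(folds$test)), sort(ids))
  expect_equal(unique(lengths(folds$test)), 2L)
  expect_equal(length(Reduce(intersect, folds$test)), 0L)
  for (f in 1:5) {
    for (s in c("1", "2")) {
      sp <- folds$inner[[f]][[s]]
      expect_setequal(c(sp$train, sp$val, folds$test[[f]]), ids)
      expect_length(intersect(sp$val, folds$test[[f]]), 0)
    }
    # same test folds across seeds, different validation sets somewhere
  }
  folds_b <- make_folds(ids, k = 5, seeds = 1:2, val_fraction = 0.2)
  expect_identical(folds, folds_b)
  vals1 <- lapply(1:5, function(f) folds$inner[[f]][["1"]]$val)
  vals2 <- lapply(1:5, function(f) folds$inner[[f]][["2"]]$val)
  expect_false(identical(vals1, vals2))
  expect_error(make_folds(c("a", "a", "b")), "duplicate")
})

test_that("fold splits serialize and reload bit-exactly", {
  folds <- make_folds(sprintf("g%03d", 1:40), k = 4, seeds = 1:3)
  path <- tempfile(fileext = ".json")
  save_folds(folds, path)
  back <- load_folds(path)
  expect_equal(back$test, folds$test)
  expect_equal(back$inner, folds$inner)
  expect_equal(back$k, folds$k)
})

test_that("training reduces validation MSE on a learnable synthetic signal", {
  # y = mean of the ATAC row: an ATAC-only model must beat its untrained self
  set.seed(31)
  n <- 60; L <- 40
  atac <- matrix(runif(n * L), n, L,
                 dimnames = list(sprintf("g%02d", 1:n), NULL))
  seqs <- setNames(vapply(1:n, function(i) random_dna(L), character(1)),
                   rownames(atac))
  gex <- setNames(rowMeans(atac), rownames(atac))
  ds <- ablate_channels(build_dataset(seqs, atac, gex), "atac_only")
  folds <- make_folds(ds$gene_ids, k = 3, seeds = 1L, val_fraction = 0.2)
  cfg <- model_config(1, L, list(c(4L, 5L, 2L)), c(8L), dropout = 0,
                      global_pool = TRUE)
  tc <- train_config(lr = 5e-3, weight_decay = 1e-4, batch_size = 16L,
                     max_epochs = 40L, val_every = 4L)
  ck <- train_model(cfg, tc, ds, folds, fold = 1, seed = 1)
  expect_lt(ck$best_val, ck$init_val)
  expect_equal(ck$history$epoch[1], 0L)
  expect_equal(nrow(ck$history), 11L)
})

test_that("exactly one validation evaluation happens when max_epochs == val_every", {
  ds <- toy_dataset(n = 12)
  folds <- make_folds(ds$gene_ids, k = 3, seeds = 1L, val_fraction = 0.25)
  tc <- train_config(lr = 1e-3, weight_decay = 0, batch_size = 8L,
                     max_epochs = 4L, val_every = 4L)
  ck <- train_model(toy_model_config(), tc, ds, folds, 1, 1)
  expect_equal(sum(ck$history$epoch > 0), 1L)
  expect_equal(ck$best_val, ck$history$val_loss[ck$history$epoch == 4])
})

test_that("training is reproducible given seed and data", {
  ds <- toy_dataset(n = 16)
  folds <- make_folds(ds$gene_ids, k = 4, seeds = 1:2)
  tc <- train_config(lr = 1e-3, weight_decay = 1e-4, batch_size = 8L,
                     max_epochs = 8L, val_every = 4L)
  ck1 <- train_model(toy_model_config(), tc, ds, folds, 1, 1)
  ck2 <- train_model(toy_model_config(), tc, ds, folds, 1, 1)
  expect_identical(ck1$history, ck2$history)
  expect_identical(ck1$model$params, ck2$model$params)
  # different seeds share the test fold but differ in weights
  ck3 <- train_model(toy_model_config(), tc, ds, folds, 1, 2)
  expect_identical(ck1$test_ids, ck3$test_ids)
  expect_false(identical(ck1$model$params, ck3$model$params))
})

test_that("reloaded checkpoints reproduce the logged validation minimum", {
  ds <- toy_dataset(n = 16)
  folds <- make_folds(ds$gene_ids, k = 4, seeds = 1L)
  tc <- train_config(lr = 1e-3, weight_decay = 0, batch_size = 8L,
                     max_epochs = 8L, val_every = 4L)
  ck <- train_model(toy_model_config(), tc, ds, folds, 1, 1)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  va <- subset_dataset(ds, back$val_ids)
  expect_equal(mean((va$y - predict(back$model, va))^2), ck$best_val,
               tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("fine-tuning copies weights exactly and refreshes only the ATAC slice", {
  ds <- toy_dataset(n = 16)
  folds <- make_folds(ds$gene_ids, k = 4, seeds = 1L)
  tc <- train_config(lr = 1e-3, weight_decay = 0, batch_size = 8L,
                     max_epochs = 4L, val_every = 4L)
  dna_ck <- train_model(toy_model_config(4), tc, ablate_channels(ds, "dna_only"),
                        folds, 1, 1)
  init <- fine_tune(dna_ck, ds, folds, 1, 1, epochs_zero = TRUE)
  # every non-first-layer tensor identical
  for (i in 2:length(init$model$params)) {
    expect_identical(init$model$params[[i]]$W, dna_ck$model$params[[i]]$W)
    expect_identical(init$model$params[[i]]$b, dna_ck$model$params[[i]]$b)
  }
  expect_identical(init$model$params[[1]]$W[, 1:4, ], dna_ck$model$params[[1]]$W,
                   ignore_attr = TRUE)
  # with the fresh ATAC slice zeroed, predictions equal the DNA-only model's
  zeroed <- init$model
  zeroed$params[[1]]$W[, 5, ] <- 0
  expect_equal(predict(zeroed, ds),
               predict(dna_ck$model, ablate_channels(ds, "dna_only")),
               tolerance = 1e-12)
  expect_error(fine_tune(train_model(toy_model_config(5), tc, ds, folds, 1, 1),
                         ds, folds, 1, 1), "4 input channels")
})

test_that("scrambling permutes blocks while conserving their multiset", {
  ds <- toy_dataset(n = 8)
  sc <- scramble(ds, "dna", seed = 2)
  expect_equal(sc$y, ds$y)
  expect_equal(sc$x[, 5, ], ds$x[, 5, ])
  # multiset of DNA blocks conserved, but pairing broken
  key <- function(x, rows) apply(x, 3, function(s) paste(s[, rows], collapse = ""))
  expect_setequal(key(sc$x, 1:4), key(ds$x, 1:4))
  expect_false(identical(key(sc$x, 1:4), key(ds$x, 1:4)))
  # pairwise keeps DNA and ATAC co-indexed
  pw <- scramble(ds, "both", "pairwise", seed = 2)
  expect_setequal(key(pw$x, 1:5), key(ds$x, 1:5))
  # separate with n = 2 forces distinct permutations
  two <- subset_dataset(ds, 1:2)
  sep <- scramble(two, "both", "separate", seed = 1)
  expect_false(identical(key(sep$x, 1:5), key(two$x, 1:5)))
  expect_error(scramble(ds, "dna", "pairwise"), "pairwise")
  expect_error(scramble(ablate_channels(ds, "dna_only"), "dna"), "5-channel")
})

test_that("scrambling with which_ids leaves other genes untouched", {
  ds <- toy_dataset(n = 10)
  keep <- ds$gene_ids[1:3]
  sc <- scramble(ds, "both", "pairwise", seed = 4,
                 which_ids = ds$gene_ids[4:10])
  expect_equal(sc$x[, , 1:3], ds$x[, , 1:3])
})

test_that("chromosome holdout splits are disjoint and exhaustive", {
  pr <- data.frame(gene_id = sprintf("g%d", 1:6),
                   chrom = c("chr1", "chr2", "chr9", "chr2", "chr3", "chr1"))
  sp <- chromosome_holdout_split(pr)
  expect_setequal(sp$test, c("g2", "g3", "g4"))
  expect_setequal(c(sp$train, sp$test), pr$gene_id)
  expect_warning(chromosome_holdout_split(pr[pr$chrom == "chr1", ]), "empty")
})
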