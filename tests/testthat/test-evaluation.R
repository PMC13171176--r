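test_that("metrics match from-scratch formula oracles on random vectors", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    y <- rnorm(n)
    p <- rnorm(n) + 0.3 * y
    m <- regression_metrics(y, p)
    expect_equal(m$pearson, oracle_pearson(y, p), tolerance = 1e-10)
    expect_equal(m$spearman, oracle_spearman(y, p), tolerance = 1e-10)
    expect_equal(m$mse, mean((y - p)^2), tolerance = 1e-10)
    expect_equal(m$r2, oracle_r2(y, p), tolerance = 1e-10)
  }
})

test_that("metrics handle exact fits, rank reversals and degenerate input", {
  y <- c(0.1, 0.4, 0.9)
  m <- regression_metrics(y, y)
  expect_equal(unlist(m), c(pearson = 1, spearman = 1, mse = 0, r2 = 1))
  m2 <- regression_metrics(c(1, 2, 3), c(3, 1, 2))
  expect_equal(m2$spearman, -0.5)  # 1 - 6*6/24
  m3 <- regression_metrics(y, rep(mean(y), 3))
  expect_warning(regression_metrics(y, rep(1, 3)), "constant")
  expect_equal(m3$r2, 0)
  expect_error(regression_metrics(1:3, 1:4), "length")
})

test_that("correlations are invariant to affine and monotone transforms", {
  set.seed(22)
  for (rep in 1:20) {
    y <- rnorm(15); p <- rnorm(15)
    base <- regression_metrics(y, p)
    aff <- regression_metrics(y, 2.5 * p + 1)
    expect_equal(aff$pearson, base$pearson, tolerance = 1e-12)
    mono <- regression_metrics(y, exp(p))
    expect_equal(mono$spearman, base$spearman, tolerance = 1e-12)
  }
})

test_that("ensemble prediction averages seed models and ignores order", {
  ds <- toy_dataset(n = 8)
  folds <- make_folds(ds$gene_ids, k = 2, seeds = 1:2)
  tc <- train_config(lr = 1e-3, weight_decay = 0, batch_size = 8L,
                     max_epochs = 2L, val_every = 2L)
  cks <- lapply(1:2, function(s) train_model(toy_model_config(), tc, ds, folds, 1, s))
  test_ds <- subset_dataset(ds, cks[[1]]$test_ids)
  en <- ensemble_predict(cks, test_ds)
  p1 <- predict(cks[[1]]$model, test_ds)
  p2 <- predict(cks[[2]]$model, test_ds)
  expect_equal(en, (p1 + p2) / 2)
  expect_equal(ensemble_predict(rev(cks), test_ds), en)
  expect_equal(ensemble_predict(cks[1], test_ds), p1)
})

test_that("fold evaluation and subset evaluation match direct recomputation", {
  ds <- toy_dataset(n = 16)
  folds <- make_folds(ds$gene_ids, k = 4, seeds = 1L)
  tc <- train_config(lr = 1e-3, weight_decay = 0, batch_size = 8L,
                     max_epochs = 2L, val_every = 2L)
  cks <- lapply(1:4, function(f) list(train_model(toy_model_config(), tc, ds, folds, f, 1)))
  rep_all <- evaluate_folds(cks, ds, folds)
  expect_equal(nrow(rep_all$per_fold), 4L)
  # brute-force recomputation for one fold
  f1 <- subset_dataset(ds, folds$test[[1]])
  p1 <- predict(cks[[1]][[1]]$model, f1)
  expect_equal(rep_all$per_fold$pearson[1], oracle_pearson(f1$y, p1),
               tolerance = 1e-12)
  # subset = everything is a no-op; 4-gene subset matches direct metrics
  expect_equal(subset_eval(cks, ds, folds, ds$gene_ids)$per_fold,
               rep_all$per_fold)
  sub <- unlist(lapply(folds$test, head, 2))
  rep_sub <- subset_eval(cks, ds, folds, sub)
  expect_equal(unique(rep_sub$per_fold$n_genes), 2L)
  expect_warning(subset_eval(cks, ds, folds, ds$gene_ids[1]), "empty|single")
})

test_that("the naive predictor is auATAC and scores by Spearman", {
  gex <- setNames((1:10) / 10, sprintf("g%02d", 1:10))
  au <- setNames(seq(5, 50, by = 5), names(gex))
  folds <- make_folds(names(gex), k = 2, seeds = 1L)
  ev <- naive_eval(au, gex, folds)
  expect_equal(ev$spearman, c(1, 1))
  # independence gives near-zero correlation within the null bound
  set.seed(34)
  n <- 400
  gex2 <- setNames(runif(n), sprintf("h%03d", 1:n))
  au2 <- setNames(runif(n), names(gex2))
  folds2 <- make_folds(names(gex2), k = 2, seeds = 1L)
  ev2 <- naive_eval(au2, gex2, folds2)
  expect_lt(max(abs(ev2$spearman)), 2 / sqrt(n / 2))
  expect_warning(naive_eval(setNames(rep(1, n), names(gex2)), gex2, folds2),
                 "constant")
  expect_error(naive_predict(au, "missing_gene"), "missing")
})

test_that("variant effects are deltas with reused accessibility", {
  ds <- toy_dataset(n = 4)
  m <- build_model(toy_model_config(), seed = 2)
  ref <- ds$x[, , 1]
  ref_seq <- decode_one_hot(t(ref[, 1:4]))
  expect_equal(variant_effect(m, ref, ref_seq), 0)
  alt_seq <- paste0("T", substr(ref_seq, 2, nchar(ref_seq)))
  d1 <- variant_effect(m, ref, alt_seq)
  # antisymmetry under swapping ref and alt
  alt <- ref; alt[, 1:4] <- t(one_hot_encode(alt_seq))
  expect_equal(variant_effect(m, alt, ref_seq), -d1, tolerance = 1e-12)
  expect_error(variant_effect(m, ref, "ACGT"), "length")
})

test_that("auroc matches the pairwise concordance oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "classes")
  set.seed(44)
  for (rep in 1:20) {
    s <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)
    l <- sample(0:1, 12, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(auroc(s, l), oracle_auroc(s, l), tolerance = 1e-12)
  }
})

test_that("wilcoxon p-values match full sign enumeration", {
  expect_equal(wilcoxon_one_sided(c(1, 2, 3), c(0, 0, 0))$p_value, 0.125)
  expect_error(wilcoxon_one_sided(1:3, 1:3), "zero")
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_one_sided(x, y)
    expect_equal(got$p_value, oracle_wilcoxon_greater(x, y), tolerance = 1e-12)
    expect_equal(got$method, "exact")
  }
  # paired-test consistency for continuous data
  x <- rnorm(10); y <- rnorm(10)
  expect_gte(wilcoxon_one_sided(x, y)$p_value +
             wilcoxon_one_sided(y, x)$p_value, 1)
})

test_that("exact and approximate wilcoxon agree on moderate samples", {
  set.seed(66)
  x <- rnorm(12, 0.3); y <- rnorm(12)
  exact <- wilcoxon_one_sided(x, y)$p_value
  # force the approximation path by inflating n past the exact cutoff
  approx_p <- {
    d <- x - y
    r <- rank(abs(d)); V <- sum(r[d > 0]); n <- length(d)
    mu <- n * (n + 1) / 4
    s2 <- n * (n + 1) * (2 * n + 1) / 24
    pnorm((V - mu - 0.5) / sqrt(s2), lower.tail = FALSE)
  }
  expect_lt(abs(exact - approx_p), 0.02)
  # large-n path runs and is monotone in effect direction
  xl <- rnorm(40, 0.5); yl <- rnorm(40)
  big <- wilcoxon_one_sided(xl, yl)
  expect_equal(big$method, "normal-approximation")
  expect_lt(big$p_value, wilcoxon_one_sided(yl, xl)$p_value)
})
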