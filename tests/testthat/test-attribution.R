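test_that("dinucleotide shuffles preserve counts and terminal bases exactly", {
  expect_equal(unique(dinuc_shuffle("AAAA", n = 5, seed = 1)), "AAAA")
  shufs <- dinuc_shuffle("ACGTACGT", n = 20, seed = 2)
  ref <- oracle_dinuc_counts("ACGTACGT")
  for (s in shufs) expect_equal(oracle_dinuc_counts(s), ref)
  expect_error(dinuc_shuffle("A"), "length")
  set.seed(3)
  for (rep in 1:25) {
    x <- random_dna(sample(10:60, 1))
    out <- dinuc_shuffle(x, n = 4, seed = rep)
    for (s in out) {
      expect_equal(substr(s, 1, 1), substr(x, 1, 1))
      expect_equal(substr(s, nchar(s), nchar(s)), substr(x, nchar(x), nchar(x)))
      expect_equal(oracle_dinuc_counts(s), oracle_dinuc_counts(x))
    }
  }
})

test_that("shuffles are non-trivial and seed-reproducible", {
  x <- random_dna(80, seed = 9)
  a <- dinuc_shuffle(x, n = 10, seed = 5)
  b <- dinuc_shuffle(x, n = 10, seed = 5)
  expect_identical(a, b)
  expect_gt(length(unique(a)), 1)
  expect_false(all(a == x))
})

test_that("N runs segment the shuffle and stay fixed in place", {
  x <- "ACGTACGTNNACGTACGT"
  out <- dinuc_shuffle(x, n = 10, seed = 1)
  for (s in out) {
    expect_equal(substr(s, 9, 10), "NN")
    expect_equal(oracle_dinuc_counts(substr(s, 1, 8)),
                 oracle_dinuc_counts(substr(x, 1, 8)))
    expect_equal(oracle_dinuc_counts(substr(s, 11, 18)),
                 oracle_dinuc_counts(substr(x, 11, 18)))
  }
})

test_that("backgrounds pair shuffled sequences with permuted ATAC rows", {
  ds <- toy_dataset(n = 2, L = 30)
  x <- ds$x[, , 1]
  bg <- make_backgrounds(x, n = 6, seed = 4)
  expect_equal(dim(bg), c(30, 5, 6))
  for (j in 1:6) {
    expect_equal(sort(bg[, 5, j]), sort(x[, 5]))  # permuted track
    expect_equal(colSums(bg[, 1:4, j]), colSums(x[, 1:4]))  # base counts kept
  }
  expect_false(identical(bg[, 5, 1], bg[, 5, 2]))
})

test_that("a constant model attributes zero everywhere", {
  cfg <- model_config(5, 20, list(c(4L, 3L, 2L)), c(4L), dropout = 0)
  m <- build_model(cfg, 1)
  # zero all weights: f is the constant sigmoid(bias)
  for (i in seq_along(m$params)) {
    m$params[[i]]$W[] <- 0
    m$params[[i]]$b[] <- 0
  }
  ds <- toy_dataset(n = 1, L = 20)
  x <- ds$x[, , 1]
  at <- attribute(m, x, make_backgrounds(x, 5, 1), n_steps = 8)
  expect_equal(max(abs(at$scores)), 0)
})

test_that("attributions of a linear model are exact Shapley values", {
  # single dense layer, linear output: phi = (x - mean(bg)) * w
  cfg <- model_config(5, 12, conv_specs = list(), dense_sizes = integer(0),
                      dropout = 0, output_activation = "linear")
  m <- build_model(cfg, 3)
  ds <- toy_dataset(n = 1, L = 12)
  x <- ds$x[, , 1]
  bg <- make_backgrounds(x, n = 15, seed = 2)
  at <- attribute(m, x, bg, n_steps = 4)
  W <- matrix(m$params[[1]]$W, nrow(x), ncol(x))  # column-major (L, C)
  mean_bg <- rowMeans(bg, dims = 2)
  expect_equal(at$scores, (x - mean_bg) * W, tolerance = 1e-10)
  expect_lt(at$completeness_gap, 1e-10)
})

test_that("completeness holds on a trained nonlinear model", {
  # train on a real signal (y = mean accessibility) so the attribution
  # targets f(x) - mean f(bg) are not degenerately small
  set.seed(41)
  n <- 40; L <- 30
  seqs <- setNames(vapply(seq_len(n), function(i) random_dna(L), character(1)),
                   sprintf("g%02d", seq_len(n)))
  atac <- matrix(runif(n * L), n, L, dimnames = list(names(seqs), NULL))
  gex <- setNames(rowMeans(atac), names(seqs))
  ds <- build_dataset(seqs, atac, gex)
  folds <- make_folds(ds$gene_ids, k = 2, seeds = 1L)
  tc <- train_config(lr = 5e-3, weight_decay = 1e-4, batch_size = 16L,
                     max_epochs = 20L, val_every = 4L)
  cfg <- model_config(5, 30, list(c(6L, 5L, 2L)), c(8L), dropout = 0.1)
  ck <- train_model(cfg, tc, ds, folds, 1, 1)
  for (g in 1:5) {
    x <- ds$x[, , g]
    at <- attribute(ck$model, x, make_backgrounds(x, 30, g),
                    n_steps = 32, refine_tol = 1e-3, max_steps = 4096)
    expect_lt(at$completeness_gap, 1e-3)
    # the reported gap is itself |sum(scores) - (f_x - mean f_bg)| relative
    expect_equal(at$completeness_gap,
                 abs(sum(at$scores) - (at$f_x - at$f_bg_mean)) /
                   max(abs(at$f_x - at$f_bg_mean), 1e-12),
                 tolerance = 1e-9)
  }
})

test_that("three-stage aggregation equals the grand mean when folds partition genes", {
  set.seed(6)
  mk <- function(g, f, s) structure(list(scores = matrix(rnorm(20), 10, 2),
                                         gene_id = g, fold = f, seed = s),
                                    class = "attribution")
  attrs <- list(mk("g1", 1, 1), mk("g1", 1, 2), mk("g2", 1, 1), mk("g2", 1, 2),
                mk("g3", 2, 1), mk("g3", 2, 2))
  agg <- aggregate_positional(attrs)
  # seed means first
  sm <- (attrs[[1]]$scores + attrs[[2]]$scores) / 2
  expect_equal(agg$per_gene$g1, sm)
  # grand mean over genes equals the stage-wise result here
  grand <- Reduce(`+`, lapply(attrs, function(a) a$scores)) / 3 / 2
  expect_equal(agg$profile, grand)
  expect_equal(agg$n_genes, 3L)
  # missing seed/fold combinations are reported as gaps
  expect_error(aggregate_positional(attrs[-2]), "gene g1")
})

test_that("single attribution aggregates to itself", {
  a <- structure(list(scores = matrix(1:8, 4, 2), gene_id = "g", fold = 1,
                      seed = 1), class = "attribution")
  agg <- aggregate_positional(list(a))
  expect_equal(agg$profile, a$scores)
})

test_that("channel-track correlation matches the metrics-module Spearman", {
  set.seed(8)
  track <- runif(30)
  prof <- cbind(track, -track, runif(30), runif(30), runif(30))
  cors <- channel_track_correlation(prof, track)
  expect_equal(unname(cors["A"]), 1)
  expect_equal(unname(cors["C"]), -1)
  expect_equal(unname(cors["G"]),
               regression_metrics(prof[, 3], track)$spearman,
               tolerance = 1e-12)
  expect_warning(channel_track_correlation(cbind(rep(1, 30)), track),
                 "constant")
})

test_that("modisco export filters by the auATAC threshold", {
  per_gene <- list(g1 = matrix(runif(40), 10, 4),
                   g2 = matrix(runif(40), 10, 4))
  onehots <- list(g1 = one_hot_encode(random_dna(10, seed = 1)),
                  g2 = one_hot_encode(random_dna(10, seed = 2)))
  au <- c(g1 = 1, g2 = 3)
  dir <- tempfile()
  out <- export_for_modisco(per_gene, onehots, au, threshold = mean(au), dir)
  expect_equal(out, "g2")
  expect_true(file.exists(file.path(dir, "g2.contrib.tsv")))
  expect_false(file.exists(file.path(dir, "g1.contrib.tsv")))
  all_out <- export_for_modisco(per_gene, onehots, au, threshold = -Inf, dir)
  expect_setequal(all_out, c("g1", "g2"))
  # actual contributions are the hypothetical scores masked by the one-hot
  hyp <- as.matrix(read.delim(file.path(dir, "g2.hyp.tsv"), header = FALSE))
  act <- as.matrix(read.delim(file.path(dir, "g2.contrib.tsv"), header = FALSE))
  expect_equal(act, hyp * unname(onehots$g2), ignore_attr = TRUE)
  expect_error(export_for_modisco(per_gene, onehots, au, threshold = 10, dir),
               "no genes")
})
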