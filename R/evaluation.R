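#' Regression metrics for GEx prediction
#'
#' Pearson and Spearman correlation (average ranks for ties), MSE and the
#' coefficient of determination R2 = 1 - SSres/SStot. Correlations with a
#' constant vector are undefined and reported as NaN with a warning, never
#' imputed.
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 2).
#' @return a named list with pearson, spearman, mse, r2.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) {
    warning("fewer than 2 observations; correlations undefined")
    return(list(pearson = NaN, spearman = NaN,
                mse = mean((y_true - y_pred)^2), r2 = NaN))
  }
  const <- stats::sd(y_true) == 0 || stats::sd(y_pred) == 0
  if (const) warning("constant input; correlations undefined (NaN)")
  pearson <- if (const) NaN else stats::cor(y_true, y_pred)
  spearman <- if (const) NaN else stats::cor(y_true, y_pred, method = "spearman")
  mse <- mean((y_true - y_pred)^2)
  sstot <- sum((y_true - mean(y_true))^2)
  r2 <- if (sstot == 0) NaN else 1 - sum((y_true - y_pred)^2) / sstot
  list(pearson = pearson, spearman = spearman, mse = mse, r2 = r2)
}

#' Seed-ensemble prediction for one fold
#'
#' The fold-level prediction is the arithmetic mean of the per-seed model
#' predictions, gene by gene.
#'
#' @param checkpoints list of `gex_checkpoint`s (typically 5 seeds of one
#'   fold) sharing channel mode and test gene set.
#' @param dataset a `gex_dataset` of the genes to predict.
#' @return named numeric vector of ensembled predictions.
#' @export
ensemble_predict <- function(checkpoints, dataset) {
  stopifnot(length(checkpoints) >= 1L)
  ch <- vapply(checkpoints, function(ck) ck$model$config$input_channels,
               numeric(1))
  if (length(unique(ch)) != 1L) stop("checkpoints mix channel modes")
  tests <- lapply(checkpoints, function(ck) sort(ck$test_ids))
  if (length(unique(vapply(tests, paste, character(1), collapse = ","))) != 1L)
    stop("checkpoints do not share a test gene set")
  preds <- vapply(checkpoints, function(ck) predict(ck$model, dataset),
                  numeric(length(dataset$gene_ids)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  stats::setNames(rowMeans(preds), dataset$gene_ids)
}

#' Evaluate checkpoints across CV folds
#'
#' For each fold, ensembles the per-seed checkpoints on the held-out test
#' genes of that fold and computes [regression_metrics()]; means and
#' standard deviations are taken across folds, with NaN metrics excluded
#' (and counted).
#'
#' @param checkpoints_by_fold list of length k; element f is a list of
#'   checkpoints (one per seed) for fold f.
#' @param dataset the evaluation `gex_dataset` (channels matching the
#'   models; may belong to a different cell type for cross-cell-type
#'   evaluation).
#' @param folds the `fold_split` defining the test genes.
#' @param subset optional character vector restricting evaluation to a gene
#'   subset (e.g. highly variable genes); metrics are computed on the
#'   intersection with each fold's test set.
#' @return a `metric_report`: list with `per_fold` data.frame, `mean`,
#'   `sd`, and per-gene `predictions`/`truth` over all folds.
#' @export
evaluate_folds <- function(checkpoints_by_fold, dataset, folds,
                           subset = NULL) {
  per_fold <- list()
  all_pred <- all_true <- numeric(0)
  for (f in seq_along(checkpoints_by_fold)) {
    cks <- checkpoints_by_fold[[f]]
    test_ids <- intersect(folds$test[[f]], dataset$gene_ids)
    if (!is.null(subset)) test_ids <- intersect(test_ids, subset)
    if (length(test_ids) == 0L) {
      warning(sprintf("fold %d: empty test intersection", f))
      per_fold[[f]] <- data.frame(fold = f, n_genes = 0L, pearson = NaN,
                                  spearman = NaN, mse = NaN, r2 = NaN)
      next
    }
    ds <- subset_dataset(dataset, test_ids)
    pred <- ensemble_predict(cks, ds)
    m <- if (length(test_ids) < 2L) {
      warning(sprintf("fold %d: single-gene subset; correlations NaN", f))
      list(pearson = NaN, spearman = NaN, mse = mean((ds$y - pred)^2), r2 = NaN)
    } else regression_metrics(ds$y, pred)
    per_fold[[f]] <- data.frame(fold = f, n_genes = length(test_ids),
                                pearson = m$pearson, spearman = m$spearman,
                                mse = m$mse, r2 = m$r2)
    all_pred <- c(all_pred, pred)
    all_true <- c(all_true, stats::setNames(ds$y, ds$gene_ids))
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("pearson", "spearman", "mse", "r2")
  mu <- colMeans(per_fold[metric_cols], na.rm = TRUE)
  sdv <- vapply(per_fold[metric_cols], function(v) stats::sd(v[is.finite(v)]),
                numeric(1))
  structure(list(per_fold = per_fold, mean = mu, sd = sdv,
                 n_nan = sum(!is.finite(as.matrix(per_fold[metric_cols]))),
                 predictions = all_pred, truth = all_true),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> mean +/- sd across folds\n")
  for (m in names(x$mean))
    cat(sprintf("  %-8s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Naive accessibility-only prediction
#'
#' The naive predictor outputs a gene's auATAC; its headline evaluation is
#' the Spearman correlation with ground-truth GEx on each CV test fold.
#'
#' @param auatac named per-gene auATAC vector for the cell type.
#' @param test_genes character gene IDs to predict.
#' @return named numeric predictions (the auATAC values).
#' @export
naive_predict <- function(auatac, test_genes) {
  if (!all(test_genes %in% names(auatac)))
    stop("auATAC missing for gene(s): ",
         paste(setdiff(test_genes, names(auatac))[1:5], collapse = ", "))
  auatac[test_genes]
}

#' @rdname naive_predict
#' @param gex named ground-truth GEx vector.
#' @param folds a `fold_split`.
#' @return for `naive_eval`: data.frame with per-fold Spearman.
#' @export
naive_eval <- function(auatac, gex, folds) {
  rows <- lapply(seq_len(folds$k), function(f) {
    ids <- intersect(folds$test[[f]], names(gex))
    pred <- naive_predict(auatac, ids)
    sp <- if (stats::sd(pred) == 0 || stats::sd(gex[ids]) == 0) {
      warning(sprintf("fold %d: constant input; Spearman NaN", f))
      NaN
    } else stats::cor(gex[ids], pred, method = "spearman")
    data.frame(fold = f, n_genes = length(ids), spearman = sp)
  })
  do.call(rbind, rows)
}

#' Cross-cell-type evaluation
#'
#' Scores models trained on one cell type against the inputs and GEx of
#' another cell type, using the same gene folds.
#'
#' @param checkpoints_by_fold checkpoints trained on cell type a.
#' @param dataset_b `gex_dataset` of cell type b (same genes and folds).
#' @param folds the shared `fold_split`.
#' @param subset optional gene subset.
#' @return a `metric_report`.
#' @export
cross_cell_type_eval <- function(checkpoints_by_fold, dataset_b, folds,
                                 subset = NULL) {
  evaluate_folds(checkpoints_by_fold, dataset_b, folds, subset = subset)
}

#' Evaluate on a gene subset (e.g. highly variable genes)
#'
#' Recomputes fold metrics on the intersection of each fold's test genes
#' with the subset; empty intersections yield NaN with a warning.
#'
#' @inheritParams evaluate_folds
#' @param gene_subset character vector of gene IDs.
#' @return a `metric_report`.
#' @export
subset_eval <- function(checkpoints_by_fold, dataset, folds, gene_subset) {
  evaluate_folds(checkpoints_by_fold, dataset, folds, subset = gene_subset)
}

#' Predicted expression change between reference and alternative promoter
#'
#' The alternative sample reuses the reference accessibility track (when the
#' model has an ATAC channel): delta = f(alt) - f(ref).
#'
#' @param model a `gex_cnn` (or `gex_checkpoint`).
#' @param ref_sample an L x C matrix (the reference input).
#' @param alt_sequence character alternative sequence, same length L.
#' @return the scalar prediction delta.
#' @export
variant_effect <- function(model, ref_sample, alt_sequence) {
  if (inherits(model, "gex_checkpoint")) model <- model$model
  L <- nrow(ref_sample)
  if (nchar(alt_sequence) != L) stop("alt sequence length mismatch")
  alt <- ref_sample
  C <- ncol(ref_sample)
  if (C >= 4L) alt[, 1:4] <- t(one_hot_encode(alt_sequence))
  as.numeric(predict(model, alt) - predict(model, ref_sample))
}

#' Area under the ROC curve
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half (the Mann-Whitney U normalization).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical).
#' @return a value in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-sided Wilcoxon signed-rank test
#'
#' Paired test of whether `x` tends to exceed `y` (alternative "greater") or
#' fall below it ("less"). Zero differences are dropped before ranking (the
#' common signed-rank convention). The p-value is exact — computed by
#' dynamic programming over the sign-flip distribution of the rank sum,
#' which is exact even under ties — for n <= 25 nonzero pairs, and uses the
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x,y equal-length paired samples.
#' @param alternative "greater" or "less".
#' @return a list with statistic (V, the positive-rank sum), p_value, n
#'   (nonzero pairs) and method.
#' @export
wilcoxon_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (alternative == "less") {
    V_eff <- sum(r[d < 0])  # test y > x by symmetry
  } else V_eff <- V
  if (n <= 25L) {
    # exact sign-flip distribution of the positive rank sum; double ranks so
    # average ranks (.5) become integers
    r2 <- round(2 * r)
    tot <- sum(r2)
    poly <- numeric(tot + 1L)
    poly[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), poly[seq_len(tot + 1L - ri)])
      poly <- poly + shifted
    }
    poly <- poly / 2^n
    obs <- round(2 * V_eff)
    p <- sum(poly[(obs + 1L):(tot + 1L)])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V_eff - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal-approximation"
  }
  list(statistic = V, p_value = p, n = n, method = method,
       alternative = alternative)
}
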