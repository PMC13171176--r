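# Independent brute-force oracles used to check package operations.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# naive per-base fragment coverage by explicit loop
oracle_coverage <- function(fragments, window_start, window_end) {
  L <- window_end - window_start
  cov <- numeric(L)
  for (i in seq_len(nrow(fragments))) {
    for (p in seq_len(L)) {
      pos <- window_start + p - 1L  # 0-based base
      if (pos >= fragments$start[i] && pos < fragments$end[i])
        cov[p] <- cov[p] + 1
    }
  }
  cov
}

# from-scratch metric formulas (no stats::cor)
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
oracle_rank <- function(x) {
  # average ranks from first principles
  sapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2)
}
oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))
oracle_r2 <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

# pairwise-concordance auROC
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact one-sided signed-rank p by full 2^n sign enumeration
oracle_wilcoxon_greater <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mean(vs >= v_obs - 1e-12)
}

oracle_dinuc_counts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  pairs <- paste0(chars[-length(chars)], chars[-1])
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(pairs, levels = lv))
}

# direct 1D cross-correlation conv oracle: X (L x C), W (k x C x F)
oracle_conv1d <- function(X, W, b) {
  L <- nrow(X); k <- dim(W)[1]; F <- dim(W)[3]
  P <- L - k + 1
  out <- matrix(0, P, F)
  for (f in seq_len(F))
    for (p in seq_len(P))
      out[p, f] <- sum(X[p:(p + k - 1), ] * W[, , f]) + b[f]
  out
}
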