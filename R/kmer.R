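#' Score all k-mer instances of a sequence from per-base attributions
#'
#' The per-base DNA attribution is the sum over the four DNA channels at
#' each position; the score of a k-mer instance is the mean per-base score
#' across its k bases. Every position `0..L-k` yields one (overlapping)
#' instance; instances containing `N` are skipped. Only the forward-strand
#' k-mer as written is counted — reverse complements are deliberately kept
#' distinct, since k-mer orientation carries signal.
#'
#' @param sequence character scalar, length L.
#' @param base_attr length-L numeric per-base attribution (DNA channels
#'   summed).
#' @param k k-mer size (<= L).
#' @return data.frame with kmer, position (0-based) and score.
#' @export
score_kmer_instances <- function(sequence, base_attr, k) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (length(base_attr) != L) stop("attribution length != sequence length")
  if (k > L) stop("k exceeds sequence length")
  starts <- seq_len(L - k + 1L)
  kmers <- substring(paste(chars, collapse = ""), starts, starts + k - 1L)
  cs <- cumsum(c(0, base_attr))
  scores <- (cs[starts + k] - cs[starts]) / k
  keep <- !grepl("N", kmers, fixed = TRUE)
  data.frame(kmer = kmers[keep], position = starts[keep] - 1L,
             score = scores[keep], stringsAsFactors = FALSE)
}

all_kmers <- function(k) {
  sort(do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                   stringsAsFactors = FALSE)))
}

#' Build a pooled k-mer score table
#'
#' Pools instances over models, folds and seeds. With `by_cell_type`
#' grouping (the 2-mer path), per-cell-type instance means are computed
#' first and then averaged, unweighted, across cell types. The
#' `positive_only` variant (the 6-mer path) drops instances with score <= 0
#' before averaging. k-mers with no surviving instances get count 0 and
#' score NaN.
#'
#' @param instances data.frame with columns kmer, score and optionally
#'   cell_type.
#' @param k k-mer size.
#' @param variant "all_instances" or "positive_only".
#' @return a `kmer_table`: data.frame with kmer, score, count (rows for all
#'   4^k k-mers, sorted by kmer), with k and variant attached as attributes.
#' @export
build_kmer_table <- function(instances, k,
                             variant = c("all_instances", "positive_only")) {
  variant <- match.arg(variant)
  if (nrow(instances) == 0L) stop("empty instance pool")
  if (variant == "positive_only")
    instances <- instances[instances$score > 0, , drop = FALSE]
  universe <- all_kmers(k)
  agg_one <- function(df) {
    s <- tapply(df$score, factor(df$kmer, levels = universe), mean)
    n <- tapply(rep(1L, nrow(df)), factor(df$kmer, levels = universe), sum)
    list(score = as.numeric(s), count = ifelse(is.na(n), 0L, as.integer(n)))
  }
  if (!is.null(instances$cell_type) &&
      length(unique(instances$cell_type)) > 1L) {
    per_ct <- lapply(split(instances, instances$cell_type), agg_one)
    score_mat <- vapply(per_ct, `[[`, numeric(length(universe)), "score")
    count_mat <- vapply(per_ct, `[[`, numeric(length(universe)), "count")
    score <- rowMeans(score_mat)  # unweighted mean across cell types
    count <- as.integer(rowSums(count_mat))
  } else {
    a <- agg_one(instances)
    score <- a$score
    count <- a$count
  }
  score[is.na(score)] <- NaN
  out <- data.frame(kmer = universe, score = score, count = count,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "variant") <- variant
  class(out) <- c("kmer_table", "data.frame")
  out
}

kmer_ranks <- function(table) {
  # dense descending ranks by score; ties and NaN broken/ranked by kmer,
  # NaN scores last
  ord <- order(ifelse(is.nan(table$score), -Inf, table$score),
               decreasing = TRUE)
  ord <- ord[order(ifelse(is.nan(table$score[ord]), 1L, 0L))]  # NaN last, stable
  r <- integer(nrow(table))
  r[ord] <- seq_len(nrow(table))
  r
}

#' Rank change of each k-mer between two score tables
#'
#' Both tables are ranked descending by score (ties broken by lexicographic
#' k-mer, NaN-scored k-mers last and flagged); delta = rank_a - rank_b, so
#' a positive delta means the k-mer ranks better (smaller rank) in table b.
#'
#' @param table_a,table_b `kmer_table`s with identical k and variant.
#' @return data.frame with kmer, rank_a, rank_b, delta and nan_flag.
#' @export
kmer_rank_delta <- function(table_a, table_b) {
  if (!identical(attr(table_a, "k"), attr(table_b, "k"))) stop("k mismatch")
  if (!identical(attr(table_a, "variant"), attr(table_b, "variant")))
    stop("variant mismatch")
  stopifnot(identical(table_a$kmer, table_b$kmer))
  ra <- kmer_ranks(table_a)
  rb <- kmer_ranks(table_b)
  data.frame(kmer = table_a$kmer, rank_a = ra, rank_b = rb, delta = ra - rb,
             nan_flag = is.nan(table_a$score) | is.nan(table_b$score),
             stringsAsFactors = FALSE)
}

#' Jaccard index of the top-ranked k-mer fractions of two tables
#'
#' The top `ceiling(fraction * 4^k)` k-mers of each table are compared as
#' sets: `|A intersect B| / |A union B|`.
#'
#' @param table_a,table_b `kmer_table`s with the same k.
#' @param fraction top fraction in (0, 1], default 0.10.
#' @return a value in `[0, 1]`.
#' @export
top_fraction_jaccard <- function(table_a, table_b, fraction = 0.10) {
  if (!identical(attr(table_a, "k"), attr(table_b, "k"))) stop("k mismatch")
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(table_a) == 0L || nrow(table_b) == 0L) stop("empty table")
  n_top <- as.integer(ceiling(fraction * nrow(table_a)))
  top <- function(tb) tb$kmer[order(kmer_ranks(tb))][seq_len(n_top)]
  A <- top(table_a); B <- top(table_b)
  length(intersect(A, B)) / length(union(A, B))
}

#' Write a k-mer table as TSV (kmer, score, count, rank)
#' @param table a `kmer_table`.
#' @param path output path.
#' @export
write_kmer_table <- function(table, path) {
  out <- as.data.frame(table)
  out$rank <- kmer_ranks(table)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
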