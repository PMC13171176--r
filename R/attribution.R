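#' Dinucleotide-preserving sequence shuffles
#'
#' Generates uniform-random Eulerian rearrangements (the Altschul–Erickson
#' construction): every shuffle has exactly the input's dinucleotide count
#' vector and preserves the first and last base. Runs of `N` break the
#' dinucleotide graph, so the sequence is shuffled segment-wise between
#' `N`s with the `N` positions fixed.
#'
#' @param sequence character scalar over A/C/G/T (plus N), length >= 2.
#' @param n number of shuffles.
#' @param seed integer seed.
#' @return character vector of `n` shuffled sequences.
#' @export
dinuc_shuffle <- function(sequence, n = 100L, seed = 1L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) stop("sequence must have length >= 2")
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad))
    stop(sprintf("invalid character '%s' at position %d",
                 chars[which(bad)[1]], which(bad)[1]))
  is_n <- chars == "N"
  # segments of non-N positions
  seg_id <- cumsum(c(TRUE, diff(is_n) != 0))
  segments <- split(seq_along(chars), seg_id)
  segments <- segments[!vapply(segments, function(ix) is_n[ix[1]], logical(1))]
  with_seed(derive_seed(seed, "dinuc"), {
    vapply(seq_len(n), function(j) {
      out <- chars
      for (ix in segments) {
        if (length(ix) < 2L) next
        code <- match(chars[ix], c("A", "C", "G", "T")) - 1L
        out[ix] <- c("A", "C", "G", "T")[dinuc_shuffle_one(code) + 1L]
      }
      paste(out, collapse = "")
    }, character(1))
  })
}

#' Build attribution background samples for one input
#'
#' For DNA channels the background sequence is a dinucleotide-preserving
#' shuffle; for an ATAC channel the track positions are randomly permuted,
#' one independent permutation per background sample.
#'
#' @param x an L x C input matrix (channels A, C, G, T and optionally ATAC,
#'   or ATAC alone).
#' @param n number of backgrounds.
#' @param seed integer seed.
#' @return an array (L, C, n) of background samples.
#' @export
make_backgrounds <- function(x, n = 100L, seed = 1L) {
  L <- nrow(x); C <- ncol(x)
  bg <- array(0, dim = c(L, C, n))
  has_dna <- C >= 4L
  atac_col <- if (C %in% c(1L, 5L)) C else NA_integer_
  if (has_dna) {
    seq_chr <- decode_one_hot(t(x[, 1:4]))
    shufs <- dinuc_shuffle(seq_chr, n = n, seed = derive_seed(seed, "bg-seq"))
    for (j in seq_len(n)) bg[, 1:4, j] <- t(one_hot_encode(shufs[j]))
  }
  if (!is.na(atac_col)) {
    with_seed(derive_seed(seed, "bg-atac"), {
      for (j in seq_len(n)) bg[, atac_col, j] <- x[sample(L), atac_col]
    })
  }
  bg
}

#' Attribution scores against shuffled backgrounds
#'
#' Background-averaged integrated gradients: for each background b, the
#' straight-line path integral of the model gradient from b to the sample
#' is approximated by an m-point midpoint rule, giving per-channel,
#' per-position scores `(x - b) * mean_t grad(b + (t-0.5)/m (x - b))`,
#' averaged over backgrounds. The scores satisfy the completeness
#' (efficiency) property: their sum approximates
#' `f(x) - mean_b f(b)`; with `refine_tol` set, the number of steps is
#' doubled until the relative completeness gap falls below the tolerance.
#' For a linear model the scores are exact Shapley values.
#'
#' @param model a `gex_cnn` (or `gex_checkpoint`).
#' @param x an L x C input matrix.
#' @param backgrounds array (L, C, n) from [make_backgrounds()].
#' @param n_steps initial number of path steps.
#' @param refine_tol relative completeness tolerance (NULL: no refinement).
#' @param max_steps refinement cap.
#' @param gene_id,fold,seed optional provenance carried in the result.
#' @return an `attribution` object: list with `scores` (L x C),
#'   `completeness_gap` (relative), `f_x`, `f_bg_mean`, `n_backgrounds`,
#'   `n_steps` and provenance fields.
#' @export
attribute <- function(model, x, backgrounds, n_steps = 64L,
                      refine_tol = NULL, max_steps = 2048L,
                      gene_id = NA_character_, fold = NA_integer_,
                      seed = NA_integer_) {
  if (inherits(model, "gex_checkpoint")) model <- model$model
  L <- nrow(x); C <- ncol(x)
  if (!all(dim(backgrounds)[1:2] == c(L, C)))
    stop("background shape does not match the sample")
  nb <- dim(backgrounds)[3]
  f_x <- as.numeric(predict(model, x))
  f_bg <- predict(model, backgrounds)
  target <- f_x - mean(f_bg)

  run_ig <- function(m) {
    scores <- matrix(0, L, C)
    # batch the m path points of each background through the network
    chunk <- max(1L, 1024L %/% m)
    for (b0 in seq(1L, nb, by = chunk)) {
      bidx <- b0:min(b0 + chunk - 1L, nb)
      pts <- array(0, dim = c(L, C, length(bidx) * m))
      diffs <- array(0, dim = c(L, C, length(bidx)))
      for (jj in seq_along(bidx)) {
        b <- backgrounds[, , bidx[jj]]
        d <- x - b
        diffs[, , jj] <- d
        for (t in seq_len(m))
          pts[, , (jj - 1L) * m + t] <- b + (t - 0.5) / m * d
      }
      g <- input_gradients(model, pts)
      for (jj in seq_along(bidx)) {
        gbar <- rowMeans(g[, , (jj - 1L) * m + seq_len(m), drop = FALSE], dims = 2L)
        scores <- scores + diffs[, , jj] * gbar
      }
    }
    scores / nb
  }

  m <- as.integer(n_steps)
  scores <- run_ig(m)
  gap <- abs(sum(scores) - target) / max(abs(target), 1e-12)
  if (!is.null(refine_tol)) {
    while (gap > refine_tol && m < max_steps) {
      m <- m * 2L
      scores <- run_ig(m)
      gap <- abs(sum(scores) - target) / max(abs(target), 1e-12)
    }
  }
  structure(list(scores = scores, completeness_gap = gap, f_x = f_x,
                 f_bg_mean = mean(f_bg), n_backgrounds = nb, n_steps = m,
                 gene_id = gene_id, fold = fold, seed = seed),
            class = "attribution")
}

#' Three-stage positional aggregation of attributions
#'
#' Stage 1: for each gene (within its fold), average the per-position,
#' per-channel scores across seeds. Stage 2: concatenate the per-gene means
#' of all held-out test genes across the folds. Stage 3: average across
#' genes at each position and channel. Because the test folds partition the
#' genes, every gene contributes exactly once.
#'
#' @param attributions list of `attribution` objects with gene_id, fold and
#'   seed provenance set.
#' @return a list with `profile` (L x C mean score matrix), `n_genes` and
#'   `per_gene` (list of seed-averaged L x C matrices, named by gene).
#' @export
aggregate_positional <- function(attributions) {
  genes <- vapply(attributions, function(a) a$gene_id, character(1))
  seeds <- vapply(attributions, function(a) a$seed, numeric(1))
  if (anyNA(genes) || anyNA(seeds))
    stop("attributions must carry gene_id and seed provenance")
  all_seeds <- sort(unique(seeds))
  per_gene <- list()
  gaps <- character(0)
  for (g in unique(genes)) {
    sel <- attributions[genes == g]
    have <- sort(vapply(sel, function(a) a$seed, numeric(1)))
    if (!identical(have, all_seeds)) {
      gaps <- c(gaps, sprintf("gene %s: seeds {%s} missing", g,
                              paste(setdiff(all_seeds, have), collapse = ",")))
      next
    }
    per_gene[[g]] <- Reduce(`+`, lapply(sel, function(a) a$scores)) / length(sel)
  }
  if (length(gaps) > 0L)
    stop("incomplete seed grid:\n", paste(gaps, collapse = "\n"))
  profile <- Reduce(`+`, per_gene) / length(per_gene)
  list(profile = profile, n_genes = length(per_gene), per_gene = per_gene)
}

#' Per-channel Spearman correlation of an attribution profile with the
#' ATAC input track
#'
#' @param profile an L x C mean attribution profile.
#' @param track length-L mean ATAC input track.
#' @return named numeric vector, one Spearman coefficient per channel (NaN
#'   with a warning for constant channels).
#' @export
channel_track_correlation <- function(profile, track) {
  if (nrow(profile) != length(track)) stop("length mismatch")
  C <- ncol(profile)
  nms <- c("A", "C", "G", "T", "ATAC")[seq_len(C)]
  out <- vapply(seq_len(C), function(ci) {
    v <- profile[, ci]
    if (stats::sd(v) == 0 || stats::sd(track) == 0) {
      warning(sprintf("channel %s: constant profile; Spearman NaN", nms[ci]))
      return(NaN)
    }
    stats::cor(v, track, method = "spearman")
  }, numeric(1))
  stats::setNames(out, nms)
}

#' Export attribution arrays for external motif discovery
#'
#' Writes, for every gene whose auATAC exceeds the threshold, the
#' one-hot sequence, the actual per-base contributions (scores masked by
#' the one-hot) and the hypothetical contributions (scores on all four DNA
#' rows) as plain TSV matrices in a per-gene directory layout consumable by
#' downstream motif-discovery tooling.
#'
#' @param per_gene named list of seed-averaged L x C score matrices (e.g.
#'   from [aggregate_positional()]`$per_gene`).
#' @param onehots named list of 4 x L one-hot matrices.
#' @param auatac named per-gene auATAC vector.
#' @param threshold export genes with auATAC strictly greater than this
#'   (default: the mean auATAC over the supplied genes).
#' @param dir output directory.
#' @return invisibly, the character vector of exported gene IDs.
#' @export
export_for_modisco <- function(per_gene, onehots, auatac,
                               threshold = mean(auatac), dir) {
  genes <- names(per_gene)
  pass <- genes[auatac[genes] > threshold]
  if (length(pass) == 0L) stop("no genes pass the auATAC filter")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in pass) {
    hyp <- t(per_gene[[g]][, 1:4])         # 4 x L hypothetical scores
    act <- hyp * onehots[[g]]              # masked to the actual bases
    utils::write.table(onehots[[g]], file.path(dir, paste0(g, ".onehot.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(hyp, file.path(dir, paste0(g, ".hyp.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(act, file.path(dir, paste0(g, ".contrib.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(pass)
}
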