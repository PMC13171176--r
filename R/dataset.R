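#' Assemble a model-ready dataset from sequences, tracks and GEx
#'
#' Builds the (L, C, n) input array: channels in fixed order A, C, G, T and,
#' when accessibility is supplied, the normalized ATAC track as channel 5.
#'
#' @param sequences named character vector of promoter sequences (all the
#'   same length), or a list of precomputed 4 x L one-hot matrices.
#' @param atac optional genes x L matrix of normalized ATAC tracks, rownames
#'   matching the sequence names.
#' @param gex named numeric vector of GEx targets in `[0, 1]`.
#' @param gene_ids optional explicit gene ordering; defaults to the sequence
#'   names.
#' @return an object of class `gex_dataset`: list with `x` (array L x C x n),
#'   `y`, `gene_ids` and `channels`.
#' @export
build_dataset <- function(sequences, atac = NULL, gex, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- names(sequences)
  stopifnot(!is.null(gene_ids), all(gene_ids %in% names(gex)))
  n <- length(gene_ids)
  onehots <- if (is.list(sequences)) sequences[gene_ids]
             else lapply(sequences[gene_ids], one_hot_encode)
  L <- ncol(onehots[[1]])
  C <- if (is.null(atac)) 4L else 5L
  x <- array(0, dim = c(L, C, n))
  for (i in seq_len(n)) {
    x[, 1:4, i] <- t(onehots[[i]])
    if (C == 5L) x[, 5L, i] <- atac[gene_ids[i], ]
  }
  structure(list(x = x, y = unname(gex[gene_ids]), gene_ids = gene_ids,
                 channels = c("A", "C", "G", "T", "ATAC")[seq_len(C)]),
            class = "gex_dataset")
}

#' Subset a dataset by gene IDs or indices
#' @param dataset a `gex_dataset`.
#' @param genes character gene IDs or integer indices.
#' @return the subset `gex_dataset`, order following `genes`.
#' @export
subset_dataset <- function(dataset, genes) {
  idx <- if (is.character(genes)) match(genes, dataset$gene_ids) else genes
  if (anyNA(idx)) stop("unknown gene id(s): ",
                       paste(genes[is.na(idx)], collapse = ", "))
  structure(list(x = dataset$x[, , idx, drop = FALSE],
                 y = dataset$y[idx],
                 gene_ids = dataset$gene_ids[idx],
                 channels = dataset$channels),
            class = "gex_dataset")
}

#' Select input channels for an ablation experiment
#'
#' The architecture is unchanged apart from the input channels: `atac_only`
#' keeps the ATAC row (1 channel), `dna_only` the four one-hot DNA rows,
#' `dna_atac` all five. Targets and gene order are untouched.
#'
#' @param dataset a 5-channel `gex_dataset`.
#' @param mode one of "atac_only", "dna_only", "dna_atac".
#' @return a `gex_dataset` with the selected channels.
#' @export
ablate_channels <- function(dataset, mode = c("dna_atac", "dna_only", "atac_only")) {
  mode <- match.arg(mode)
  if (dim(dataset$x)[2] != 5L) stop("ablation requires a 5-channel dataset")
  keep <- switch(mode, dna_atac = 1:5, dna_only = 1:4, atac_only = 5L)
  structure(list(x = dataset$x[, keep, , drop = FALSE],
                 y = dataset$y,
                 gene_ids = dataset$gene_ids,
                 channels = dataset$channels[keep]),
            class = "gex_dataset")
}

#' @export
print.gex_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<gex_dataset> %d genes, %d channels (%s), L = %d\n",
              d[3], d[2], paste(x$channels, collapse = ","), d[1]))
  invisible(x)
}
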