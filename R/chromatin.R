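#' Read an ATAC fragment file
#'
#' Fragment files are BED-like tab-separated text with columns chrom, start,
#' end, and optionally barcode and a per-fragment count, 0-based half-open.
#' Gzip-compressed files are handled transparently.
#'
#' @param path path to the fragments file.
#' @return a `data.table` with columns chrom, start, end and, when present,
#'   barcode and count.
#' @export
read_fragments <- function(path) {
  fr <- data.table::fread(path, header = FALSE)
  nms <- c("chrom", "start", "end", "barcode", "count")
  data.table::setnames(fr, nms[seq_len(min(ncol(fr), 5L))])
  fr
}

#' Build a raw per-base coverage track over a promoter window
#'
#' Counts, for every base of the window, the fragments overlapping it
#' (full-fragment coverage, optionally weighted by a count column). For
#' minus-strand genes the track is reversed so that index i of the track
#' matches index i of the coding-strand promoter sequence. Fragments with
#' `end <= start` are skipped with a warning.
#'
#' @param fragments data.frame with chrom, start, end (0-based half-open)
#'   and optionally count.
#' @param chrom,window_start,window_end the window, 0-based half-open.
#' @param strand "+" or "-".
#' @param weight_col optional name of a per-fragment count column; when NULL
#'   every fragment counts once.
#' @param cut_sites when TRUE, count Tn5 cut sites (fragment ends) per base
#'   instead of full-fragment coverage.
#' @return a numeric vector of length `window_end - window_start`.
#' @export
build_raw_track <- function(fragments, chrom, window_start, window_end,
                            strand = "+", weight_col = NULL,
                            cut_sites = FALSE) {
  L <- window_end - window_start
  stopifnot(L >= 1L)
  fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
  bad <- fr$end <= fr$start
  if (any(bad)) {
    warning(sprintf("skipping %d fragment(s) with end <= start", sum(bad)))
    fr <- fr[!bad, , drop = FALSE]
  }
  w <- if (!is.null(weight_col)) as.numeric(fr[[weight_col]]) else rep(1, nrow(fr))
  track <- numeric(L)
  if (nrow(fr) > 0L) {
    if (cut_sites) {
      pos <- c(fr$start, fr$end - 1L) - window_start + 1L
      ww <- c(w, w)
      keep <- pos >= 1L & pos <= L
      if (any(keep)) {
        acc <- tapply(ww[keep], pos[keep], sum)
        track[as.integer(names(acc))] <- as.numeric(acc)
      }
    } else {
      ir <- IRanges::IRanges(start = fr$start + 1L, end = fr$end)
      cov <- IRanges::coverage(ir, weight = w, width = max(window_end, max(fr$end)))
      track <- as.numeric(cov)[(window_start + 1L):window_end]
      track[is.na(track)] <- 0
    }
  }
  if (identical(strand, "-")) track <- rev(track)
  track
}

#' Smooth a track with a discrete Gaussian filter
#'
#' Convolves with a normalized Gaussian kernel truncated at 4 standard
#' deviations, using half-sample symmetric (reflect) boundary handling, so
#' total signal is conserved.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in bases (default 20).
#' @return the smoothed vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma = 20) {
  stopifnot(sigma > 0)
  L <- length(x)
  if (L == 0L) return(x)
  r <- as.integer(ceiling(4 * sigma))
  kern <- dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  # reflect (half-sample symmetric) index mapping, valid for any r
  p <- (1L - r):(L + r)
  q <- (p - 1L) %% (2L * L)
  idx <- ifelse(q < L, q + 1L, 2L * L - q)
  xp <- x[idx]
  sm <- stats::filter(xp, kern, sides = 2)
  as.numeric(sm[(r + 1L):(r + L)])
}

#' Min-max normalize the ATAC tracks of one cell type
#'
#' A single global minimum and maximum over all positions of all tracks of
#' the cell type define the affine map, so between-gene accessibility
#' differences are preserved. If all values are equal the output is all
#' zeros.
#'
#' @param tracks a genes x positions numeric matrix (or a single numeric
#'   vector, treated as one track).
#' @return the normalized tracks, same shape, values in `[0, 1]`.
#' @export
minmax_normalize <- function(tracks) {
  vec <- is.null(dim(tracks))
  m <- min(tracks); M <- max(tracks)
  if (M == m) {
    out <- tracks * 0
  } else {
    out <- (tracks - m) / (M - m)
  }
  if (vec) as.numeric(out) else out
}

#' Area under a normalized ATAC track (auATAC)
#'
#' The unit-width rectangle (sum) convention: the sum of per-base normalized
#' values.
#'
#' @param track a numeric vector, or a genes x positions matrix for which
#'   per-gene areas are returned.
#' @return a numeric scalar or per-gene vector.
#' @export
compute_auatac <- function(track) {
  if (is.null(dim(track))) sum(track) else rowSums(track)
}

#' Build pooled, smoothed and normalized ATAC tracks for many promoters
#'
#' Runs the fixed pipeline coverage -> Gaussian smoothing -> global min-max
#' normalization for one cell type over a promoter table.
#'
#' @param fragments fragment table (see [read_fragments()]); pre-filter to
#'   the cell type's barcodes upstream.
#' @param promoters promoter data.frame with chrom, strand, window_start,
#'   window_end (all windows the same width).
#' @param sigma Gaussian kernel standard deviation.
#' @param weight_col,cut_sites forwarded to [build_raw_track()].
#' @return a list with matrices `raw`, `smoothed`, `normalized` (genes x
#'   positions, rownames gene_id) and the per-gene `auatac` vector.
#' @export
build_atac_tracks <- function(fragments, promoters, sigma = 20,
                              weight_col = NULL, cut_sites = FALSE) {
  L <- unique(promoters$window_end - promoters$window_start)
  stopifnot(length(L) == 1L)
  raw <- t(vapply(seq_len(nrow(promoters)), function(i) {
    build_raw_track(fragments, promoters$chrom[i], promoters$window_start[i],
                    promoters$window_end[i], promoters$strand[i],
                    weight_col = weight_col, cut_sites = cut_sites)
  }, numeric(L)))
  rownames(raw) <- promoters$gene_id
  smoothed <- t(apply(raw, 1, gaussian_smooth, sigma = sigma))
  rownames(smoothed) <- promoters$gene_id
  normalized <- minmax_normalize(smoothed)
  list(raw = raw, smoothed = smoothed, normalized = normalized,
       auatac = compute_auatac(normalized))
}

#' Read a single-cell UMI count matrix in Matrix Market format
#'
#' @param mtx_path path to the MTX file (genes x cells or cells x genes;
#'   rows are matched to the features list).
#' @param features_path text file of gene identifiers (first column used).
#' @param barcodes_path text file of cell barcodes.
#' @return a sparse `dgCMatrix`, genes in rows, barcodes in columns.
#' @export
read_umi_matrix <- function(mtx_path, features_path, barcodes_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  feats <- data.table::fread(features_path, header = FALSE)[[1]]
  cells <- data.table::fread(barcodes_path, header = FALSE)[[1]]
  if (nrow(m) == length(cells) && ncol(m) == length(feats) &&
      length(feats) != length(cells)) m <- Matrix::t(m)
  stopifnot(nrow(m) == length(feats), ncol(m) == length(cells))
  dimnames(m) <- list(feats, cells)
  m
}

resolve_cells <- function(umi, cell_labels, cell_type) {
  if (is.data.frame(cell_labels)) {
    labs <- stats::setNames(as.character(cell_labels[[2]]),
                            as.character(cell_labels[[1]]))
    labs <- labs[colnames(umi)]
  } else if (!is.null(names(cell_labels))) {
    labs <- cell_labels[colnames(umi)]
  } else {
    stopifnot(length(cell_labels) == ncol(umi))
    labs <- cell_labels
  }
  which(!is.na(labs) & labs == cell_type)
}

#' Compute GEx: the proportion of cells expressing each gene
#'
#' For each gene, the fraction of cells of the requested cell type with a
#' nonzero UMI count — a probability of expression in `[0, 1]`.
#'
#' @param umi genes x cells count matrix (sparse or dense).
#' @param cell_labels a two-column data.frame (barcode, cell_type), a named
#'   character vector keyed by barcode, or an unnamed vector aligned with
#'   the matrix columns.
#' @param cell_type the cell type of interest.
#' @return a named numeric vector of per-gene proportions.
#' @export
compute_gex <- function(umi, cell_labels, cell_type) {
  cells <- resolve_cells(umi, cell_labels, cell_type)
  if (length(cells) == 0L) stop("no cells of type ", cell_type)
  sub <- umi[, cells, drop = FALSE]
  gex <- as.numeric(Matrix::rowSums(sub > 0)) / length(cells)
  stats::setNames(gex, rownames(umi))
}

#' Select highly variable genes within a cell type
#'
#' Ranks genes by the variance-to-mean ratio (dispersion) of per-cell UMI
#' counts within the cell type and returns the top `n` gene IDs, ties broken
#' by lexicographic gene ID. The exact highly-variable definition used for
#' the published evaluations is not fully specified; this dispersion rule is
#' a documented stand-in.
#'
#' @param umi genes x cells count matrix.
#' @param cell_labels see [compute_gex()].
#' @param cell_type the cell type of interest.
#' @param n number of genes to return.
#' @return a character vector of `n` gene IDs.
#' @export
select_highly_variable <- function(umi, cell_labels, cell_type, n) {
  stopifnot(n >= 1L)
  if (n > nrow(umi)) stop("n exceeds the number of genes")
  cells <- resolve_cells(umi, cell_labels, cell_type)
  if (length(cells) == 0L) stop("no cells of type ", cell_type)
  sub <- as.matrix(umi[, cells, drop = FALSE])
  mu <- rowMeans(sub)
  v <- apply(sub, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ids <- rownames(umi) %||% as.character(seq_len(nrow(umi)))
  ids[order(-disp, ids)][seq_len(n)]
}

#' Write a gene x cell-type table as TSV
#' @param mat matrix with rownames (genes) and colnames (cell types).
#' @param path output path.
#' @export
write_gene_table <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
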