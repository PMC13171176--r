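#' Read a GENCODE-dialect GTF file
#'
#' Minimal line-aware GTF reader used for promoter selection. Coordinates in
#' the returned table are the file's 1-based inclusive coordinates; callers
#' convert to the package's 0-based half-open convention. Malformed lines
#' (not nine tab-separated fields) raise an error naming the offending line
#' number, which is why this reader is line-based.
#'
#' @param path path to a GTF file (plain or gzip).
#' @return a `data.table` with columns chrom, source, feature, start, end,
#'   score, strand, frame, attributes.
#' @keywords internal
read_gtf <- function(path) {
  lines <- data.table::fread(path, sep = NULL, header = FALSE,
                             col.names = "line", quote = "")$line
  keep <- !startsWith(lines, "#")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(keep)[which(nf != 9L)[1]]
    stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields, found %d",
                 bad, path, nf[which(nf != 9L)[1]]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  out <- data.table::data.table(
    chrom = m[, 1], source = m[, 2], feature = m[, 3],
    start = suppressWarnings(as.integer(m[, 4])),
    end = suppressWarnings(as.integer(m[, 5])),
    score = m[, 6], strand = m[, 7], frame = m[, 8], attributes = m[, 9]
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(keep)[which(is.na(out$start) | is.na(out$end))[1]]
    stop(sprintf("malformed GTF line %d in %s: non-numeric coordinates", bad, path))
  }
  out
}

gtf_attr <- function(attributes, key) {
  pat <- paste0(key, ' "([^"]*)"')
  m <- regmatches(attributes, regexec(pat, attributes))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Select canonical promoters from a GTF annotation
#'
#' Filters a GENCODE-style annotation to protein-coding genes and picks one
#' transcript per gene: the one tagged "Ensembl_canonical", falling back to
#' the transcript with the 5'-most TSS (ties broken by lexicographic
#' transcript ID) when the tag is absent; every fallback is logged via
#' [message()] when `options(chromexpr.quiet = FALSE)`. The TSS is reported
#' 0-based; on the minus strand it is the transcript's 5'-most base, i.e.
#' the larger genomic coordinate.
#'
#' @param gtf_path path to the GTF file.
#' @param chromosome_filter chromosomes to keep; the default keeps human
#'   autosomes only. `NULL` keeps everything.
#' @return a `data.frame` with columns gene_id, chrom, strand, tss (0-based),
#'   transcript_id and canonical_tag (logical), one row per gene, sorted by
#'   gene_id. Window coordinates and sequences are filled in later by
#'   [extract_promoter_windows()].
#' @export
select_canonical_promoters <- function(gtf_path,
                                       chromosome_filter = paste0("chr", 1:22)) {
  gtf <- read_gtf(gtf_path)
  tx <- gtf[gtf$feature == "transcript", ]
  if (nrow(tx) == 0L) stop("no transcript features in ", gtf_path)
  tx$gene_id <- gtf_attr(tx$attributes, "gene_id")
  tx$transcript_id <- gtf_attr(tx$attributes, "transcript_id")
  tx$gene_type <- gtf_attr(tx$attributes, "gene_type")
  tx <- tx[!is.na(tx$gene_type) & tx$gene_type == "protein_coding", ]
  if (!is.null(chromosome_filter)) tx <- tx[tx$chrom %in% chromosome_filter, ]
  if (nrow(tx) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      transcript_id = character(), canonical_tag = logical()))
  }
  tx$canonical <- grepl('tag "Ensembl_canonical"', tx$attributes, fixed = TRUE)
  # 0-based TSS: 5' end of the transcript on its coding strand
  tx$tss <- ifelse(tx$strand == "+", tx$start - 1L, tx$end - 1L)

  pick <- function(sub) {
    if (any(sub$canonical)) {
      cand <- sub[sub$canonical, ]
    } else {
      cx_log("no Ensembl_canonical tag for gene %s; falling back to 5'-most TSS",
             sub$gene_id[1])
      # 5'-most TSS: smallest start on '+', largest end on '-'
      key <- ifelse(sub$strand == "+", sub$tss, -sub$tss)
      cand <- sub[key == min(key), ]
    }
    cand <- cand[order(cand$transcript_id), ][1, ]
    cand
  }
  sel <- do.call(rbind, lapply(split(tx, tx$gene_id), pick))
  sel <- sel[order(sel$gene_id), ]
  data.frame(gene_id = sel$gene_id, chrom = sel$chrom, strand = sel$strand,
             tss = as.integer(sel$tss), transcript_id = sel$transcript_id,
             canonical_tag = sel$canonical, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Load a genome FASTA as a DNAStringSet
#'
#' @param x path to a FASTA file, a `Biostrings::DNAStringSet`, or a named
#'   character vector of sequences.
#' @return a `DNAStringSet` named by chromosome.
#' @export
load_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    g <- Biostrings::readDNAStringSet(x)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  if (is.character(x) && !is.null(names(x))) return(Biostrings::DNAStringSet(x))
  stop("cannot interpret genome input")
}

#' Extract a TSS-centered promoter window for one gene
#'
#' Returns the coding-strand sequence of the `2*flank` window centered on
#' the TSS: on the plus strand `[tss - flank, tss + flank)` of the genome,
#' on the minus strand the reverse complement of
#' `[tss - flank + 1, tss + flank + 1)`. In both cases the TSS base sits at
#' 0-based index `flank` of the returned sequence (complemented on the
#' minus strand). Windows crossing a chromosome end raise an error; there
#' is no padding.
#'
#' @param record a list or one-row data.frame with fields chrom, strand and
#'   tss (0-based).
#' @param genome anything accepted by [load_genome()].
#' @param flank half window width in bp (>= 1).
#' @return the record as a list with sequence, window_start and window_end
#'   (0-based half-open genomic coordinates) filled in.
#' @export
extract_window <- function(record, genome, flank = 1000L) {
  stopifnot(flank >= 1L)
  genome <- load_genome(x = genome)
  record <- as.list(record)
  chrom <- record$chrom
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome[chrom])
  tss <- as.integer(record$tss)
  if (identical(record$strand, "+")) {
    ws <- tss - flank; we <- tss + flank
  } else if (identical(record$strand, "-")) {
    ws <- tss - flank + 1L; we <- tss + flank + 1L
  } else stop("strand must be '+' or '-'")
  if (ws < 0L || we > len)
    stop(sprintf("window [%d,%d) for gene %s out of bounds on %s (length %d)",
                 ws, we, record$gene_id %||% "?", chrom, len))
  s <- Biostrings::subseq(genome[[chrom]], start = ws + 1L, end = we)
  if (record$strand == "-") s <- Biostrings::reverseComplement(s)
  record$window_start <- ws
  record$window_end <- we
  record$sequence <- toupper(as.character(s))
  record
}

#' Extract promoter windows for a table of genes
#'
#' Vectorized companion to [extract_window()]: genes whose window would
#' cross a chromosome boundary are dropped (and logged), not padded.
#'
#' @param promoters data.frame from [select_canonical_promoters()].
#' @param genome anything accepted by [load_genome()].
#' @param flank half window width in bp.
#' @return `promoters` with columns window_start, window_end and sequence
#'   added, out-of-bounds genes removed.
#' @export
extract_promoter_windows <- function(promoters, genome, flank = 1000L) {
  genome <- load_genome(genome)
  rows <- vector("list", nrow(promoters))
  kept <- logical(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    rec <- tryCatch(extract_window(promoters[i, ], genome, flank),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      cx_log("dropping gene %s: %s", promoters$gene_id[i], conditionMessage(rec))
    } else {
      rows[[i]] <- rec
      kept[i] <- TRUE
    }
  }
  rows <- rows[kept]
  out <- promoters[kept, , drop = FALSE]
  out$window_start <- vapply(rows, function(r) as.integer(r$window_start), integer(1))
  out$window_end <- vapply(rows, function(r) as.integer(r$window_end), integer(1))
  out$sequence <- vapply(rows, function(r) r$sequence, character(1))
  rownames(out) <- NULL
  out
}

.BASES <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' Rows are in fixed order A, C, G, T. `N` (any case) yields an all-zero
#' column; lower-case bases are treated as their upper-case base. Any other
#' character raises an error naming its position.
#'
#' @param sequence a character scalar over A/C/G/T/N.
#' @return a 4 x L binary matrix with rownames A, C, G, T.
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, c(.BASES, "N"))
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("invalid character '%s' at position %d", chars[pos], pos))
  }
  L <- length(chars)
  m <- matrix(0, nrow = 4L, ncol = L, dimnames = list(.BASES, NULL))
  hit <- idx <= 4L
  m[cbind(idx[hit], which(hit))] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Columns summing to one decode to their argmax base; all-zero columns
#' decode to `N`.
#'
#' @param m a 4 x L matrix as produced by [one_hot_encode()].
#' @return a character scalar.
#' @export
decode_one_hot <- function(m) {
  stopifnot(nrow(m) == 4L)
  if (ncol(m) == 0L) return("")
  cs <- colSums(m)
  base <- .BASES[max.col(t(m), ties.method = "first")]
  base[cs == 0] <- "N"
  paste(base, collapse = "")
}

#' Write a promoter table as tab-separated text
#' @param promoters promoter data.frame.
#' @param path output path.
#' @export
write_promoter_table <- function(promoters, path) {
  cols <- intersect(c("gene_id", "chrom", "strand", "tss",
                      "window_start", "window_end"), names(promoters))
  data.table::fwrite(promoters[, cols, drop = FALSE], path, sep = "\t")
  invisible(path)
}

#' Write promoter sequences as FASTA
#' @param promoters promoter data.frame with a sequence column.
#' @param path output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- promoters$gene_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
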