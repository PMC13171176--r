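# Small fixtures built in code at test time.

write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, feature, start, end, strand, gene_id,
                     transcript_id = paste0(gene_id, ".t1"),
                     gene_type = "protein_coding", canonical = TRUE) {
  tags <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";%s',
                  gene_id, transcript_id, gene_type,
                  if (canonical) ' tag "basic"; tag "Ensembl_canonical";' else ' tag "basic";')
  paste(chrom, "TEST", feature, start, end, ".", strand, ".", tags, sep = "\t")
}

random_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  out <- character(0)
  for (nm in names(seqs)) out <- c(out, paste0(">", nm), seqs[[nm]])
  writeLines(out, path)
  path
}

# a tiny 5-channel dataset with random inputs and targets
toy_dataset <- function(n = 12, L = 40, seed = 1) {
  set.seed(seed)
  seqs <- setNames(vapply(seq_len(n), function(i) random_dna(L), character(1)),
                   sprintf("g%02d", seq_len(n)))
  atac <- matrix(runif(n * L), n, L, dimnames = list(names(seqs), NULL))
  gex <- setNames(runif(n), names(seqs))
  build_dataset(seqs, atac, gex)
}

toy_model_config <- function(channels = 5, L = 40) {
  model_config(channels, L, conv_specs = list(c(6L, 5L, 2L), c(4L, 3L, 2L)),
               dense_sizes = c(8L), dropout = 0.1)
}
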