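#' Default planted motif set
#'
#' Three real promoter motifs at learnable width: the AP-1 half site
#' (TGACTC), the E-box (CACGTG) and the SP1 GC-box (GGGCGG), as
#' near-consensus PWMs.
#'
#' @param consensus consensus strings.
#' @param consensus_prob probability of the consensus base at each position.
#' @return list of 4 x w PWMs.
#' @export
default_motifs <- function(consensus = c("TGACTC", "CACGTG", "GGGCGG"),
                           consensus_prob = 0.92) {
  lapply(consensus, function(s) {
    chars <- strsplit(s, "")[[1]]
    pwm <- matrix((1 - consensus_prob) / 3, nrow = 4, ncol = length(chars),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm[cbind(match(chars, rownames(pwm)), seq_along(chars))] <- consensus_prob
    pwm
  })
}

#' Configuration of the synthetic multiome generator
#'
#' The generator emulates the structure of a multiome experiment at desk
#' scale: promoter-like sequences with planted transcription-factor motifs,
#' accessibility tracks peaked near the TSS (window center), and GEx values
#' in `[0, 1]` produced by a known motif-times-accessibility model:
#' `GEx = logistic(w0 + w_A * auATAC + sum_m beta[m,c] * sum_i abar_i)`,
#' where `abar_i` is the mean normalized accessibility over motif instance
#' i's footprint. All randomness flows from one master seed via named
#' substreams.
#'
#' @param n_genes number of genes.
#' @param L window length in bases.
#' @param n_cell_types number of cell types.
#' @param background_probs base probabilities (A, C, G, T).
#' @param motifs list of 4 x w PWMs (rows A, C, G, T).
#' @param effect_weights motifs x cell-types matrix of beta weights; a
#'   scalar is recycled.
#' @param accessibility_weight w_A; the default `12 / L` makes the logit
#'   contribution of a fully open window independent of window length.
#' @param intercept w0.
#' @param placement_rate Poisson mean of instances per motif per promoter.
#' @param placement_sd standard deviation (bases) of the TSS-biased motif
#'   placement around the window center, mirroring the TSS-proximal
#'   clustering of functional binding sites in real promoters; `Inf` gives
#'   uniform placement.
#' @param bump_count number of accessibility bumps per promoter.
#' @param bump_width Gaussian bump standard deviation in bases.
#' @param bump_jitter standard deviation of bump centers around the window
#'   center.
#' @param openness_shape1,openness_shape2 Beta parameters of the per-gene
#'   basal openness shared by all cell types.
#' @param openness_coupling concentration of the per-cell-type openness
#'   around the basal value (`Beta(kappa*o, kappa*(1-o))`); larger values
#'   give higher cross-cell-type accessibility correlation, as seen in real
#'   multiome data.
#' @param gc_coupling amplitude of the CpG-island-like coupling between a
#'   gene's background GC content and its basal openness (GC-rich,
#'   broadly open promoters), the main sequence-only correlate of
#'   expression in real promoters; 0 disables it.
#' @param raw_noise_sd standard deviation of the nonnegative (half-normal)
#'   noise added to raw tracks.
#' @param noise_sd GEx observation noise standard deviation (Gaussian mode).
#' @param gex_mode "gaussian" (additive noise, clipped) or "binomial"
#'   (`Binomial(n_cells, GEx)/n_cells`, integer-consistent with a UMI
#'   rendering).
#' @param n_cells cells per cell type (binomial mode and rendering).
#' @param track_sigma Gaussian smoothing sigma of the track pipeline.
#' @param seed master seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 3000L, L = 2000L, n_cell_types = 1L,
                         background_probs = rep(0.25, 4),
                         motifs = default_motifs(),
                         effect_weights = 4,
                         accessibility_weight = 12 / L,
                         intercept = -3,
                         placement_rate = 1.2,
                         placement_sd = 0.2 * L,
                         bump_count = 2L,
                         bump_width = 0.15 * L,
                         bump_jitter = 0.08 * L,
                         openness_shape1 = 2, openness_shape2 = 2,
                         openness_coupling = 20,
                         gc_coupling = 0.12,
                         raw_noise_sd = 0.05,
                         noise_sd = 0.05,
                         gex_mode = c("gaussian", "binomial"),
                         n_cells = 500L,
                         track_sigma = 20,
                         seed = 1L) {
  gex_mode <- match.arg(gex_mode)
  stopifnot(abs(sum(background_probs) - 1) < 1e-8, noise_sd >= 0,
            all(vapply(motifs, ncol, numeric(1)) <= L))
  if (length(effect_weights) == 1L)
    effect_weights <- matrix(effect_weights, length(motifs), n_cell_types)
  stopifnot(nrow(effect_weights) == length(motifs),
            ncol(effect_weights) == n_cell_types)
  structure(list(n_genes = as.integer(n_genes), L = as.integer(L),
                 n_cell_types = as.integer(n_cell_types),
                 background_probs = background_probs, motifs = motifs,
                 effect_weights = effect_weights,
                 accessibility_weight = accessibility_weight,
                 intercept = intercept, placement_rate = placement_rate,
                 placement_sd = placement_sd,
                 bump_count = as.integer(bump_count), bump_width = bump_width,
                 bump_jitter = bump_jitter,
                 openness_shape1 = openness_shape1,
                 openness_shape2 = openness_shape2,
                 openness_coupling = openness_coupling,
                 gc_coupling = gc_coupling,
                 raw_noise_sd = raw_noise_sd, noise_sd = noise_sd,
                 gex_mode = gex_mode, n_cells = as.integer(n_cells),
                 track_sigma = track_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

place_instances <- function(L, widths, counts, placement_sd = NULL,
                            max_tries = 100L) {
  # non-overlapping starts for `counts[m]` instances of each motif; when
  # placement_sd is finite, starts are TSS-biased (truncated Gaussian around
  # the window center, like TFBS density in real promoters), else uniform
  placed <- data.frame(motif = integer(0), start = integer(0), width = integer(0))
  occupied <- logical(L)
  for (m in seq_along(widths)) {
    w <- widths[m]
    for (j in seq_len(counts[m])) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        if (is.null(placement_sd) || !is.finite(placement_sd)) {
          s <- sample.int(L - w + 1L, 1L) - 1L
        } else {
          s <- as.integer(round(L / 2 + rnorm(1L, 0, placement_sd) - w / 2))
          if (s < 0L || s > L - w) next
        }
        if (!any(occupied[(s + 1L):(s + w)])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place motif instances without overlap")
      occupied[(s + 1L):(s + w)] <- TRUE
      placed <- rbind(placed,
                      data.frame(motif = m, start = s, width = w))
    }
  }
  placed
}

#' Generate a synthetic multiome-like dataset
#'
#' See [synth_config()] for the generative model. Fully deterministic given
#' the config's master seed.
#'
#' @param config a [synth_config()].
#' @return a `synth_data` list: `sequences` (named character), `tracks`
#'   (per cell type: raw/smoothed/normalized gene x L matrices and auatac),
#'   `gex` (genes x cell types realized GEx), `truth` (instances data.frame,
#'   openness, noiseless GEx, bump centers) and the config.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes; L <- config$L; nct <- config$n_cell_types
  gene_ids <- sprintf("G%05d", seq_len(n))
  widths <- vapply(config$motifs, ncol, numeric(1))

  # --- basal openness: a per-gene latent shared by all cell types
  o_base <- with_seed(derive_seed(config$seed, "openness-base"),
                      rbeta(n, config$openness_shape1, config$openness_shape2))

  # --- sequences: GC-coupled background then planted motif instances.
  # Background GC content tracks basal openness (CpG-island-like promoters
  # are broadly open), clipped to a plausible range.
  p0 <- config$background_probs
  gc0 <- p0[2] + p0[3]
  gc <- pmin(0.65, pmax(0.25, gc0 + config$gc_coupling * (2 * o_base - 1)))
  chars <- with_seed(derive_seed(config$seed, "seq-bg"), {
    m <- matrix("", n, L)
    for (g in seq_len(n)) {
      probs <- c(p0[1] / (p0[1] + p0[4]) * (1 - gc[g]),
                 p0[2] / (p0[2] + p0[3]) * gc[g],
                 p0[3] / (p0[2] + p0[3]) * gc[g],
                 p0[4] / (p0[1] + p0[4]) * (1 - gc[g]))
      m[g, ] <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs)
    }
    m
  })
  instances <- with_seed(derive_seed(config$seed, "placement"), {
    lapply(seq_len(n), function(g) {
      counts <- rpois(length(widths), config$placement_rate)
      pl <- place_instances(L, widths, counts, config$placement_sd)
      if (nrow(pl) > 0L) pl$gene_id <- gene_ids[g]
      pl
    })
  })
  chars <- with_seed(derive_seed(config$seed, "motif-draw"), {
    for (g in seq_len(n)) {
      pl <- instances[[g]]
      for (r in seq_len(nrow(pl))) {
        pwm <- config$motifs[[pl$motif[r]]]
        draw <- vapply(seq_len(ncol(pwm)), function(p)
          sample(rownames(pwm), 1L, prob = pwm[, p]), character(1))
        chars[g, (pl$start[r] + 1L):(pl$start[r] + pl$width[r])] <- draw
      }
    }
    chars
  })
  sequences <- stats::setNames(apply(chars, 1, paste, collapse = ""), gene_ids)
  instances <- do.call(rbind, instances[vapply(instances, nrow, integer(1)) > 0])

  # --- accessibility: per-gene bump profile, per-(gene, cell type) openness
  bumps <- with_seed(derive_seed(config$seed, "bumps"), {
    lapply(seq_len(n), function(g) {
      centers <- L / 2 + rnorm(config$bump_count, 0, config$bump_jitter)
      amps <- runif(config$bump_count, 0.5, 1)
      list(centers = centers, amps = amps)
    })
  })
  pos <- seq_len(L)
  profiles <- t(vapply(bumps, function(b) {
    colSums(do.call(rbind, lapply(seq_along(b$centers), function(j)
      b$amps[j] * exp(-(pos - b$centers[j])^2 / (2 * config$bump_width^2)))))
  }, numeric(L)))
  kappa <- config$openness_coupling
  openness <- with_seed(derive_seed(config$seed, "openness"), {
    ob <- pmin(pmax(o_base, 0.02), 0.98)
    matrix(rbeta(n * nct, rep(kappa * ob, nct), rep(kappa * (1 - ob), nct)),
           n, nct)
  })
  raw_noise <- with_seed(derive_seed(config$seed, "raw-noise"),
                         lapply(seq_len(nct), function(ct)
                           matrix(abs(rnorm(n * L, 0, config$raw_noise_sd)), n, L)))

  tracks <- lapply(seq_len(nct), function(ct) {
    raw <- profiles * openness[, ct] + raw_noise[[ct]]
    rownames(raw) <- gene_ids
    smoothed <- t(apply(raw, 1, gaussian_smooth, sigma = config$track_sigma))
    rownames(smoothed) <- gene_ids
    normalized <- minmax_normalize(smoothed)
    list(raw = raw, smoothed = smoothed, normalized = normalized,
         auatac = compute_auatac(normalized))
  })
  names(tracks) <- paste0("ct", seq_len(nct))

  # --- GEx from the motif x accessibility model
  noiseless <- matrix(0, n, nct, dimnames = list(gene_ids, names(tracks)))
  for (ct in seq_len(nct)) {
    norm <- tracks[[ct]]$normalized
    motif_term <- numeric(n)
    if (!is.null(instances) && nrow(instances) > 0L) {
      gidx <- match(instances$gene_id, gene_ids)
      abar <- vapply(seq_len(nrow(instances)), function(r)
        mean(norm[gidx[r], (instances$start[r] + 1L):
                            (instances$start[r] + instances$width[r])]),
        numeric(1))
      contrib <- config$effect_weights[instances$motif, ct] * abar
      agg <- tapply(contrib, gidx, sum)
      motif_term[as.integer(names(agg))] <- as.numeric(agg)
    }
    eta <- config$intercept +
      config$accessibility_weight * tracks[[ct]]$auatac + motif_term
    noiseless[, ct] <- stats::plogis(eta)
  }
  gex <- with_seed(derive_seed(config$seed, "gex-noise"), {
    if (config$gex_mode == "gaussian") {
      pmin(pmax(noiseless + matrix(rnorm(n * nct, 0, config$noise_sd), n, nct),
                0), 1)
    } else {
      matrix(rbinom(n * nct, config$n_cells, noiseless) / config$n_cells,
             n, nct)
    }
  })
  dimnames(gex) <- dimnames(noiseless)

  structure(list(sequences = sequences, tracks = tracks, gex = gex,
                 truth = list(instances = instances, openness = openness,
                              basal_openness = o_base, gc_content = gc,
                              noiseless = noiseless, bumps = bumps),
                 gene_ids = gene_ids, config = config),
            class = "synth_data")
}

#' Two-cell-type synthetic dataset with shared and private motifs
#'
#' Builds the effect-weight matrix so that shared motifs act (beta > 0) in
#' both cell types while each private motif acts in exactly one, then
#' generates a two-cell-type dataset. Overlapping shared/private sets are
#' an error.
#'
#' @param config a [synth_config()] (its motif list indexes the sets).
#' @param shared_motifs integer indices of motifs active in both cell types.
#' @param private_motifs list of two integer vectors: motifs private to
#'   cell type 1 and to cell type 2.
#' @param beta effect weight given to active motifs.
#' @return a `synth_data` with two cell types.
#' @export
make_cell_type_pair <- function(config, shared_motifs = 1L,
                                private_motifs = list(2L, 3L),
                                beta = 4) {
  priv <- unlist(private_motifs)
  if (length(intersect(shared_motifs, priv)) > 0L)
    stop("shared and private motif sets overlap")
  if (length(private_motifs) != 2L)
    stop("private_motifs must list motifs for exactly two cell types")
  nm <- length(config$motifs)
  B <- matrix(0, nm, 2L)
  B[shared_motifs, ] <- beta
  B[private_motifs[[1]], 1] <- beta
  B[private_motifs[[2]], 2] <- beta
  config$n_cell_types <- 2L
  config$effect_weights <- B
  synth_generate(config)
}

#' Model-ready dataset from synthetic data
#'
#' @param gen a `synth_data`.
#' @param cell_type cell-type index or name.
#' @return a 5-channel `gex_dataset`.
#' @export
synth_dataset <- function(gen, cell_type = 1L) {
  ct <- if (is.character(cell_type)) cell_type else names(gen$tracks)[cell_type]
  build_dataset(gen$sequences, gen$tracks[[ct]]$normalized,
                stats::setNames(gen$gex[, ct], gen$gene_ids))
}

#' Render synthetic data in the real input formats
#'
#' Inverse-renders a `synth_data` object as the on-disk formats the
#' preparation pipeline consumes, so the I/O paths can be exercised end to
#' end: a single-chromosome genome FASTA (promoters laid head to tail with
#' random spacers), a promoter table, per-cell-type fragments TSV whose
#' coverage approximates the raw tracks, a Matrix Market UMI matrix with
#' features/barcodes lists, and a barcode-to-cell-type annotation TSV.
#'
#' @param gen a `synth_data`.
#' @param dir output directory.
#' @param fragment_length mean rendered fragment length in bases.
#' @param depth sequencing-depth multiplier: rendered per-base coverage
#'   approximates `depth` times the generator's raw track.
#' @param spacer bases of random sequence between consecutive promoters.
#' @return invisibly, a named list of the file paths written.
#' @export
render_raw_formats <- function(gen, dir, fragment_length = 100L, depth = 20,
                               spacer = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- gen$config
  n <- cfg$n_genes; L <- cfg$L
  step <- L + spacer
  starts <- (seq_len(n) - 1L) * step  # 0-based gene window starts
  spacer_seq <- with_seed(derive_seed(cfg$seed, "render-spacer"),
                          paste(sample(c("A", "C", "G", "T"), spacer,
                                       replace = TRUE), collapse = ""))
  genome <- paste(vapply(seq_len(n), function(g)
    paste0(gen$sequences[g], spacer_seq), character(1)), collapse = "")
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(genome), "chrS"), fa)

  promoters <- data.frame(gene_id = gen$gene_ids, chrom = "chrS",
                          strand = "+", tss = starts + L %/% 2L,
                          window_start = starts, window_end = starts + L)
  ptab <- file.path(dir, "promoters.tsv")
  write_promoter_table(promoters, ptab)

  nct <- cfg$n_cell_types
  barcodes <- lapply(seq_len(nct), function(ct)
    sprintf("CT%d_CELL%04d", ct, seq_len(cfg$n_cells)))
  annot <- data.frame(barcode = unlist(barcodes),
                      cell_type = rep(names(gen$tracks), each = cfg$n_cells))
  an <- file.path(dir, "annotation.tsv")
  data.table::fwrite(annot, an, sep = "\t", col.names = FALSE)

  frag_path <- file.path(dir, "fragments.tsv")
  frags <- with_seed(derive_seed(cfg$seed, "render-frags"), {
    out <- list()
    for (ct in seq_len(nct)) {
      raw <- gen$tracks[[ct]]$raw
      for (g in seq_len(n)) {
        mass <- sum(raw[g, ]) * depth
        n_frag <- max(0L, round(mass / fragment_length))
        if (n_frag == 0L) next
        centers <- sample.int(L, n_frag, replace = TRUE,
                              prob = raw[g, ] + 1e-9)
        lens <- pmax(20L, round(rnorm(n_frag, fragment_length,
                                      fragment_length / 5)))
        fs <- pmax(0L, starts[g] + centers - 1L - lens %/% 2L)
        out[[length(out) + 1L]] <- data.frame(
          chrom = "chrS", start = fs, end = fs + lens,
          barcode = sample(barcodes[[ct]], n_frag, replace = TRUE))
      }
    }
    data.table::rbindlist(out)
  })
  data.table::setorder(frags, start)
  data.table::fwrite(frags, frag_path, sep = "\t", col.names = FALSE)

  # UMI counts: a cell expresses gene g with probability GEx[g, ct]
  umi <- with_seed(derive_seed(cfg$seed, "render-umi"), {
    cols <- list()
    for (ct in seq_len(nct)) {
      p <- gen$gex[, ct]
      expressed <- matrix(rbinom(n * cfg$n_cells, 1L, p), n, cfg$n_cells)
      counts <- expressed * (1L + matrix(rpois(n * cfg$n_cells, 1), n,
                                         cfg$n_cells))
      cols[[ct]] <- counts
    }
    methods::as(Matrix::Matrix(do.call(cbind, cols), sparse = TRUE),
                "CsparseMatrix")
  })
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(umi, mtx)
  feat <- file.path(dir, "features.tsv")
  writeLines(gen$gene_ids, feat)
  bc <- file.path(dir, "barcodes.tsv")
  writeLines(annot$barcode, bc)

  invisible(list(genome = fa, promoters = ptab, fragments = frag_path,
                 annotation = an, mtx = mtx, features = feat, barcodes = bc))
}
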