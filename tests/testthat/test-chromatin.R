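test_that("raw track counts overlapping fragments per base", {
  fr <- data.frame(chrom = "chr1", start = 1005L, end = 1008L)
  expect_equal(build_raw_track(fr, "chr1", 1000L, 1010L),
               c(0, 0, 0, 0, 0, 1, 1, 1, 0, 0))
  none <- data.frame(chrom = "chr2", start = 1L, end = 5L)
  expect_equal(build_raw_track(none, "chr1", 1000L, 1010L), rep(0, 10))
})

test_that("minus-strand tracks are reversed to sequence orientation", {
  fr <- data.frame(chrom = "chr1", start = 1000L, end = 1002L)
  minus <- build_raw_track(fr, "chr1", 1000L, 1010L, strand = "-")
  expect_equal(minus, rev(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_equal(which(minus > 0), c(9L, 10L))
})

test_that("raw coverage matches a brute-force overlap oracle with weights", {
  set.seed(3)
  for (rep in 1:10) {
    fr <- data.frame(chrom = "chr1",
                     start = sample(0:80, 15, replace = TRUE))
    fr$end <- fr$start + sample(1:20, 15, replace = TRUE)
    got <- build_raw_track(fr, "chr1", 20L, 60L)
    expect_equal(got, oracle_coverage(fr, 20L, 60L))
    # count-weighted coverage doubles when every weight is 2
    fr$count <- 2L
    expect_equal(build_raw_track(fr, "chr1", 20L, 60L, weight_col = "count"),
                 2 * got)
  }
})

test_that("invalid fragments are skipped with a warning", {
  fr <- data.frame(chrom = "chr1", start = c(5L, 30L), end = c(10L, 30L))
  expect_warning(tr <- build_raw_track(fr, "chr1", 0L, 40L), "end <= start")
  expect_equal(sum(tr), 5)
})

test_that("gaussian smoothing matches the closed-form impulse response", {
  x <- numeric(401)
  x[201] <- 1
  sm <- gaussian_smooth(x, sigma = 20)
  expect_equal(sm[201], 1 / (20 * sqrt(2 * pi)), tolerance = 1e-4)
  # symmetric around the impulse
  expect_equal(sm[201 - 15], sm[201 + 15], tolerance = 1e-12)
  expect_equal(gaussian_smooth(numeric(50), 20), numeric(50))
})

test_that("gaussian smoothing conserves mass under reflect boundaries", {
  set.seed(5)
  for (rep in 1:10) {
    x <- runif(sample(c(120, 400, 2000), 1))
    expect_equal(sum(gaussian_smooth(x, sigma = 20)), sum(x), tolerance = 1e-6)
  }
  # short vector relative to the kernel still conserves mass
  x <- runif(30)
  expect_equal(sum(gaussian_smooth(x, sigma = 20)), sum(x), tolerance = 1e-6)
})

test_that("min-max normalization is global per cell type", {
  tracks <- rbind(c(0, 2), c(1, 4))
  expect_equal(minmax_normalize(tracks), rbind(c(0, 0.5), c(0.25, 1)))
  expect_equal(minmax_normalize(c(3, 3, 3)), c(0, 0, 0))
  set.seed(9)
  m <- matrix(rnorm(200), 10, 20)
  nm <- minmax_normalize(m)
  expect_equal(max(nm), 1)
  expect_equal(min(nm), 0)
  # order preservation
  expect_equal(order(as.vector(m)), order(as.vector(nm)))
})

test_that("auATAC is the unit-width rectangle sum", {
  expect_equal(compute_auatac(rep(1, 2000)), 2000)
  expect_equal(compute_auatac(c(0, 0.5, 1)), 1.5)
  expect_equal(compute_auatac(numeric(10)), 0)
  m <- rbind(a = c(0.2, 0.3), b = c(1, 0))
  expect_equal(compute_auatac(m), c(a = 0.5, b = 1))
})

test_that("GEx is the proportion of expressing cells and scale-invariant", {
  umi <- Matrix::Matrix(rbind(g1 = c(0, 2, 0, 1), g2 = c(0, 0, 0, 0),
                              g3 = c(1, 1, 1, 4)), sparse = TRUE)
  colnames(umi) <- paste0("c", 1:4)
  labs <- setNames(rep("T", 4), colnames(umi))
  gex <- compute_gex(umi, labs, "T")
  expect_equal(unname(gex), c(0.5, 0, 1))
  # times cell count is an integer; invariant to scaling counts
  expect_true(all(gex * 4 == round(gex * 4)))
  expect_equal(compute_gex(umi * 7L, labs, "T"), gex)
  expect_error(compute_gex(umi, labs, "B"), "no cells")
})

test_that("highly variable selection ranks by dispersion with ID ties", {
  umi <- rbind(gconst = rep(5, 6), gbim = c(0, 10, 0, 10, 0, 10))
  colnames(umi) <- paste0("c", 1:6)
  labs <- setNames(rep("T", 6), colnames(umi))
  expect_equal(select_highly_variable(umi, labs, "T", 1), "gbim")
  expect_setequal(select_highly_variable(umi, labs, "T", 2),
                  c("gconst", "gbim"))
  tie <- rbind(gb = c(0, 4), ga = c(0, 4))
  colnames(tie) <- c("c1", "c2")
  labs2 <- setNames(rep("T", 2), colnames(tie))
  expect_equal(select_highly_variable(tie, labs2, "T", 1), "ga")
  expect_error(select_highly_variable(tie, labs2, "T", 3), "exceeds")
})

test_that("the fragment-to-dataset pipeline runs end to end on rendered files", {
  cfg <- synth_config(n_genes = 6L, L = 120L, n_cells = 40L, seed = 4L,
                      gex_mode = "binomial")
  gen <- synth_generate(cfg)
  dir <- tempfile()
  paths <- render_raw_formats(gen, dir)
  fr <- read_fragments(paths$fragments)
  expect_true(all(c("chrom", "start", "end", "barcode") %in% names(fr)))
  pr <- read.delim(paths$promoters)
  tracks <- build_atac_tracks(fr, pr, sigma = gen$config$track_sigma)
  expect_equal(dim(tracks$normalized), c(6L, 120L))
  expect_true(all(tracks$normalized >= 0 & tracks$normalized <= 1))
  # rendered coverage correlates with the generating raw track
  expect_gt(cor(as.vector(tracks$raw), as.vector(gen$tracks$ct1$raw)), 0.5)
  umi <- read_umi_matrix(paths$mtx, paths$features, paths$barcodes)
  annot <- read.delim(paths$annotation, header = FALSE)
  gex <- compute_gex(umi, annot, "ct1")
  expect_equal(length(gex), 6L)
  # binomial-mode GEx times cell count is integral
  expect_true(all(abs(gen$gex[, 1] * cfg$n_cells -
                      round(gen$gex[, 1] * cfg$n_cells)) < 1e-9))
})
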