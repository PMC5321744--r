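test_that("cohorts are bit-identical for the same config and seed", {
  cfg <- generatorConfig(n_genes = 120, seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a@truth@genes, b@truth@genes)
  expect_identical(occupancyMatrix(a@geneTable), occupancyMatrix(b@geneTable))
  expect_identical(geneIntervals(a@annotation), geneIntervals(b@annotation))
  expect_identical(trackValues(a@tracks$ip), trackValues(b@tracks$ip))
  # and the global RNG stream is restored afterwards
  set.seed(1); x <- stats::rnorm(1)
  set.seed(1); generateCohort(generatorConfig(n_genes = 10, seed = 5),
                              tracks = FALSE)
  expect_identical(stats::rnorm(1), x)
})

test_that("conservation D = L + R holds exactly in every genotype", {
  for (seed in 1:3) {
    g <- generateCohort(generatorConfig(n_genes = 400, seed = seed,
                                        beta = 0.7), tracks = FALSE)@truth@genes
    for (gt in c("wt", "fft3", "spt16")) {
      D <- g[[paste0("D_", gt)]]
      expect_identical(D, g[[paste0("L_", gt)]] + g[[paste0("R_", gt)]])
      expect_true(all(D >= 0 & D <= 1))
    }
  }
})

test_that("genotype effects follow the model's proportionality rules", {
  cfg <- generatorConfig(n_genes = 300, seed = 8, x_prime_true = 0.6,
                         beta = 0.5)
  g <- generateCohort(cfg, tracks = FALSE)@truth@genes
  expect_equal(g$L_fft3, (1 - 0.6) * g$L_wt)
  expect_equal(g$D_fft3, (1 - 0.6) * g$D_wt)
  expect_true(all(g$R_spt16 == 0))
  expect_equal(g$D_spt16, 0.5 * g$D_wt)
  expect_equal(mean(g$D_spt16), 0.5 * mean(g$D_wt))   # linear scaling
})

test_that("the realised median disassembly hits its target", {
  ts <- truthSummary(generateCohort(generatorConfig(n_genes = 5000,
                                                    seed = 2),
                                    tracks = FALSE)@truth)
  expect_lt(abs(ts$median_D_wt - 0.10) / 0.10, 0.01)
  expect_equal(ts$x_prime_true, 0.84)
})

test_that("truth summaries of an all-zero truth are zero", {
  z <- rep(0, 4)
  truth <- new("SyntheticTruth",
               genes = data.frame(gene_id = paste0("g", 1:4), T = 1 + z,
                                  D_wt = z, L_wt = z, R_wt = z, rho = z,
                                  D_fft3 = z, L_fft3 = z, R_fft3 = z,
                                  D_spt16 = z, L_spt16 = z, R_spt16 = z),
               xPrimeTrue = 0.5, beta = 1)
  ts <- truthSummary(truth)
  expect_true(all(unlist(ts$genotype_means) == 0))
})

test_that("noise-free observables equal their defining formulas", {
  cfg <- generatorConfig(n_genes = 200, seed = 13, sigma_obs = 0,
                         sigma_P = 0, beta = 0.8, gamma = 1.5)
  co <- generateCohort(cfg, tracks = FALSE)
  g <- co@truth@genes
  m <- occupancyMatrix(co@geneTable)
  expect_equal(unname(m[, "dH3_fft3"]), 0.84 * g$L_wt)
  expect_equal(unname(m[, "dH3_spt16"]), g$L_wt - 0.8 * g$D_wt)
  expect_equal(unname(m[, "pol_wt"]), log2(g$T))
  expect_equal(unname(m[, "dpol_fft3"]), -1.5 * 0.84 * g$D_wt)
})

test_that("reassembly heterogeneity decouples loss from disassembly", {
  g <- generateCohort(generatorConfig(n_genes = 2000, seed = 3),
                      tracks = FALSE)@truth@genes
  expect_lt(pearsonR(g$L_wt, g$D_wt)$r, 1)
  # degenerate mode: constant rho makes loss exactly proportional
  gc <- generateCohort(generatorConfig(n_genes = 2000, seed = 3,
                                       constant_rho = TRUE),
                       tracks = FALSE)@truth@genes
  expect_equal(gc$L_wt, 0.2 * gc$D_wt)
})

test_that("synthetic tracks encode transcription over gene bodies", {
  cfg <- generatorConfig(n_genes = 60, seed = 19)
  co <- generateCohort(cfg)
  # control is flat 1; IP over a gene body ~ T_g (log2 ratio ~ log2 T)
  expect_true(all(unlist(trackValues(co@tracks$control)) == 1))
  occ <- geneOccupancy(co@tracks$ip, co@tracks$control, co@annotation,
                       pseudocount = 0)
  # boundary bins mix in the intergenic baseline, so the recovered log2
  # occupancy tracks log2(T) closely but not exactly
  diffs <- occupancyColumn(occ, "occupancy") - log2(co@truth@genes$T)
  expect_lt(max(abs(diffs)), 0.1)
  expect_gt(pearsonR(occupancyColumn(occ, "occupancy"),
                     log2(co@truth@genes$T))$r, 0.999)
  # flat transcription: flat log2-ratio metagene at 0
  co1 <- generateCohort(generatorConfig(n_genes = 40, seed = 4,
                                        sigma_T = 0, sigma_D = 0))
  ratio <- coverageTrack(
    lapply(names(trackValues(co1@tracks$ip)), function(cn)
      log2(trackValues(co1@tracks$ip)[[cn]] /
             trackValues(co1@tracks$control)[[cn]])) |>
      stats::setNames(names(trackValues(co1@tracks$ip))),
    stepSize(co1@tracks$ip), trackSeqlengths(co1@tracks$ip))
  mg <- scaleRegionsMatrix(ratio, co1@annotation,
                           metageneConfig(upstream_bp = 0, downstream_bp = 0,
                                          body_bins = 10))
  expect_true(all(abs(metageneMatrix(mg)) < 1e-9))
})

test_that("invalid generator configurations name the offending field", {
  expect_error(generatorConfig(x_prime_true = 0), "x_prime_true")
  expect_error(generatorConfig(x_prime_true = 1.2), "x_prime_true")
  expect_error(generatorConfig(d_median = 0.95, d_max = 0.9), "d_median")
  expect_error(generatorConfig(sigma_obs = -1), "sigma_obs")
  expect_error(generatorConfig(n_genes = 1), "n_genes")
})

test_that("annotation written to GFF3 re-reads to identical intervals", {
  co <- generateCohort(generatorConfig(n_genes = 50, seed = 6),
                       tracks = FALSE)
  d <- withr::local_tempdir()
  writeCohort(co, d)
  back <- readGeneAnnotation(file.path(d, "genes.gff3"), "gff3")
  expect_equal(geneIntervals(back), geneIntervals(co@annotation))
  tab <- readGeneTable(file.path(d, "gene_table.tsv"))
  expect_identical(occupancyMatrix(tab), occupancyMatrix(co@geneTable))
})
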