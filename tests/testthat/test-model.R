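## Small noise-free cohorts give exact algebraic identities; seeded noisy
## cohorts exercise the estimator end to end.

test_that("reconstruction follows dH3_fft3 / x' - dH3_spt16", {
  obs <- disassemblyObservables(c(g1 = 0.4), c(g1 = -0.2), c(g1 = 1))
  expect_equal(unname(reconstructDisassembly(obs, 0.8)), 0.7)
  # x' = 1: plain elementwise difference
  obs2 <- disassemblyObservables(c(0.4, 0.1), c(-0.2, 0.3), c(1, 2))
  expect_equal(unname(reconstructDisassembly(obs2, 1)), c(0.6, -0.2))
  expect_error(reconstructDisassembly(obs, 0), "0, 1")
  expect_error(reconstructDisassembly(obs, 1.01), "0, 1")
})

test_that("noise-free reconstruction at the true x' recovers latent D_spt16", {
  cfg <- generatorConfig(n_genes = 500, seed = 10, sigma_obs = 0,
                         beta = 1.3, x_prime_true = 0.6)
  co <- generateCohort(cfg, tracks = FALSE)
  obs <- observablesFromTable(co@geneTable)
  d <- reconstructDisassembly(obs, 0.6)
  expect_equal(unname(d), co@truth@genes$D_spt16, tolerance = 1e-12)
})

test_that("the division and rescaled forms give identical correlations", {
  co <- generateCohort(generatorConfig(n_genes = 800, seed = 11),
                       tracks = FALSE)
  obs <- observablesFromTable(co@geneTable)
  grid <- seq(0.01, 1, by = 0.01)
  curve <- contributionCurve(obs, grid)
  direct <- vapply(grid, function(x)
    stats::cor(reconstructDisassembly(obs, x), obs@pol), 0)
  expect_equal(unname(curve), direct, tolerance = 1e-12)
})

test_that("curve invariances: flat when dH3_spt16 = 0, joint-scaling invariant", {
  set.seed(12)
  f <- stats::rnorm(50, 1); p <- stats::rnorm(50)
  obs0 <- disassemblyObservables(f, rep(0, 50), p)
  r0 <- contributionCurve(obs0)
  expect_lt(max(r0) - min(r0), 1e-12)

  s <- stats::rnorm(50)
  r1 <- contributionCurve(disassemblyObservables(f, s, p))
  r2 <- contributionCurve(disassemblyObservables(13 * f, 13 * s, p))
  expect_equal(unname(r1), unname(r2), tolerance = 1e-12)
  # and x-hat is invariant to positive affine maps of pol
  e1 <- estimateContribution(disassemblyObservables(f, s, p))
  e2 <- estimateContribution(disassemblyObservables(f, s, 4 * p + 2))
  expect_identical(xHat(e1), xHat(e2))
})

test_that("the coarse-grid argmax matches a dense-grid oracle", {
  for (seed in c(1, 2, 3)) {
    co <- generateCohort(generatorConfig(n_genes = 2000, seed = seed,
                                         sigma_obs = 0, sigma_P = 0),
                         tracks = FALSE)
    obs <- observablesFromTable(co@geneTable)
    est <- estimateContribution(obs)
    dense <- seq(0.001, 1, by = 0.001)
    rDense <- contributionCurve(obs, dense)
    xDense <- dense[which.max(rDense)]
    expect_lt(abs(xHat(est) - xDense), 0.01 + 1e-9)
  }
})

test_that("constant reassembly fraction with zero noise is non-identifiable", {
  cfg <- generatorConfig(n_genes = 1000, seed = 14, sigma_obs = 0,
                         sigma_P = 0, constant_rho = TRUE)
  obs <- observablesFromTable(generateCohort(cfg, tracks = FALSE)@geneTable)
  est <- estimateContribution(obs)
  expect_false(isIdentifiable(est))
  expect_lt(est@flatness, 1e-3)
  # heterogeneous rho restores identifiability
  cfg2 <- generatorConfig(n_genes = 1000, seed = 14, sigma_obs = 0,
                          sigma_P = 0)
  est2 <- estimateContribution(
    observablesFromTable(generateCohort(cfg2, tracks = FALSE)@geneTable))
  expect_true(isIdentifiable(est2))
})

test_that("missing observables are excluded once, before the grid sweep", {
  set.seed(15)
  f <- stats::rnorm(30, 1); s <- stats::rnorm(30); p <- stats::rnorm(30)
  f[c(3, 7)] <- NA; p[11] <- NA
  obs <- disassemblyObservables(f, s, p)
  expect_message(est <- estimateContribution(obs), "excluded")
  expect_equal(est@nGenesUsed, 27L)
  expect_length(est@dEstimates, 27L)
  keep <- !(seq_len(30) %in% c(3, 7, 11))
  ref <- estimateContribution(
    disassemblyObservables(f[keep], s[keep], p[keep]))
  expect_equal(unname(est@rCurve), unname(ref@rCurve))
})

test_that("disassembly levels behave as an arbitrary-scale disassembly readout", {
  cfg <- generatorConfig(n_genes = 1500, seed = 16, sigma_obs = 0,
                         sigma_P = 0)
  co <- generateCohort(cfg, tracks = FALSE)
  obs <- observablesFromTable(co@geneTable)
  est <- estimateContribution(obs)
  lev <- fun30DisassemblyLevels(est)
  expect_identical(attr(lev, "scale"), "arbitrary")
  # tracks the remodeller-attributable disassembly x' * D_wt
  expect_gt(pearsonR(lev, 0.84 * co@truth@genes$D_wt)$r, 0.99)
  # a positive multiple of the reconstruction: identical correlations
  third <- co@truth@genes$T
  expect_equal(pearsonR(2.7 * unname(lev), third)$r,
               pearsonR(unname(lev), third)$r)
  # sign pattern: levels anti-correlate with the RNAPII change observable
  co2 <- generateCohort(generatorConfig(n_genes = 1500, seed = 17),
                        tracks = FALSE)
  est2 <- estimateContribution(observablesFromTable(co2@geneTable))
  dpol <- occupancyColumn(co2@geneTable, "dpol_fft3")
  expect_lt(pearsonR(fun30DisassemblyLevels(est2), dpol)$r, 0)
})

test_that("degenerate model inputs raise informative errors", {
  expect_error(contributionCurve(
    disassemblyObservables(c(1, 2, 3), c(0, 1, 0), c(2, 2, 2))),
    "zero variance")
  expect_error(contributionCurve(
    disassemblyObservables(c(1, 1, 1), c(0, 0, 0), c(1, 2, 3))),
    "zero variance")
  expect_error(contributionCurve(
    disassemblyObservables(c(1, 2), c(0, 1), c(1, 2))), "3 complete")
  expect_error(contributionCurve(
    disassemblyObservables(c(1, 2, 3), c(0, 1, 0), c(1, 2, 3)),
    grid = c(0, 0.5)), "grid")
})

test_that("estimates serialise to JSON with the full curve", {
  co <- generateCohort(generatorConfig(n_genes = 300, seed = 18),
                       tracks = FALSE)
  est <- estimateContribution(observablesFromTable(co@geneTable))
  f <- withr::local_tempfile(fileext = ".json")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeContributionEstimate(est, f, genePath = g)
  rec <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rec$x_hat, xHat(est))
  expect_length(rec$r_curve, 100L)
  expect_equal(nrow(utils::read.delim(g)), est@nGenesUsed)
})
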