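# Model fitting: these tests use one small shared dataset so the suite
# stays fast; heavier calibration studies live in test-acceptance.R.

sim_small <- local({
  tr <- simulateYuleTree(8, seed = 101)
  spec <- codonSubstitutionSpec(kappa = 2,
                                siteClass = siteClassModel("M0", omega = 0.3))
  sim <- simulateCodonAlignment(tr, spec, 150, seed = 102)
  list(tree = tr, aln = sim$alignment)
})

test_that("site-class models discretize correctly", {
  m7 <- siteClassModel("M7", p = 0.5, q = 1.5)
  mix <- classWeightsOmegas(m7)
  expect_equal(sum(mix$weights), 1, tolerance = 1e-12)
  expect_equal(length(mix$omegas), 10L)
  # category means average to the beta mean
  expect_equal(mean(mix$omegas), 0.5 / 2, tolerance = 1e-6)
  expect_true(all(diff(mix$omegas) > 0))

  m8 <- siteClassModel("M8", p0 = 0.9, p = 0.5, q = 1.5, omegaS = 4)
  mix8 <- classWeightsOmegas(m8)
  expect_equal(sum(mix8$weights), 1, tolerance = 1e-12)
  expect_equal(mix8$omegas[11], 4)
  expect_equal(mix8$weights[11], 0.1)

  expect_error(siteClassModel("M8", p0 = 1.2), "p0")
  expect_error(siteClassModel("M2a", omega2 = 0.5), "omega2")
  expect_error(classWeightsOmegas(siteClassModel("M7", p = 1)), "requires")
})

test_that("M0 fitting recovers the data-generating parameters roughly", {
  f0 <- fitSiteModel(sim_small$aln, sim_small$tree, siteClassModel("M0"),
                     nstarts = 1)
  expect_true(f0@convergence$converged)
  expect_gt(fitParams(f0)[["omega"]], 0.15)
  expect_lt(fitParams(f0)[["omega"]], 0.5)
  expect_gt(fitParams(f0)[["kappa"]], 1)
  expect_lt(fitParams(f0)[["kappa"]], 4)

  # refitting from the returned MLE reproduces the optimum (fixed point)
  f0b <- fitSiteModel(sim_small$aln, sim_small$tree, siteClassModel("M0"),
                      nstarts = 1, start = as.list(fitParams(f0)))
  expect_equal(f0b@logLik, f0@logLik, tolerance = 1e-8)
})

test_that("nested model series obeys the log-likelihood ordering", {
  fits <- fitSiteModelSeries(sim_small$aln, sim_small$tree,
                             models = c("M0", "M3", "M7", "M8a", "M8", "M1a",
                                        "M2a"),
                             nstarts = 1)
  tol <- 1e-6
  expect_gte(fits$M3@logLik, fits$M0@logLik - tol)
  expect_gte(fits$M8@logLik, fits$M7@logLik - tol)
  expect_gte(fits$M8@logLik, fits$M8a@logLik - tol)
  expect_gte(fits$M2a@logLik, fits$M1a@logLik - tol)

  # degrees of freedom of the canonical comparisons
  expect_equal(lrtSiteModels(fits$M1a, fits$M2a)$df, 2L)
  expect_equal(lrtSiteModels(fits$M7, fits$M8)$df, 2L)
  expect_equal(lrtSiteModels(fits$M8a, fits$M8)$df, 1L)
  expect_error(lrtSiteModels(fits$M0, fits$M8), "nested")

  lr <- lrtSiteModels(fits$M7, fits$M8)
  expect_gte(lr$statistic, 0)
  expect_true(lr$pValue >= 0 && lr$pValue <= 1)
})

test_that("identical fits give a null LRT and boundary mixture halves p", {
  f <- fitSiteModel(sim_small$aln, sim_small$tree, siteClassModel("M8a"),
                    nstarts = 1)
  fake_alt <- f
  fake_alt@model@name <- "M8"
  fake_alt@npar <- f@npar + 1L
  lr <- lrtSiteModels(f, fake_alt)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$pValue, 1)
  lrb <- lrtSiteModels(f, fake_alt, boundaryMixture = TRUE)
  expect_equal(lrb$pValue, 1)  # statistic 0: all mass at the point mass
})

test_that("posterior machinery behaves at the edges", {
  # vanishing positive class: posteriors vanish with it
  toy <- new("CodonSiteFit",
             model = siteClassModel("M8", p0 = 1, p = 0.5, q = 2, omegaS = 2),
             logLik = -10, params = c(kappa = 2, treeScale = 1),
             weights = c(rep(0.1, 10), 0),
             omegas = c(paraselect:::.beta_category_means(0.5, 2, 10), 2),
             siteClassLogLik = matrix(-5, 4, 11), pi = rep(1 / 61, 61),
             npar = 6L, convergence = list(converged = TRUE), data = list())
  expect_equal(sitePosteriors(toy, "NEB"), rep(0, 4))

  expect_error(sitePosteriors(
    new("CodonSiteFit", model = siteClassModel("M7", p = 1, q = 1),
        logLik = -1, params = c(kappa = 2), weights = rep(0.1, 10),
        omegas = rep(0.5, 10), siteClassLogLik = matrix(-1, 2, 10),
        pi = rep(1 / 61, 61), npar = 4L,
        convergence = list(), data = list()), "NEB"),
    "positive-selection")

  # threshold semantics and monotonicity of the reported set
  post <- c(0.95, 0.5, 0.91, 0.89)
  expect_equal(selectedSites(post, 0.90)$site, c(1L, 3L))
  expect_equal(nrow(selectedSites(post, 1.0)), 0L)
  expect_true(all(selectedSites(post, 0.90)$site %in%
                    selectedSites(post, 0.5)$site))
})

test_that("posteriors rank truly selected sites above neutral ones", {
  tr <- simulateYuleTree(10, seed = 201)
  spec <- codonSubstitutionSpec(
    kappa = 2, siteClass = siteClassModel("M8", p0 = 0.85, p = 0.4, q = 2,
                                          omegaS = 5))
  sim <- simulateCodonAlignment(tr, spec, 300, seed = 202)
  fits <- fitSiteModelSeries(sim$alignment, tr, c("M7", "M8"), nstarts = 1)
  neb <- sitePosteriors(fits$M8, "NEB")
  beb <- sitePosteriors(fits$M8, "BEB")
  sel <- sim$siteClass == 11L
  expect_gt(median(neb[sel]), median(neb[!sel]))
  expect_gt(median(beb[sel]), median(beb[!sel]))
  expect_true(all(beb >= 0 & beb <= 1))
  expect_true(all(neb >= 0 & neb <= 1))
})
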