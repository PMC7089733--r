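# Consensus scoring, structure filtering and the pseudo-genetic engine.

test_that("filterByFitness applies percentile and chi2 cuts", {
  set.seed(13)
  scores <- data.frame(id = sprintf("s%03d", 1:500),
                       total_energy = rnorm(500),
                       restraint_energy = rnorm(500),
                       chi2_rna = runif(500, 1, 5))
  # no cuts: full pool
  all <- filterByFitness(scores, c("total_energy", "restraint_energy"),
                         100, c(chi2_rna = Inf))
  expect_equal(nrow(all), 500L)
  # top 2 % of 500 = exactly 10 per energy column before chi2 cuts
  e <- filterByFitness(scores, "total_energy", 2)
  expect_equal(nrow(e), 10L)
  expect_true(all(e$total_energy <= sort(scores$total_energy)[10]))
  # planted low-chi2 subset is recovered
  planted <- sample(500, 25)
  scores$chi2_rna[planted] <- runif(25, 0.10, 0.12)
  got <- filterByFitness(scores, character(), 100, c(chi2_rna = 1.3))
  expect_setequal(got$id, scores$id[planted])
  expect_error(filterByFitness(scores, character(), 100,
                               c(chi2_rna = 0.5)),
               "binding")
})

test_that("truth ensemble scores ~0 on noiseless data, normalized in [0,1]", {
  fx <- toyFixture()
  truthIds <- names(fx$weights)
  # exact representable mixture: 2 on + 1 off at f_on = 2/3
  w <- setNames(c(2 / 3, 1 / 3), c(fx$onIds[1], fx$offIds[1]))
  sim <- simulateDatasets(fx$allConf, w, fx$toy$schemes, seed = 5,
                          sasFrac = 0, preSigma = 0)
  lib <- buildCurveLibrary(fx$allConf, sim$sasData, fx$toy$schemes)
  r6 <- preR6Table(fx$allConf, sim$preData)
  truth <- ensemble(c(fx$onIds[1], fx$onIds[1], fx$offIds[1]))
  others <- list(truth, ensemble(fx$offIds[1:3]), ensemble(fx$onIds[1:3]))
  sc <- scoreEnsembles(others, sim$sasData, lib, sim$preData, r6)
  expect_lt(max(as.numeric(sc[1, seq_len(5)])), 1e-10)
  expect_lt(sc$preChi2[1], 1e-10)
  expect_true(all(sc$sasFitness >= 0 & sc$sasFitness <= 1))
  expect_true(all(sc$preFitness >= 0 & sc$preFitness <= 1))
  expect_equal(sc$consensus[1], min(sc$consensus))
})

test_that("the fast scorer agrees with the reference scoring path", {
  fx <- toyFixture()
  sim <- simulateDatasets(fx$allConf, fx$weights, fx$toy$schemes, seed = 3)
  lib <- buildCurveLibrary(fx$allConf, sim$sasData, fx$toy$schemes)
  r6 <- preR6Table(fx$allConf, sim$preData)
  fast <- presas:::makeRawScorer(sim$sasData, lib, sim$preData, r6,
                                 relaxationParams())
  set.seed(17)
  for (i in 1:10) {
    ids <- sample(names(fx$allConf), sample(3:8, 1), replace = TRUE)
    e <- ensemble(ids)
    v <- fast(ids)
    for (k in seq_along(sim$sasData))
      expect_equal(unname(v[k]),
                   chi2Fit(sim$sasData[[k]], ensembleCurve(e, lib[[k]]))$chi2,
                   tolerance = 1e-12)
    expect_equal(unname(v[6]),
                 preChi2(predictRatios(e, r6, sim$preData), sim$preData),
                 tolerance = 1e-12)
  }
})

test_that("selection is deterministic for a fixed seed", {
  fx <- toyFixture()
  sim <- simulateDatasets(fx$allConf, fx$weights, fx$toy$schemes, seed = 3)
  cfg <- scoringConfig(nIterations = 10L, nRuns = 2L, seed = 77L)
  args <- list(list(on = fx$toy$onPool, off = fx$toy$offPool),
               sim$sasData, schemes = fx$toy$schemes,
               preData = sim$preData, cfg = cfg,
               curveLib = buildCurveLibrary(fx$allConf, sim$sasData,
                                            fx$toy$schemes))
  r1 <- do.call(runSelection, args)
  r2 <- do.call(runSelection, args)
  expect_identical(r1$runs[[1]]$keys, r2$runs[[1]]$keys)
  expect_identical(r1$runs[[1]]$raw, r2$runs[[1]]$raw)
  expect_identical(memberIds(r1$best), memberIds(r2$best))
  # independent runs differ (different derived seeds)
  expect_false(identical(r1$runs[[1]]$keys, r1$runs[[2]]$keys))
})

test_that("best-so-far consensus is non-increasing across iterations", {
  fx <- toyFixture()
  sim <- simulateDatasets(fx$allConf, fx$weights, fx$toy$schemes, seed = 4)
  cfg <- scoringConfig(nIterations = 40L, nRuns = 1L, seed = 31L)
  res <- runSelection(list(on = fx$toy$onPool, off = fx$toy$offPool),
                      sim$sasData, schemes = fx$toy$schemes,
                      preData = sim$preData, cfg = cfg,
                      curveLib = buildCurveLibrary(fx$allConf, sim$sasData,
                                                   fx$toy$schemes),
                      r6table = fx$r6)
  tr <- res$runs[[1]]$trajectory
  expect_true(all(diff(tr[!is.na(tr)]) <= 1e-12))
})

test_that("population estimates aggregate top ensembles correctly", {
  tags <- c(a = "on_off", b = "on_off", c = "off_off")
  e <- ensemble(c("a", "b", "c"))
  pe <- estimatePopulation(list(list(e, e, e), list(e, e, e),
                                list(e, e, e)), tags)
  expect_equal(pe$fOn, 2 / 3, tolerance = 1e-12)
  expect_equal(pe$sd, 0)
  mk <- function(nOn) ensemble(c(rep("a", nOn), rep("c", 50 - nOn)))
  pe2 <- estimatePopulation(list(list(mk(29), mk(33), mk(37))), tags)
  expect_equal(pe2$fOn, 0.66, tolerance = 1e-9)
  expect_error(estimatePopulation(list(list(ensemble("zz"))), tags),
               "untagged")
})

test_that("tag refinement improves PRE fit and leaves structures alone", {
  fx <- toyFixture()
  sim <- simulateDatasets(fx$allConf, fx$weights, fx$toy$schemes, seed = 6)
  sel <- ensemble(c(fx$onIds[1], fx$onIds[2], fx$offIds[1]))
  truthA <- unname(tagSites(fx$toy$template)$tagA[1, ])
  set.seed(23)
  cand <- rbind(truthA,
                matrix(rep(truthA, each = 40), 40, 3) +
                  matrix(rnorm(120, 0, 10), 40, 3))
  rowsA <- sim$preData[sim$preData$tag_id == "tagA", ]
  cfg <- scoringConfig(nIterations = 30L, parentSizeRange = c(1L, 5L),
                       childSizeRange = c(1L, 5L), seed = 3L)
  before <- lapply(fx$allConf[unique(memberIds(sel))], coords)
  rt <- refineTags(sel, fx$allConf, list(tagA = cand), rowsA, cfg = cfg)
  expect_lt(rt$tagA$chi2, rt$tagA$initialChi2)
  # structure coordinates untouched
  after <- lapply(fx$allConf[unique(memberIds(sel))], coords)
  expect_identical(before, after)
  # SAS chi2 cannot change: tags do not enter the scattering model
  lib <- buildCurveLibrary(fx$allConf[unique(memberIds(sel))],
                           sim$sasData, fx$toy$schemes)
  sas1 <- chi2Fit(sim$sasData[[1]], ensembleCurve(sel, lib[[1]]))$chi2
  expect_identical(sas1,
                   chi2Fit(sim$sasData[[1]],
                           ensembleCurve(sel, lib[[1]]))$chi2)
  # single-conformation pool: output equals input
  one <- refineTags(sel, fx$allConf, list(tagA = cand[1, , drop = FALSE]),
                    rowsA, cfg = cfg)
  expect_equal(nrow(one$tagA$ensemble@positions), 1L)
  expect_equal(one$tagA$chi2, one$tagA$initialChi2)
})
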