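# PRE forward/inverse models, tauC calibration and back-calculation.

p800 <- relaxationParams(tauC = 50e-9, tauCErr = 0, omega = 2 * pi * 800e6)

test_that("intensity-ratio model matches direct evaluation", {
  expect_equal(ratioFromGamma2(0, 50, 60, p800), 1.0)
  expect_lt(ratioFromGamma2(5000, 50, 60, p800), 1e-8)
  # direct evaluation oracle: exp(-30 * 0.0076) * 3000 / (80 * 90)
  expect_equal(ratioFromGamma2(30, 50, 60, p800),
               exp(-30 * 7.6e-3) * (50 * 60) / (80 * 90), tolerance = 1e-12)
  expect_equal(round(ratioFromGamma2(30, 50, 60, p800), 3), 0.332)
})

test_that("ratio is strictly decreasing in the PRE rate", {
  set.seed(8)
  for (i in 1:20) {
    rh <- runif(1, 20, 80)
    rhc <- runif(1, 20, 90)
    g <- sort(runif(8, 0, 400))
    r <- ratioFromGamma2(g, rh, rhc, p800)
    expect_true(all(diff(r) < 0))
  }
})

test_that("rate inversion recovers the forward model", {
  expect_equal(gamma2FromRatio(1, 50, 60, p800)$value, 0)
  g <- gamma2FromRatio(0.332, 50, 60, p800)
  expect_equal(g$value, 30, tolerance = 1e-3)
  expect_error(gamma2FromRatio(0, 50, 60, p800), "> 0")
  # noise ratio above 1: rate 0 with an error-model upper bound
  gHigh <- gamma2FromRatio(1.1, 50, 60, p800, ratioErr = 0.05)
  expect_equal(gHigh$value, 0)
  expect_gte(gHigh$upper, 0)
  # bounds bracket the value and widen with the error inputs
  gb <- gamma2FromRatio(0.4, 50, 60, p800, ratioErr = 0.08,
                        r2DiaHErr = 3, r2DiaHCErr = 3)
  expect_lte(gb$lower, gb$value)
  expect_gte(gb$upper, gb$value)
  expect_gt(gb$upper - gb$lower, 0)
})

test_that("distance equation matches cgs evaluation and scaling law", {
  # (K / Gamma2 * J)^(1/6) evaluated independently in cgs
  J <- 4 * 50e-9 + 3 * 50e-9 / (1 + (2 * pi * 800e6)^2 * (50e-9)^2)
  rExp <- (1.23e-32 / 100 * J)^(1 / 6) * 1e8
  expect_equal(distanceFromGamma2(100, p800), rExp, tolerance = 1e-12)
  expect_equal(round(distanceFromGamma2(100, p800), 1), 17.1)
  # halving Gamma2 grows r by 2^(1/6)
  expect_equal(distanceFromGamma2(50, p800) / distanceFromGamma2(100, p800),
               2^(1 / 6), tolerance = 1e-12)
  expect_equal(gamma2FromDistance(rExp, p800), 100, tolerance = 1e-10)
  expect_error(gamma2FromDistance(0, p800), "> 0")
})

test_that("full inversion chain closes on random valid inputs", {
  set.seed(42)
  n <- 1000
  rh <- runif(n, 20, 80)
  rhc <- runif(n, 25, 90)
  g0 <- runif(n, 0.5, 300)
  for (i in seq_len(n)) {
    ratio <- ratioFromGamma2(g0[i], rh[i], rhc[i], p800)
    g1 <- gamma2FromRatio(ratio, rh[i], rhc[i], p800)$value
    r <- distanceFromGamma2(g1, p800)
    g2 <- gamma2FromDistance(r, p800)
    ratio2 <- ratioFromGamma2(g2, rh[i], rhc[i], p800)
    expect_equal(ratio2, ratio, tolerance = 1e-5)
    expect_equal(g1, g0[i], tolerance = 1e-5)
  }
})

test_that("tauC calibration recovers the generating correlation time", {
  pTrue <- relaxationParams(tauC = 51.8e-9, tauCErr = 0)
  set.seed(9)
  r <- runif(12, 14, 24)
  g <- gamma2FromDistance(r, pTrue)
  known <- data.frame(distance = r,
                      ratio = ratioFromGamma2(g, 50, 60, pTrue),
                      r2_dia_h = 50, r2_dia_hc = 60)
  fit <- calibrateTauC(known, relaxationParams(tauC = 20e-9), seed = 2)
  expect_equal(fit$tauC, 51.8e-9, tolerance = 1e-3)
  # equal distances with consistent rates: exact regardless of weights
  knownEq <- data.frame(distance = rep(18, 4),
                        ratio = ratioFromGamma2(
                          gamma2FromDistance(18, pTrue), 50, 60, pTrue),
                        r2_dia_h = 50, r2_dia_hc = 60)
  fitEq <- calibrateTauC(knownEq, relaxationParams(tauC = 20e-9), seed = 2)
  expect_equal(fitEq$tauC, 51.8e-9, tolerance = 1e-3)
  expect_error(calibrateTauC(known[1:2, ]), "at least 3")
})

test_that("noisy calibration spreads cover the truth", {
  pTrue <- relaxationParams(tauC = 51.8e-9, tauCErr = 0)
  covered <- 0
  nRep <- 10
  for (rep in seq_len(nRep)) {
    set.seed(300 + rep)
    r <- runif(10, 14, 24)
    g <- gamma2FromDistance(r, pTrue)
    ratio <- ratioFromGamma2(g, 50, 60, pTrue) * (1 + rnorm(10, 0, 0.05))
    known <- data.frame(distance = r, ratio = pmin(ratio, 0.999),
                        r2_dia_h = 50, r2_dia_hc = 60)
    fit <- calibrateTauC(known, relaxationParams(tauC = 20e-9),
                         nFits = 20, seed = rep)
    expect_gt(fit$sd, 0)
    if (abs(fit$tauC - 51.8e-9) <= 2.5 * fit$sd) covered <- covered + 1
  }
  expect_gte(covered, 9)
})

test_that("back-calculation reduces to the scalar chain for one conformer", {
  x <- miniConformer()
  meas <- data.frame(methyl_id = c("m1", "m2"), tag_id = "t1",
                     ratio = NA, ratio_err = 0.05,
                     r2_dia_h = 50, r2_dia_hc = 60)
  e1 <- ensemble("c1")
  out <- backcalcPre(e1, list(c1 = x), meas, p800)
  r1 <- sqrt(sum((c(30, 0, 0))^2))
  expect_equal(out$predicted[1],
               ratioFromGamma2(gamma2FromDistance(r1, p800), 50, 60, p800),
               tolerance = 1e-12)
  # ensemble of identical members equals the single member
  e3 <- ensemble(c("c1", "c1", "c1"))
  out3 <- backcalcPre(e3, list(c1 = x), meas, p800)
  expect_equal(out3$predicted, out$predicted, tolerance = 1e-12)
})

test_that("two tags at equal distance double the PRE rate", {
  coords <- rbind(c(0, 0, 0), c(20, 0, 0))
  x1 <- conformer(coords, "A",
                  methylSites = matrix(c(20, 0, 0), 1, 3,
                                       dimnames = list("m", NULL)),
                  tagSites = list(tl = matrix(c(0, 0, 0), 1, 3)))
  x2 <- conformer(coords, "A",
                  methylSites = matrix(c(20, 0, 0), 1, 3,
                                       dimnames = list("m", NULL)),
                  tagSites = list(tl = matrix(c(0, 0, 0), 1, 3),
                                  tr = matrix(c(40, 0, 0), 1, 3)))
  meas <- data.frame(methyl_id = "m", tag_id = "ds", ratio = NA,
                     ratio_err = 0.05, r2_dia_h = 50, r2_dia_hc = 60)
  g1 <- gamma2FromDistance(20, p800)
  out1 <- backcalcPre(ensemble("a"), list(a = x1), meas, p800,
                      tagMap = list(ds = "tl"))
  out2 <- backcalcPre(ensemble("a"), list(a = x2), meas, p800,
                      tagMap = list(ds = c("tl", "tr")))
  expect_equal(out1$predicted, ratioFromGamma2(g1, 50, 60, p800))
  expect_equal(out2$predicted, ratioFromGamma2(2 * g1, 50, 60, p800),
               tolerance = 1e-12)
})

test_that("two-copy ratios are averaged after the ratio model", {
  coords <- rbind(c(0, 0, 0), c(15, 0, 0), c(30, 0, 0))
  x <- conformer(coords, "A",
                 methylSites = matrix(c(15, 0, 0, 30, 0, 0), 2, 3,
                                      byrow = TRUE,
                                      dimnames = list(c("mA", "mB"), NULL)),
                 tagSites = list(t = matrix(c(0, 0, 0), 1, 3)))
  meas <- data.frame(methyl_id = "peak", tag_id = "t", ratio = NA,
                     ratio_err = 0.05, r2_dia_h = 50, r2_dia_hc = 60)
  out <- backcalcPre(ensemble("a"), list(a = x), meas, p800,
                     copyMap = list(peak = list("mA", "mB")))
  rA <- ratioFromGamma2(gamma2FromDistance(15, p800), 50, 60, p800)
  rB <- ratioFromGamma2(gamma2FromDistance(30, p800), 50, 60, p800)
  expect_equal(out$predicted, (rA + rB) / 2, tolerance = 1e-12)
  # OR-grouped sites within one copy sum r^-6 instead
  outOR <- backcalcPre(ensemble("a"), list(a = x), meas, p800,
                       copyMap = list(peak = list(c("mA", "mB"))))
  gOR <- gamma2FromDistance(15, p800) + gamma2FromDistance(30, p800)
  expect_equal(outOR$predicted, ratioFromGamma2(gOR, 50, 60, p800),
               tolerance = 1e-12)
})

test_that("predicted ratios are physical and distant tags are negligible", {
  fx <- toyFixture()
  e <- ensemble(c(fx$onIds[1], fx$offIds[1]))
  meas <- fx$sim0$preData
  out <- backcalcPre(e, fx$allConf, meas)
  expect_true(all(out$predicted > 0 & out$predicted <= 1))
  # add a remote tag (> 60 A from every methyl): ratios shift < 1 %
  confFar <- lapply(fx$allConf[unique(memberIds(e))], function(cf) {
    ts <- tagSites(cf)
    ts$far <- matrix(c(500, 500, 500), 1, 3)
    conformer(coords(cf), subunitIds(cf), stateTag = stateTag(cf),
              methylSites = methylSites(cf), tagSites = ts)
  })
  tm <- list(tagA = c("tagA", "far"), tagB = "tagB", tagC = "tagC")
  outFar <- backcalcPre(e, confFar, meas, tagMap = tm)
  expect_true(all(abs(outFar$predicted - out$predicted) /
                    out$predicted < 0.01))
})

test_that("PRE chi2 and Q-factor grade agreement consistently", {
  obs <- data.frame(ratio = c(0.3, 0.6, 0.9), ratio_err = c(0.1, 0.1, 0.1))
  expect_equal(preChi2(c(0.3, 0.6, 0.9), obs), 0)
  expect_equal(preChi2(c(0.4, 0.6, 0.9), obs), 1 / 3)
  pred <- c(0.35, 0.5, 0.8)
  expect_equal(preChi2(pred, obs),
               mean(((obs$ratio - pred) / obs$ratio_err)^2))
  expect_error(preChi2(pred, transform(obs, ratio_err = 0)), "zero")
  # Q-factor ordering agrees with chi2 ordering for uniform errors
  predGood <- c(0.31, 0.59, 0.91)
  expect_lt(preChi2(predGood, obs), preChi2(pred, obs))
  expect_lt(preQFactor(predGood, obs), preQFactor(pred, obs))
})
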