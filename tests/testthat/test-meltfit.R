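test_that("noiseless curve fits recover the generating parameters to 0.1%", {
  for (dHdS in list(c(-77.6, -217.1), c(-104.9, -291.6), c(-71.2, -197.4))) {
    p <- twoStateParams(dHdS[1], dHdS[2])
    cv <- simulateCurve(p, 1e-4)
    f <- fitCurve(cv)
    expect_lt(abs(f@params@dH - dHdS[1]) / abs(dHdS[1]), 1e-3)
    expect_lt(abs(f@params@dS - dHdS[2]) / abs(dHdS[2]), 1e-3)
  }
})

test_that("noisy curve fits recover the enthalpy within 5%", {
  set.seed(21)
  cv <- simulateCurve(corePlot, 1e-4)
  amp <- diff(range(cv@absorbance))
  cv@absorbance <- cv@absorbance + rnorm(length(cv@absorbance), 0, 0.002 * amp)
  f <- fitCurve(cv)
  expect_lt(abs(f@params@dH + 77.6) / 77.6, 0.05)
})

test_that("degenerate curves raise 'no transition detected'", {
  flat <- meltCurve(0:90, rep(1, 91), 1e-4)
  expect_error(fitCurve(flat), "no transition detected")
  line <- meltCurve(0:90, 0.9 + 0.001 * (0:90), 1e-4)
  expect_error(fitCurve(line), "no transition detected")
})

test_that("the Tm-plot fit is exact on noiseless model-generated points", {
  cts <- 10^seq(-6, -3, length.out = 9)
  pts <- data.frame(ct = cts, tm = vapply(cts, function(ct)
    meltingTemperature(corePlot, ct, celsius = FALSE), 0))
  f <- fitTmPlot(pts)
  expect_equal(f@params@dH, -77.6, tolerance = 1e-9)
  expect_equal(f@params@dS, -217.1, tolerance = 1e-9)
  expect_equal(round(f@tm, 1), 52.7)
  ## dG37 from the fit equals dH - 310.15*dS by construction
  expect_equal(f@dG37@value, f@params@dH - 310.15 * f@params@dS / 1000)
  expect_error(fitTmPlot(pts[1:2, ]), "at least 3")
})

test_that("noisy Tm-plot points are recovered within the regression sd", {
  set.seed(22)
  cts <- 10^seq(-6, -3, length.out = 9)
  ok <- 0
  for (r in 1:10) {
    tms <- vapply(cts, function(ct)
      meltingTemperature(corePlot, ct, celsius = FALSE), 0)
    pts <- data.frame(ct = cts, tm = tms + rnorm(9, 0, 0.08))
    f <- fitTmPlot(pts)
    if (abs(f@params@dH + 77.6) <= 2.5 * f@dHsd) ok <- ok + 1
  }
  expect_gte(ok, 9)  # ~2.5 sigma coverage
})

test_that("two-state consistency reproduces the tabulated comparisons", {
  ## first table row: within the 15% criterion
  r <- twoStateConsistency(-78.5, -71.7)
  expect_equal(round(100 * r$relDiff, 1), 9.1)
  expect_true(r$twoState)
  ## equal inputs
  r <- twoStateConsistency(-80, -80)
  expect_equal(r$relDiff, 0)
  ## the two-transition melt fails the criterion
  r <- twoStateConsistency(-105.9, -76.8)
  expect_equal(round(100 * r$relDiff, 1), 31.9)
  expect_false(r$twoState)
  expect_error(twoStateConsistency(-80, 80), "sign")
})

test_that("dataset fitting ties the two routes together", {
  ds <- generateDataset(twoStateParams(-80, -220), seed = 5)
  res <- fitMeltingDataset(ds)
  expect_s4_class(res$tmPlot, "FitResult")
  expect_equal(res$tmPlot@method, "tm_plot")
  expect_equal(res$curveAverage@method, "curve_average")
  expect_true(res$consistency$twoState)
  expect_lt(abs(res$tmPlot@params@dH + 80) / 80, 0.05)
  ## each curve's recorded Tm is the alpha = 1/2 point of its own fit
  f1 <- res$curveFits[[1]]
  expect_equal(f1@diagnostics$tmCurve,
               meltingTemperature(f1@params, ds[[1]]@ct))
})
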