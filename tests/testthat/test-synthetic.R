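test_that("generated datasets have the designed structure and determinism", {
  p <- twoStateParams(-80, -220)
  ds <- generateDataset(p, seed = 3)
  expect_equal(length(ds), 9L)
  cts <- vapply(ds@curves, function(c) c@ct, 0)
  expect_equal(cts[1], 1e-6); expect_equal(cts[9], 1e-3)
  ## log-spaced
  expect_equal(diff(log(cts)), rep(log(1e3) / 8, 8), tolerance = 1e-12)
  ## identical seed, identical data
  ds2 <- generateDataset(p, seed = 3)
  expect_identical(lapply(ds@curves, function(c) c@absorbance),
                   lapply(ds2@curves, function(c) c@absorbance))
  ## different seed, different noise
  ds3 <- generateDataset(p, seed = 4)
  expect_false(identical(ds[[1]]@absorbance, ds3[[1]]@absorbance))
  ## noiseless on request
  ds0 <- generateDataset(p, noiseSD = 0, seed = 3)
  expect_equal(ds0[[5]]@absorbance,
               simulateCurve(p, cts[5])@absorbance)
})

test_that("doubling the noise inflates the scatter of fitted enthalpies", {
  p <- twoStateParams(-80, -220)
  fitOne <- function(noise, seed) {
    ds <- generateDataset(p, nConcentrations = 3, ctRange = c(1e-5, 1e-3),
                          noiseSD = noise, seed = seed)
    fitCurve(ds[[2]])@params@dH
  }
  lo <- vapply(1:25, function(s) fitOne(0.0004, s), 0)
  hi <- vapply(1:25, function(s) fitOne(0.0008, 100 + s), 0)
  expect_gt(sd(hi), sd(lo))
})

test_that("the reference compilation holds 20 test duplexes plus 2 cores", {
  fx <- tableFixtures()
  expect_equal(sum(fx$variant == "psi"), 20L)
  expect_equal(sum(fx$variant == "core"), 2L)
  expect_equal(length(unique(fx$group)), 22L)
  ## the core-1 row carries the canonical plot-route numbers
  c1 <- fx[fx$group == "core1", ]
  expect_equal(c1$top, "CAGUCAGU")
  expect_equal(c(c1$tp_dH, c1$tp_dS, c1$tp_dG37, c1$tp_tm),
               c(-77.6, -217.1, -10.26, 52.7))
  ## exactly one entry is flagged non-two-state (central U-G analog)
  expect_equal(sum(!fx$two_state), 1L)
  expect_equal(fx$variant[!fx$two_state], "u")
  expect_equal(fx$group[!fx$two_state], "g11")
})

test_that("every fixture is internally consistent: dG37 = dH - 310.15 dS", {
  fx <- tableFixtures()
  for (m in c("cf", "tp")) {
    dg <- fx[[paste0(m, "_dH")]] - 310.15 * fx[[paste0(m, "_dS")]] / 1000
    expect_lt(max(abs(dg - fx[[paste0(m, "_dG37")]])), 0.1)
    ## and the printed Tm is reproduced from the printed dH/dS
    for (i in seq_len(nrow(fx))) {
      tm <- meltingTemperature(
        twoStateParams(fx[[paste0(m, "_dH")]][i], fx[[paste0(m, "_dS")]][i]))
      expect_lt(abs(tm - fx[[paste0(m, "_tm")]][i]), 0.5)
    }
  }
})

test_that("parameter recovery holds across representative fixture conditions", {
  fx <- tableFixtures()
  picks <- c("core1", "g05", "g06", "g13", "g14")
  for (g in picks) {
    row <- fx[fx$group == g & fx$variant %in% c("psi", "core"), ]
    p <- twoStateParams(row$tp_dH, row$tp_dS)
    ds <- generateDataset(p, noiseSD = 0.002, seed = 1)
    res <- fitMeltingDataset(ds)
    expect_lt(abs(res$tmPlot@params@dH - row$tp_dH) / abs(row$tp_dH), 0.10)
    expect_lt(abs(res$tmPlot@dG37@value - row$tp_dG37), 0.2)
    ## the two estimation routes agree within the 15% two-state bound
    expect_true(res$consistency$twoState)
  }
})
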