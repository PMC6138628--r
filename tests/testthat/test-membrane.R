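test_that("laurdanGP matches its closed form on boundary and symmetry cases", {
  expect_equal(laurdanGP(100, 100), 0)
  expect_equal(laurdanGP(100, 0), 1)
  expect_equal(laurdanGP(0, 100), -1)
  expect_equal(laurdanGP(150, 50), 0.5)
  expect_error(laurdanGP(0, 0), "degenerate")
  expect_error(laurdanGP(-1, 10), ">= 0")
})

test_that("GP is antisymmetric under swapping the band intensities", {
  set.seed(21)
  for (rep in 1:25) {
    a <- runif(1, 1, 500); b <- runif(1, 1, 500)
    expect_equal(laurdanGP(a, b), -laurdanGP(b, a), tolerance = 1e-12)
  }
})

test_that("gpFromSpectrum reads the bands off a two-Gaussian spectrum", {
  wl <- seq(400, 550, by = 1)
  band <- function(c0, a) a * exp(-(wl - c0)^2 / (2 * 18^2))
  # equal amplitudes, symmetric overlap -> GP 0
  s <- Spectrum(wl, band(440, 100) + band(490, 100))
  expect_equal(gp(gpFromSpectrum(s)), 0, tolerance = 1e-9)
  # pure 440 band: GP -> 1 up to the analytic Gaussian tail at 490
  s1 <- Spectrum(wl, band(440, 100))
  tail <- exp(-(490 - 440)^2 / (2 * 18^2))
  expect_equal(gp(gpFromSpectrum(s1)), (1 - tail) / (1 + tail),
               tolerance = 1e-9)
  # out-of-range spectrum
  expect_error(gpFromSpectrum(Spectrum(seq(450, 550, 1), seq(450, 550, 1))),
               "cover")
})

test_that("generated Laurdan spectra invert back to the target GP", {
  g <- genLaurdanSpectrum(0.15, seed = 3)
  expect_equal(gp(gpFromSpectrum(g$spectrum)), 0.15, tolerance = 0.01)
  g2 <- genLaurdanSpectrum(0, seed = 3)
  expect_equal(gp(gpFromSpectrum(g2$spectrum)), 0, tolerance = 1e-9)
  expect_error(genLaurdanSpectrum(0.99), "infeasible")
})

test_that("mixingPercent normalizes between the residual and Triton levels", {
  expect_equal(mixingPercent(10, 10, 110), 0)
  expect_equal(mixingPercent(110, 10, 110), 100)
  expect_equal(mixingPercent(35, 10, 110), 25)
  expect_error(mixingPercent(50, 10, 10), "degenerate")
  over <- mixingPercent(150, 10, 110)
  expect_gt(as.numeric(over), 100)          # not clamped
  expect_true(attr(over, "outOfRange"))     # but flagged
})

test_that("mixingPercent is invariant to affine rescaling of the signal", {
  set.seed(31)
  for (rep in 1:25) {
    f <- runif(1, 20, 90); a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(mixingPercent(a * f + b, a * 10 + b, a * 110 + b),
                 mixingPercent(f, 10, 110), tolerance = 1e-9)
  }
})

test_that("mixing curves recover the generator's saturation point", {
  grid <- c(0.002, 0.005, 0.01, 0.02, 0.03, 0.05, 0.07, 0.1)
  g <- genMixingSeries(0.05, 100, plGrid = grid, seed = 5)
  mc <- mixingCurve(g$series, 10, 110, assay = "total")
  fit <- fitSaturation(mc)
  expect_equal(fit$plateau, 100, tolerance = 0.5)
  # curve reaches 100 +- 0.5% of plateau... the saturation P/L itself:
  expect_equal(fit$saturationPL, 0.05, tolerance = 0.05 * 0.2)

  # constant series at f0 -> all zeros, reported flat
  flat <- TitrationSeries(grid, rep(10, length(grid)),
                          "peptide_lipid_ratio")
  mc0 <- mixingCurve(flat, 10, 110, assay = "leakage")
  expect_true(all(mixingPercents(mc0) == 0))
  expect_equal(fitSaturation(mc0)$plateau, 0)
})

test_that("a leakage-free generator yields near-zero leakage percentages", {
  g <- genMixingSeries(0.05, 0, plGrid = c(0.01, 0.03, 0.05, 0.1),
                       noiseType = "multiplicative", noiseSd = 0.02,
                       seed = 8)
  lk <- mixingCurve(g$series, 10, 110, assay = "leakage")
  expect_lt(max(abs(mixingPercents(lk))), 3 * 2 * 0.02 * 10)
})

test_that("recovered mixing extent is exact at zero noise and within 2
           points MAE at 2% noise", {
  grid <- c(0.002, 0.005, 0.01, 0.02, 0.03, 0.05, 0.07, 0.1)
  g0 <- genMixingSeries(0.05, 100, plGrid = grid, seed = 1)
  expect_equal(fitSaturation(mixingCurve(g0$series, 10, 110))$plateau, 100,
               tolerance = 1e-6)
  errs <- vapply(1:200, function(i) {
    g <- genMixingSeries(0.05, 100, plGrid = grid,
                         noiseType = "multiplicative", noiseSd = 0.02,
                         seed = i)
    abs(fitSaturation(mixingCurve(g$series, 10, 110))$plateau - 100)
  }, numeric(1))
  expect_lt(mean(errs), 2)
})

test_that("BBB saturates earlier and fuses its inner monolayer less than
           liver", {
  bbb <- conditionPreset("BBB"); liv <- conditionPreset("liver")
  recover <- function(pre, plateau, seed) {
    g <- genMixingSeries(pre$saturationPL, plateau, plGrid = pre$plGrid,
                         noiseType = "multiplicative", noiseSd = 0.02,
                         seed = seed)
    fitSaturation(mixingCurve(g$series, 10, 110))
  }
  sb <- recover(bbb, bbb$totalPlateau, 42)
  sl <- recover(liv, liv$totalPlateau, 43)
  expect_lt(sb$saturationPL, sl$saturationPL)
  ib <- recover(bbb, bbb$innerPlateau, 44)
  il <- recover(liv, liv$innerPlateau, 45)
  expect_lt(ib$plateau, il$plateau)
})
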