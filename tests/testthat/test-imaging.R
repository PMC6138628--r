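test_that("thresholdNonzero separates signal from background", {
  # all-zero image: empty mask with a warning, not an error
  img0 <- VesselImage(matrix(0, 8, 8), matrix(FALSE, 8, 8))
  expect_warning(m0 <- thresholdNonzero(img0), "contrast|empty")
  expect_false(any(m0))

  # binary image: positive method keeps exactly the 100-valued pixels
  px <- matrix(0, 10, 10); px[3:5, 3:5] <- 100
  img <- VesselImage(px, matrix(FALSE, 10, 10))
  expect_identical(thresholdNonzero(img, "positive"), px == 100)

  # bimodal image: otsu recalls essentially all true signal pixels
  set.seed(61)
  sig <- matrix(FALSE, 64, 64); sig[20:40, 10:50] <- TRUE
  px2 <- matrix(abs(rnorm(64 * 64, 5, 1)), 64, 64)
  px2[sig] <- rnorm(sum(sig), 100, 5)
  img2 <- VesselImage(px2, matrix(FALSE, 64, 64))
  m2 <- thresholdNonzero(img2, "otsu")
  expect_gte(sum(m2 & sig) / sum(sig), 0.99)
})

test_that("integratedDensity is mean fluorescence times ROI area", {
  px <- matrix(10, 20, 20)
  img <- VesselImage(px, matrix(FALSE, 20, 20), pixelAreaUm2 = 1)
  roi <- matrix(FALSE, 20, 20); roi[1:10, 1:10] <- TRUE
  id <- integratedDensity(img, roi)
  expect_equal(id@meanFluorescence, 10)
  expect_equal(id@areaUm2, 100)
  expect_equal(idValue(id), 1000)

  # single pixel
  roi1 <- matrix(FALSE, 20, 20); roi1[5, 5] <- TRUE
  img2 <- VesselImage(px, matrix(FALSE, 20, 20), pixelAreaUm2 = 0.76)
  expect_equal(idValue(integratedDensity(img2, roi1)), 10 * 0.76)

  # checkerboard 0/20 over 200 pixels -> mean 10, ID 2000
  cb <- matrix(rep(c(0, 20), 200), 20, 20)
  imgc <- VesselImage(cb, matrix(FALSE, 20, 20), pixelAreaUm2 = 1)
  roic <- matrix(FALSE, 20, 20); roic[, 1:10] <- TRUE
  idc <- integratedDensity(imgc, roic)
  expect_equal(idc@meanFluorescence, 10)
  expect_equal(idValue(idc), 2000)

  expect_error(integratedDensity(img, matrix(FALSE, 20, 20)), "degenerate")
})

test_that("integrated density is additive over disjoint ROIs and scales
           linearly", {
  set.seed(62)
  px <- matrix(runif(400, 0, 50), 20, 20)
  img <- VesselImage(px, matrix(FALSE, 20, 20), pixelAreaUm2 = 0.76)
  a <- matrix(FALSE, 20, 20); a[1:20, 1:7] <- TRUE
  b <- matrix(FALSE, 20, 20); b[1:20, 8:20] <- TRUE
  expect_equal(idValue(integratedDensity(img, a)) +
               idValue(integratedDensity(img, b)),
               idValue(integratedDensity(img, a | b)),
               tolerance = 1e-9)
  # linear in intensity and in pixel area
  img2 <- VesselImage(3 * px, matrix(FALSE, 20, 20), pixelAreaUm2 = 0.76)
  expect_equal(idValue(integratedDensity(img2, a)),
               3 * idValue(integratedDensity(img, a)), tolerance = 1e-9)
  img3 <- VesselImage(px, matrix(FALSE, 20, 20), pixelAreaUm2 = 1.52)
  expect_equal(idValue(integratedDensity(img3, a)),
               2 * idValue(integratedDensity(img, a)), tolerance = 1e-9)
})

test_that("insideOutsideSplit separates vessel and parenchymal signal", {
  # signal confined to vessels -> outside ID 0
  g <- genBrainImage(insideAmount = 70, outsideAmount = 0, seed = 11)
  sp <- insideOutsideSplit(g$image)
  expect_equal(idValue(sp$outside), 0)
  expect_equal(idValue(sp$inside), 50 * 70, tolerance = 1e-6)

  # 70:30 generator truth recovered
  g2 <- genBrainImage(insideAmount = 70, outsideAmount = 30, seed = 12)
  sp2 <- insideOutsideSplit(g2$image)
  tot <- idValue(sp2$inside) + idValue(sp2$outside)
  expect_equal(100 * idValue(sp2$inside) / tot, 70, tolerance = 2)

  # degenerate masks
  px <- matrix(1, 8, 8)
  expect_error(insideOutsideSplit(VesselImage(px, matrix(FALSE, 8, 8))),
               "empty")
  expect_error(insideOutsideSplit(VesselImage(px, matrix(TRUE, 8, 8))),
               "whole frame")
})

test_that("fitCalibration recovers line and 4PL parameters", {
  am <- seq(0, 30, by = 5)
  lin <- fitCalibration(am, 50 * am, "linear")
  expect_equal(lin@slope, 50, tolerance = 1e-9)
  expect_equal(lin@intercept, 0, tolerance = 1e-6)
  expect_equal(lin@r2, 1, tolerance = 1e-9)

  flat <- fitCalibration(am, rep(7, 7), "linear")
  expect_equal(flat@slope, 0, tolerance = 1e-12)

  # noiseless 4PL round trip
  pr <- c(a = 5, b = 2.2, c = 12, d = 900)
  x <- seq(0.5, 40, length.out = 12)
  y <- pr["d"] + (pr["a"] - pr["d"]) / (1 + (x / pr["c"])^pr["b"])
  rod <- fitCalibration(x, as.numeric(y), "rodbard")
  expect_equal(unname(rod@coef), unname(pr), tolerance = 1e-4)

  # auto prefers the line on linear data
  expect_equal(fitCalibration(am, 50 * am + 3, "auto")@model, "linear")
  expect_error(fitCalibration(rep(3, 5), 1:5), "degenerate")
})

test_that("percentDelivered inverts the calibration", {
  cal <- fitCalibration(seq(0, 30, 5), 50 * seq(0, 30, 5), "linear")
  expect_equal(percentDelivered(50 * 20, cal, 20), 100)
  expect_equal(percentDelivered(50 * 10, cal, 20), 50)
  expect_error(percentDelivered(500, cal, 0), "administered")

  pr <- c(a = 5, b = 2.2, c = 12, d = 900)
  x <- seq(0.5, 40, length.out = 12)
  y <- as.numeric(pr["d"] + (pr["a"] - pr["d"]) / (1 + (x / pr["c"])^pr["b"]))
  rod <- fitCalibration(x, y, "rodbard")
  expect_equal(percentDelivered(y[6], rod, x[6]), 100, tolerance = 1e-3)
  expect_error(percentDelivered(1e6, rod, 10), "range")
})

test_that("percent delivered decreases with dose when efficiency does", {
  cal <- fitCalibration(seq(0, 30, 5), 50 * seq(0, 30, 5), "linear")
  doses <- c(10, 20, 40)
  eff <- 0.9 / (1 + doses / 15)     # delivery efficiency falls with dose
  pct <- vapply(seq_along(doses), function(i) {
    delivered <- doses[i] * eff[i]
    g <- genBrainImage(insideAmount = 0.7 * delivered,
                       outsideAmount = 0.3 * delivered, seed = 20 + i)
    sp <- insideOutsideSplit(g$image)
    percentDelivered(idValue(sp$inside) + idValue(sp$outside), cal,
                     doses[i])
  }, numeric(1))
  expect_true(all(diff(pct) < 0))
  expect_equal(pct, 100 * eff, tolerance = 0.02)
})
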