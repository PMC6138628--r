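test_that("blueShift resolves sub-grid emission-maximum shifts", {
  free <- gaussSpectrum(350)
  expect_equal(blueShift(free, free), 0, tolerance = 1e-9)
  bound <- gaussSpectrum(344)
  expect_equal(blueShift(free, bound), 6, tolerance = 0.1)
  flat <- Spectrum(seq(300, 400, 1), rep(5, 101))
  expect_error(blueShift(free, flat), "degenerate")
})

test_that("dilutionCorrect rescales by the volume ratio", {
  expect_equal(dilutionCorrect(100, 1000, 0), 100)
  expect_equal(dilutionCorrect(100, 1000, 100), 110)
  expect_error(dilutionCorrect(100, 0, 10), "v0")
  expect_error(dilutionCorrect(100, 1000, -1), "vAdded")
})

test_that("estimateFInf recovers the hyperbolic limit exactly", {
  L <- c(2e-5, 5e-5, 1e-4, 2e-4, 4e-4, 8e-4)
  Lp <- 0.6 * L
  f <- 300 * Lp / (5e-5 + Lp)  # double reciprocal of this is exactly linear
  fi <- estimateFInf(L, f)
  expect_equal(as.numeric(fi), 300, tolerance = 300 * 1e-3)
  expect_equal(attr(fi, "r2"), 1, tolerance = 1e-9)

  # constant fluorescence -> zero-slope line, F_inf = the constant
  expect_equal(as.numeric(estimateFInf(L, rep(120, 6))), 120,
               tolerance = 1e-9)

  # decreasing series is flagged
  expect_warning(try(estimateFInf(L, rev(f)), silent = TRUE), "decreas")
})

test_that("estimateFInf agrees with a brute-force grid search oracle", {
  L <- c(2e-5, 5e-5, 1e-4, 2e-4, 4e-4, 8e-4)
  f <- 300 * (0.6 * L) / (5e-5 + 0.6 * L)
  oracle <- bruteForceFInf(L, f)
  expect_equal(as.numeric(estimateFInf(L, f)), oracle, tolerance = 0.1)
})

test_that("boundFraction maps the fluorescence scale onto [0, 1]", {
  expect_equal(boundFraction(50, 50, 250), 0)
  expect_equal(boundFraction(250, 50, 250), 1)
  expect_equal(boundFraction(100, 50, 250), 0.25)
  expect_error(boundFraction(100, 50, 50), "degenerate")
  oor <- boundFraction(300, 50, 250)
  expect_true(attr(oor, "outOfRange"))
})

test_that("boundFraction composed with its inverse is the identity", {
  set.seed(41)
  for (rep in 1:25) {
    fb <- runif(1)
    f <- 50 + fb * (250 - 50)  # the inverse map
    expect_equal(as.numeric(boundFraction(f, 50, 250)), fb,
                 tolerance = 1e-12)
  }
})

test_that("buildIsotherm converts titrations point-wise", {
  # single-point arithmetic at the study's lipid-to-peptide ratio of 200
  s <- TitrationSeries(c(8e-4, 1e-3, 2e-3), c(200, 250, 280), "lipid_conc")
  iso <- buildIsotherm(s, peptideTotal = 4e-6, f0 = 100, fInf = 300,
                       outerFraction = 0.6)
  p1 <- iso@points[1, ]  # f = 200 -> fb = 0.5
  expect_equal(p1$fb, 0.5)
  expect_equal(p1$cf, 2e-6)
  expect_equal(p1$xb, 2.5e-3)
  expect_equal(p1$xb_star, 4.1667e-3, tolerance = 1e-4)

  # outerFraction 1 leaves xb unchanged
  iso1 <- buildIsotherm(s, 4e-6, 100, 300, outerFraction = 1)
  expect_equal(iso1@points$xb_star, iso1@points$xb)

  # all-unbound titration
  s0 <- TitrationSeries(c(1e-5, 1e-4, 1e-3), rep(100, 3), "lipid_conc")
  iso0 <- buildIsotherm(s0, 4e-6, 100, 300)
  expect_true(all(iso0@points$xb_star == 0))
  expect_true(all(iso0@points$cf == 4e-6))
})

test_that("partitionCoefficient recovers exact linear isotherm slopes", {
  for (kpTrue in c(4.24e4, 1.55e3)) {
    g <- genTrpTitration(kpTrue, seed = 2)
    iso <- buildIsotherm(g$series, g$truth$peptide_total, g$truth$f0,
                         g$truth$f_inf_true, g$truth$outer_fraction)
    fit <- partitionCoefficient(iso)
    expect_equal(kp(fit), kpTrue, tolerance = 1e-6)
    # independent oracle: direct origin-constrained slope formula on the
    # same initial-region points
    pts <- iso@points[iso@points$cf > 0, ]
    sel <- pts$cf <= 0.3 * max(pts$cf)
    if (sum(sel) < 3) sel <- rank(pts$cf, ties.method = "first") <= 4
    expect_equal(kp(fit),
                 originSlopeOracle(pts$cf[sel], pts$xb_star[sel]),
                 tolerance = 1e-9)
  }
  # a flat isotherm has no slope to report
  s0 <- TitrationSeries(c(1e-5, 1e-4, 1e-3), rep(100, 3), "lipid_conc")
  expect_error(partitionCoefficient(buildIsotherm(s0, 4e-6, 100, 300)),
               "zero-slope")
})

test_that("the initial-slope Kp is insensitive to surface self-association", {
  base <- genTrpTitration(4.24e4, cooperativity = 0, seed = 6)
  ref <- kp(partitionCoefficient(buildIsotherm(
    base$series, 4e-6, 100, 300, 0.6)))
  for (coop in c(2, 10, 50)) {
    g <- genTrpTitration(4.24e4, cooperativity = coop, seed = 6)
    kpc <- kp(partitionCoefficient(buildIsotherm(
      g$series, 4e-6, 100, 300, 0.6)))
    expect_equal(kpc, ref, tolerance = 0.05)
  }
})

test_that("sternVolmerFit recovers exact quenching constants", {
  for (ksvTrue in c(10.21, 2.05)) {
    g <- genQuenchingSeries(ksvTrue, seed = 2)
    fit <- sternVolmerFit(g$series, f0 = 100)
    expect_equal(ksv(fit), ksvTrue, tolerance = 1e-9)
    expect_equal(fit@intercept, 1, tolerance = 1e-9)
    expect_equal(fit@r2, 1, tolerance = 1e-9)
  }
  # constant fluorescence -> no quenching
  flat <- TitrationSeries(seq(0, 0.2, 0.05), rep(100, 5), "quencher_conc")
  expect_equal(ksv(sternVolmerFit(flat, f0 = 100)), 0)
  # contract checks
  g <- genQuenchingSeries(5, seed = 1)
  neg <- TitrationSeries(c(0, 0.05, 0.1, 0.15), c(100, 80, -1, 50),
                         "quencher_conc")
  expect_error(sternVolmerFit(neg, f0 = 100), "> 0")
  over <- TitrationSeries(c(0, 0.1, 0.25, 0.3), c(100, 80, 60, 55),
                          "quencher_conc")
  expect_error(sternVolmerFit(over, f0 = 100), "0.2")
})

test_that("sternVolmerFit matches the direct slope oracle under noise", {
  g <- genQuenchingSeries(3.04, noiseType = "multiplicative",
                          noiseSd = 0.02, seed = 9)
  fit <- sternVolmerFit(g$series, f0 = 100)
  q <- xValues(g$series); f <- yValues(g$series)
  expect_equal(ksv(fit),
               originSlopeOracle(q[q > 0], 100 / f[q > 0] - 1),
               tolerance = 1e-12)
})

test_that("noisy replicates preserve the Kp and Ksv condition orderings", {
  ok <- vapply(1:40, function(i) {
    gb <- genTrpTitration(4.24e4, noiseType = "multiplicative",
                          noiseSd = 0.02, seed = 1000 + i)
    gl <- genTrpTitration(1.55e3, noiseType = "multiplicative",
                          noiseSd = 0.02, seed = 2000 + i)
    kb <- kp(partitionCoefficient(buildIsotherm(gb$series, 4e-6, 100, 300)))
    kl <- kp(partitionCoefficient(buildIsotherm(gl$series, 4e-6, 100, 300)))
    qb <- ksv(sternVolmerFit(genQuenchingSeries(
      10.21, noiseType = "multiplicative", noiseSd = 0.02,
      seed = 3000 + i)$series, f0 = 100))
    ql <- ksv(sternVolmerFit(genQuenchingSeries(
      3.04, noiseType = "multiplicative", noiseSd = 0.02,
      seed = 4000 + i)$series, f0 = 100))
    qm <- ksv(sternVolmerFit(genQuenchingSeries(
      2.05, noiseType = "multiplicative", noiseSd = 0.02,
      seed = 5000 + i)$series, f0 = 100))
    kb > kl && qb > ql && ql > qm
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
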