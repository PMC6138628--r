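# Seeded ground-truth generators for every assay stage. Each generator is a
# pure function of (parameters, seed): the same call yields bit-identical
# output, and the true parameters are returned as a sidecar `truth` record,
# never embedded in the data. Noise defaults emulate photodetector behaviour:
# multiplicative Gaussian on fluorescence, additive Gaussian on images.

# Evaluate expr under a temporary RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

.applyNoise <- function(y, noiseType, noiseSd) {
  switch(noiseType,
    none = y,
    multiplicative = y * (1 + stats::rnorm(length(y), 0, noiseSd)),
    additive = y + stats::rnorm(length(y), 0, noiseSd),
    stop("unknown noiseType '", noiseType, "'"))
}

.truth <- function(stage, seed, noiseType, noiseSd, ...) {
  list(stage = stage, seed = seed,
       noise = list(type = noiseType, sd = noiseSd), ...)
}

#' Generate a two-band Laurdan emission spectrum with known GP
#'
#' The spectrum is the sum of two Gaussian bands centred at 440 nm
#' (ordered phase) and 490 nm (disordered phase), sigma 18 nm, sampled on a
#' 400-550 nm grid. Band amplitudes are solved, accounting for the
#' cross-band tails, so that the intensities read at exactly 440/490 nm
#' give `gpTrue` at zero noise. Because of the band overlap only
#' |GP| < (1 - t)/(1 + t) with t = exp(-50^2/(2*18^2)) (about 0.958) is
#' representable; a target beyond that is a generator error.
#'
#' @param gpTrue target generalized polarization, in (-1, 1).
#' @param nPoints number of grid points over 400-550 nm.
#' @param noiseType `"none"`, `"multiplicative"` or `"additive"`.
#' @param noiseSd noise sigma (relative for multiplicative, a.u. for
#'   additive).
#' @param seed integer seed.
#' @return list with `spectrum` ([Spectrum-class]) and `truth` (stage,
#'   gp_true, band amplitudes, seed, noise).
#' @export
genLaurdanSpectrum <- function(gpTrue, nPoints = 151, noiseType = "none",
                               noiseSd = 0, seed = 1) {
  if (gpTrue <= -1 || gpTrue >= 1) stop("gpTrue must be in (-1, 1)")
  sigma <- 18
  tail <- exp(-(490 - 440)^2 / (2 * sigma^2))
  g2 <- gpTrue * (1 + tail) / (1 - tail)
  if (abs(g2) >= 1)
    stop(sprintf(
      "gpTrue = %g infeasible under the 440/490 band overlap (|GP| < %.4f)",
      gpTrue, (1 - tail) / (1 + tail)))
  a490 <- 100
  a440 <- a490 * (1 + g2) / (1 - g2)
  wl <- seq(400, 550, length.out = nPoints)
  y <- a440 * exp(-(wl - 440)^2 / (2 * sigma^2)) +
       a490 * exp(-(wl - 490)^2 / (2 * sigma^2))
  y <- withSeed(seed, .applyNoise(y, noiseType, noiseSd))
  list(
    spectrum = Spectrum(wl, y, kind = "emission", excitationNm = 365,
                        label = sprintf("laurdan gp=%g", gpTrue)),
    truth = .truth("laurdan_gp", seed, noiseType, noiseSd,
                   gp_true = gpTrue, a440 = a440, a490 = a490,
                   sigma_nm = sigma))
}

#' Generate a lipid-mixing (or leakage) P/L titration with known plateau
#'
#' Monotone saturating Hill curve
#' `extent(x) = plateau * x^h / (x^h + K^h)` with `K` chosen so the extent
#' reaches 95% of the plateau exactly at `saturationPL`; fluorescence is
#' `F = f0 + extent/100 * (f100 - f0)` plus noise. `plateauPercent = 0`
#' yields a flat series at `f0` (the leakage-free case).
#'
#' @param saturationPL P/L ratio at which the curve reaches 95% of its
#'   plateau.
#' @param plateauPercent plateau extent in percent, in \[0, 100\].
#' @param f0,f100 assay fluorescence levels (`f100 != f0`).
#' @param plGrid P/L ratios to sample (non-empty).
#' @param hill Hill exponent of the curve family (default 2).
#' @param noiseType,noiseSd,seed see [genLaurdanSpectrum()].
#' @return list with `series` ([TitrationSeries-class]) and `truth`.
#' @export
genMixingSeries <- function(saturationPL, plateauPercent, f0 = 10,
                            f100 = 110, plGrid, hill = 2,
                            noiseType = "none", noiseSd = 0, seed = 1) {
  if (!length(plGrid)) stop("input error: empty PL grid")
  if (f100 == f0) stop("f100 must differ from f0")
  if (plateauPercent < 0 || plateauPercent > 100)
    stop("plateauPercent must be in [0, 100]")
  k <- saturationPL * (0.05 / 0.95)^(1 / hill)
  extent <- if (plateauPercent == 0) rep(0, length(plGrid))
    else plateauPercent * plGrid^hill / (plGrid^hill + k^hill)
  f <- f0 + extent / 100 * (f100 - f0)
  f <- withSeed(seed, .applyNoise(f, noiseType, noiseSd))
  list(
    series = TitrationSeries(plGrid, f, xKind = "peptide_lipid_ratio"),
    truth = .truth("lipid_mixing", seed, noiseType, noiseSd,
                   saturation_PL = saturationPL,
                   plateau_percent = plateauPercent, f0 = f0, f100 = f100,
                   hill = hill, k = k, extent = extent))
}

#' Generate a tryptophan lipid titration consistent with a partition
#' equilibrium
#'
#' For each lipid concentration the bound fraction is the solution of the
#' partition balance `X_b* = iso(C_f)` with
#' `iso(c) = Kp c` below a critical free-peptide concentration and an
#' added upward-curving term `Kp * cooperativity * (c - cfCritical)^2 /
#' cfCritical` above it (surface self-association). With
#' `cooperativity = 0` the balance has the closed form
#' `f_b = Ko L / (1 + Ko L)`, `Ko = Kp * outerFraction`; otherwise it is
#' solved numerically (the balance is strictly monotone in `f_b`).
#' Fluorescence is `F = f0 + f_b (fInfTrue - f0)` plus noise.
#'
#' @param kpTrue true partition coefficient (M^-1, > 0).
#' @param peptideTotal total peptide concentration (M), default 4e-6.
#' @param lipidGrid lipid concentrations (M); default 10 log-spaced points
#'   from 1e-5 to 8e-4 M (lipid-to-peptide ratio 2.5 to 200).
#' @param f0,fInfTrue fluorescence scale.
#' @param outerFraction accessible-lipid fraction, default 0.6.
#' @param cooperativity self-association strength (>= 0; 0 = pure
#'   partition).
#' @param cfCritical onset of self-association (M); default
#'   `0.4 * peptideTotal`.
#' @param noiseType,noiseSd,seed see [genLaurdanSpectrum()].
#' @return list with `series` ([TitrationSeries-class]) and `truth`
#'   (includes the exact per-point bound fractions).
#' @export
genTrpTitration <- function(kpTrue, peptideTotal = 4e-6,
                            lipidGrid = exp(seq(log(1e-5), log(8e-4),
                                                length.out = 10)),
                            f0 = 100, fInfTrue = 300, outerFraction = 0.6,
                            cooperativity = 0, cfCritical = NULL,
                            noiseType = "none", noiseSd = 0, seed = 1) {
  if (kpTrue <= 0) stop("kpTrue must be > 0")
  if (is.null(cfCritical)) cfCritical <- 0.4 * peptideTotal
  iso <- function(cf)
    kpTrue * cf + if (cooperativity > 0)
      kpTrue * cooperativity * pmax(0, cf - cfCritical)^2 / cfCritical
    else 0
  fb <- vapply(lipidGrid, function(L) {
    if (L == 0) return(0)
    if (cooperativity == 0) {
      ko <- kpTrue * outerFraction
      return(ko * L / (1 + ko * L))
    }
    bal <- function(b)
      b * peptideTotal / (L * outerFraction) - iso((1 - b) * peptideTotal)
    root <- stats::uniroot(bal, c(0, 1), tol = 1e-14)
    if (abs(bal(root$root)) > 1e-6 * kpTrue * peptideTotal)
      stop("generator error: no partition-balance solution in [0, 1]")
    root$root
  }, numeric(1))
  f <- f0 + fb * (fInfTrue - f0)
  f <- withSeed(seed, .applyNoise(f, noiseType, noiseSd))
  list(
    series = TitrationSeries(lipidGrid, f, xKind = "lipid_conc"),
    truth = .truth("trp_titration", seed, noiseType, noiseSd,
                   kp_true = kpTrue, peptide_total = peptideTotal,
                   f0 = f0, f_inf_true = fInfTrue,
                   outer_fraction = outerFraction,
                   cooperativity = cooperativity,
                   cf_critical = cfCritical, fb = fb))
}

#' Generate an acrylamide quenching titration with known Ksv
#'
#' Exact inversion of the Stern-Volmer law: `F = f0 / (1 + Ksv q)` plus
#' noise, on a quencher grid bounded by 0.2 M.
#'
#' @param ksvTrue true Stern-Volmer constant (M^-1, >= 0).
#' @param f0 unquenched fluorescence.
#' @param qGrid quencher concentrations (M), all in \[0, 0.2\].
#' @param noiseType,noiseSd,seed see [genLaurdanSpectrum()].
#' @return list with `series` ([TitrationSeries-class]) and `truth`.
#' @export
genQuenchingSeries <- function(ksvTrue, f0 = 100,
                               qGrid = seq(0, 0.2, by = 0.025),
                               noiseType = "none", noiseSd = 0, seed = 1) {
  if (ksvTrue < 0) stop("ksvTrue must be >= 0")
  if (any(qGrid < 0)) stop("input error: negative quencher concentration")
  if (any(qGrid > 0.2))
    stop("input error: quencher grid exceeds the 0.2 M maximum")
  f <- f0 / (1 + ksvTrue * qGrid)
  f <- withSeed(seed, .applyNoise(f, noiseType, noiseSd))
  list(
    series = TitrationSeries(qGrid, f, xKind = "quencher_conc"),
    truth = .truth("stern_volmer", seed, noiseType, noiseSd,
                   ksv_true = ksvTrue, f0 = f0))
}

# Fixed analytic CD basis shapes (Gaussian mixtures; arguments in nm).
# Helix: negative bands near 222 and 208 nm, positive band near 193 nm.
# Coil: strong negative band near 198 nm, near-zero signal at 222 nm.
.cdHelixBasis <- function(wl)
  -1.00 * exp(-(wl - 222)^2 / (2 * 10.5^2)) -
   1.05 * exp(-(wl - 208)^2 / (2 * 9^2)) +
   1.90 * exp(-(wl - 193)^2 / (2 * 7.5^2))

.cdCoilBasis <- function(wl)
  -1.00 * exp(-(wl - 198)^2 / (2 * 9^2)) +
   0.08 * exp(-(wl - 220)^2 / (2 * 11^2))

#' Generate a CD spectrum with known helix fraction and 222/208 ratio
#'
#' A linear combination of a fixed helix basis (negative bands at 208 and
#' 222 nm, positive near 193 nm) and a coil basis (near-zero at 222 nm).
#' The two amplitudes are solved from the pair of constraints
#' `mre222 = fHTrue * (-40000 (1 - 2.5/nRes))` and
#' `mre222/mre208 = ratioTarget`, both evaluated under `convention`, so a
#' zero-noise round trip through [analyzeCD()] recovers the targets
#' exactly. `fHTrue = 0` emits a pure-coil spectrum (the ratio target does
#' not apply). The returned spectrum is the observed ellipticity in mdeg
#' for the stated path length and concentration, on a 190-260 nm grid that
#' contains 208 and 222 nm as exact grid points.
#'
#' @param fHTrue target helix fraction in \[0, 1\].
#' @param ratioTarget target theta222/theta208 ratio (ignored when
#'   `fHTrue = 0`).
#' @param nRes number of residues (> 2).
#' @param pathCm,concM acquisition geometry used to scale MRE back to mdeg.
#' @param convention `"paper"` or `"factor10"`; must match the analyzer's.
#' @param noiseType `"none"`, `"multiplicative"` (per grid point),
#'   `"additive"` (mdeg) or `"band"` (multiplicative on the two basis
#'   amplitudes).
#' @param noiseSd,seed see [genLaurdanSpectrum()].
#' @return list with `spectrum` (CD [Spectrum-class], mdeg) and `truth`.
#' @export
genCDSpectrum <- function(fHTrue, ratioTarget = 0.68, nRes = 20,
                          pathCm = 0.1, concM = 8e-6,
                          convention = c("paper", "factor10"),
                          noiseType = "none", noiseSd = 0, seed = 1) {
  convention <- match.arg(convention)
  if (fHTrue < 0 || fHTrue > 1) stop("fHTrue must be in [0, 1]")
  if (nRes <= 2) stop("nRes must exceed 2")
  wl <- seq(190, 260, by = 0.5)
  h222 <- .cdHelixBasis(222); h208 <- .cdHelixBasis(208)
  c222 <- .cdCoilBasis(222); c208 <- .cdCoilBasis(208)
  ref <- -40000 * (1 - 2.5 / nRes)
  if (fHTrue == 0) {
    alpha <- 0
    beta <- 15000  # coil amplitude: ~-15000 MRE at the 198 nm trough
  } else {
    m222 <- fHTrue * ref
    m208 <- m222 / ratioTarget
    det <- h222 * c208 - h208 * c222
    alpha <- (m222 * c208 - m208 * c222) / det
    beta <- (h222 * m208 - h208 * m222) / det
    if (!is.finite(alpha) || !is.finite(beta) || alpha < 0)
      stop(sprintf(
        "generator error: (fH = %g, ratio = %g) infeasible under the basis shapes",
        fHTrue, ratioTarget))
  }
  res <- withSeed(seed, {
    a <- alpha; b <- beta
    if (noiseType == "band") {
      a <- a * (1 + stats::rnorm(1, 0, noiseSd))
      b <- b * (1 + stats::rnorm(1, 0, noiseSd))
    }
    mreCurve <- a * .cdHelixBasis(wl) + b * .cdCoilBasis(wl)
    denom <- pathCm * concM * nRes * if (convention == "factor10") 10 else 1
    obsd <- mreCurve * denom
    if (!noiseType %in% c("none", "band"))
      obsd <- .applyNoise(obsd, noiseType, noiseSd)
    obsd
  })
  list(
    spectrum = Spectrum(wl, res, kind = "cd",
                        label = sprintf("cd fH=%g", fHTrue)),
    truth = .truth("cd_spectrum", seed, noiseType, noiseSd,
                   fH_true = fHTrue,
                   ratio_target = if (fHTrue == 0) NA_real_ else ratioTarget,
                   n_res = nRes, path_cm = pathCm, conc_M = concM,
                   convention = convention, alpha = alpha, beta = beta))
}

#' Generate a brain-slice vessel image with known inside/outside amounts
#'
#' Vessels are rendered as thick smoothed random-walk tubes crossing the
#' frame; the vessel pixels carry a total fluorescence of
#' `calibrationSlope * insideAmount` (so integrated density inverts to the
#' amount through a linear calibration of that slope). Parenchymal signal
#' outside the vessels is rendered as Gaussian puncta carrying
#' `calibrationSlope * outsideAmount` in total. Optional additive Gaussian
#' noise and a constant background offset are applied last (clipped at 0).
#' The ground-truth vessel mask is emitted with the image.
#'
#' @param shape integer(2), image rows and columns.
#' @param nVessels number of vessel tubes.
#' @param vesselRadius tube half-width in pixels.
#' @param insideAmount,outsideAmount fluorophore amounts (calibration
#'   units, >= 0).
#' @param calibrationSlope integrated density per unit amount.
#' @param pixelAreaUm2 pixel area (um^2).
#' @param nPuncta number of parenchymal puncta.
#' @param background constant background offset (a.u.).
#' @param noiseSd additive Gaussian noise sigma (a.u.).
#' @param seed integer seed.
#' @return list with `image` ([VesselImage-class]) and `truth`.
#' @export
genBrainImage <- function(shape = c(160, 160), nVessels = 3,
                          vesselRadius = 4, insideAmount = 70,
                          outsideAmount = 30, calibrationSlope = 50,
                          pixelAreaUm2 = 1, nPuncta = 80, background = 0,
                          noiseSd = 0, seed = 1) {
  if (insideAmount < 0 || outsideAmount < 0)
    stop("amounts must be >= 0")
  nr <- shape[1]; nc <- shape[2]
  withSeed(seed, {
    mask <- matrix(FALSE, nr, nc)
    dr <- -vesselRadius:vesselRadius
    disc <- expand.grid(dr = dr, dc = dr)
    disc <- disc[disc$dr^2 + disc$dc^2 <= vesselRadius^2, ]
    for (v in seq_len(nVessels)) {
      row <- stats::runif(1, 0.15, 0.85) * nr
      ang <- stats::runif(1, -0.35, 0.35)
      col <- 1
      while (col <= nc) {
        rr <- pmin(pmax(round(row) + disc$dr, 1), nr)
        cc <- pmin(pmax(round(col) + disc$dc, 1), nc)
        mask[cbind(rr, cc)] <- TRUE
        ang <- ang + stats::rnorm(1, 0, 0.1)
        ang <- max(min(ang, 1.2), -1.2)
        row <- min(max(row + sin(ang), 1), nr)
        col <- col + cos(ang)
      }
    }
    if (!any(mask) || all(mask))
      stop("generator error: degenerate vessel geometry")
    inside <- matrix(0, nr, nc)
    nin <- sum(mask)
    inside[mask] <- calibrationSlope * insideAmount / (nin * pixelAreaUm2)
    outside <- matrix(0, nr, nc)
    if (outsideAmount > 0) {
      free <- which(!mask)
      centers <- sample(free, min(nPuncta, length(free)))
      sig <- 1.6; rad <- 4
      off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
      kern <- exp(-(off$dr^2 + off$dc^2) / (2 * sig^2))
      for (ct in centers) {
        r0 <- (ct - 1) %% nr + 1
        c0 <- (ct - 1) %/% nr + 1
        rr <- r0 + off$dr; cc <- c0 + off$dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        idx <- cbind(rr[ok], cc[ok])
        outside[idx] <- outside[idx] +
          kern[ok] * stats::runif(1, 0.5, 1.5)
      }
      outside[mask] <- 0
      tot <- sum(outside)
      if (tot == 0) stop("generator error: no room for parenchymal puncta")
      outside <- outside *
        (calibrationSlope * outsideAmount / (tot * pixelAreaUm2))
    }
    px <- inside + outside + background
    if (noiseSd > 0)
      px <- px + stats::rnorm(length(px), 0, noiseSd)
    px <- pmax(px, 0)
    list(
      image = VesselImage(matrix(px, nr, nc), mask,
                          pixelAreaUm2 = pixelAreaUm2,
                          label = "synthetic brain slice"),
      truth = .truth("brain_image", seed, "additive", noiseSd,
                     inside_amount = insideAmount,
                     outside_amount = outsideAmount,
                     calibration_slope = calibrationSlope,
                     background = background, n_vessel_px = sum(mask)))
  })
}

#' Study-condition presets for the synthetic generators
#'
#' Bundles, per membrane condition, the generator truths taken from the
#' study this package models: GP values per condition and temperature, the
#' partition coefficient Kp, the Stern-Volmer constant Ksv, the helix
#' fraction and 222/208 ratio, the fusion saturation P/L with the total and
#' inner-monolayer plateaus, zero leakage, and the sampling grids each
#' titration uses. By construction the presets reproduce the study's
#' orderings: Kp(BBB) > Kp(liver), Ksv(buffer) > Ksv(liver) > Ksv(BBB),
#' helicity(BBB) > helicity(liver), saturation P/L (BBB) < (liver),
#' inner-monolayer plateau (BBB) << (liver).
#'
#' @param label `"BBB"`, `"liver"` or `"buffer"`.
#' @return named list of stage truths and grids.
#' @export
conditionPreset <- function(label) {
  presets <- list(
    BBB = list(
      label = "BBB",
      gp = c(no_peptide_25C = 0.20, no_peptide_37C = 0.19,
             peptide_37C = 0.15),
      kp = 4.24e4, ksv = 2.05, fH = 0.58, ratio = 0.68,
      saturationPL = 0.05, totalPlateau = 100, innerPlateau = 20,
      leakagePlateau = 0,
      plGrid = c(0.002, 0.005, 0.01, 0.02, 0.03, 0.05, 0.07, 0.1),
      lipidGrid = exp(seq(log(1e-5), log(8e-4), length.out = 10)),
      qGrid = seq(0, 0.2, by = 0.025)),
    liver = list(
      label = "liver",
      gp = c(no_peptide_25C = 0.44, no_peptide_37C = 0.40,
             peptide_37C = 0.49),
      kp = 1.55e3, ksv = 3.04, fH = 0.40, ratio = 0.45,
      saturationPL = 0.7, totalPlateau = 100, innerPlateau = 100,
      leakagePlateau = 0,
      plGrid = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.7, 0.9, 1.2),
      lipidGrid = exp(seq(log(1e-5), log(8e-4), length.out = 10)),
      qGrid = seq(0, 0.2, by = 0.025)),
    buffer = list(
      label = "buffer",
      gp = NULL, kp = NA_real_, ksv = 10.21, fH = 0, ratio = NA_real_,
      saturationPL = NA_real_, totalPlateau = NA_real_,
      innerPlateau = NA_real_, leakagePlateau = NA_real_,
      plGrid = NULL,
      lipidGrid = NULL,
      qGrid = seq(0, 0.2, by = 0.025))
  )
  if (!label %in% names(presets))
    stop("unknown preset '", label, "'; valid labels: ",
         paste(names(presets), collapse = ", "))
  presets[[label]]
}

#' Generate and re-analyze one full condition (end-to-end round trip)
#'
#' For the given condition preset, generates every applicable synthetic
#' assay at the stated noise level and runs the corresponding analysis,
#' returning the recovered quantities next to the preset truths. This is
#' the workhorse of the parameter-recovery and ordering checks.
#'
#' @param label `"BBB"`, `"liver"` or `"buffer"`.
#' @param seed integer seed (stage sub-seeds are derived by small offsets).
#' @param noiseType,noiseSd noise settings passed to every generator
#'   (default 2% multiplicative).
#' @return named list of recovered values: `kp`, `ksv`, `gp` (with-peptide
#'   37C condition), `helixFraction`, `ratio`, `state`, `saturationPL`,
#'   `totalPlateau`, `innerPlateau`, `leakageMaxAbs`, plus `truth` (the
#'   preset).
#' @export
runConditionRecovery <- function(label, seed = 1,
                                 noiseType = "multiplicative",
                                 noiseSd = 0.02) {
  pre <- conditionPreset(label)
  out <- list(truth = pre, label = label)
  # tryptophan binding -> Kp
  if (is.finite(pre$kp)) {
    g <- genTrpTitration(pre$kp, lipidGrid = pre$lipidGrid,
                         noiseType = noiseType, noiseSd = noiseSd,
                         seed = seed + 1)
    iso <- buildIsotherm(g$series, g$truth$peptide_total, g$truth$f0,
                         g$truth$f_inf_true, g$truth$outer_fraction)
    out$kp <- kp(partitionCoefficient(iso))
  } else out$kp <- NA_real_
  # acrylamide quenching -> Ksv
  g <- genQuenchingSeries(pre$ksv, qGrid = pre$qGrid,
                          noiseType = noiseType, noiseSd = noiseSd,
                          seed = seed + 2)
  out$ksv <- ksv(sternVolmerFit(g$series, f0 = g$truth$f0))
  # Laurdan GP (with peptide, 37 C)
  if (!is.null(pre$gp)) {
    g <- genLaurdanSpectrum(pre$gp[["peptide_37C"]], noiseType = noiseType,
                            noiseSd = noiseSd, seed = seed + 3)
    out$gp <- gp(gpFromSpectrum(g$spectrum))
  } else out$gp <- NA_real_
  # CD -> helicity and association state
  g <- genCDSpectrum(pre$fH,
                     ratioTarget = if (is.na(pre$ratio)) 0.68 else pre$ratio,
                     noiseType = noiseType, noiseSd = noiseSd,
                     seed = seed + 4)
  cd <- analyzeCD(g$spectrum, g$truth$path_cm, g$truth$conc_M,
                  g$truth$n_res, g$truth$convention)
  out$helixFraction <- helixFractionOf(cd)
  out$ratio <- cd@ratio222_208
  out$state <- oligomerStateOf(cd)
  # fusion assays
  if (!is.null(pre$plGrid)) {
    g <- genMixingSeries(pre$saturationPL, pre$totalPlateau,
                         plGrid = pre$plGrid, noiseType = noiseType,
                         noiseSd = noiseSd, seed = seed + 5)
    ft <- fitSaturation(mixingCurve(g$series, g$truth$f0, g$truth$f100,
                                    assay = "total"))
    out$saturationPL <- ft$saturationPL
    out$totalPlateau <- ft$plateau
    g <- genMixingSeries(pre$saturationPL, pre$innerPlateau,
                         plGrid = pre$plGrid, noiseType = noiseType,
                         noiseSd = noiseSd, seed = seed + 6)
    fi <- fitSaturation(mixingCurve(g$series, g$truth$f0, g$truth$f100,
                                    assay = "inner_monolayer"))
    out$innerPlateau <- fi$plateau
    g <- genMixingSeries(pre$saturationPL, pre$leakagePlateau,
                         plGrid = pre$plGrid, noiseType = noiseType,
                         noiseSd = noiseSd, seed = seed + 7)
    lk <- mixingCurve(g$series, g$truth$f0, g$truth$f100,
                      assay = "leakage")
    out$leakageMaxAbs <- max(abs(mixingPercents(lk)))
  } else {
    out$saturationPL <- out$totalPlateau <- out$innerPlateau <-
      out$leakageMaxAbs <- NA_real_
  }
  out
}
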