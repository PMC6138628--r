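# Tryptophan-fluorescence binding analysis. The binding is modelled as a
# surface partition equilibrium X_b = Kp * C_f; X_b is corrected to the
# outer-leaflet-accessible lipid as X_b* = X_b / outer_fraction (0.6 by
# default). Tryptophan accessibility to acrylamide follows the
# Stern-Volmer law F0/F = 1 + Ksv [Q].

#' Emission-maximum blue shift between two spectra
#'
#' The maximum of each spectrum is located on the grid and refined by a
#' local parabola through the three points around it, giving sub-nm
#' resolution for the small shifts membrane insertion produces.
#'
#' @param spectrumFree emission [Spectrum-class] of the peptide in buffer.
#' @param spectrumBound emission [Spectrum-class] in the presence of
#'   vesicles.
#' @return shift in nm, `lambda_max(free) - lambda_max(bound)`; positive
#'   values are blue shifts (toward shorter wavelength, i.e. a less polar
#'   tryptophan environment).
#' @export
blueShift <- function(spectrumFree, spectrumBound) {
  .lambdaMax(spectrumFree) - .lambdaMax(spectrumBound)
}

.lambdaMax <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  y <- spectrum@values
  x <- spectrum@wavelength
  if (diff(range(y)) == 0)
    stop("degenerate input: flat spectrum has no unique maximum")
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(x[i])  # boundary maximum
  # quadratic through the three bracketing points (grid may be non-uniform)
  xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(x[i])
  unname(-co[2] / (2 * co[3]))
}

#' Correct a fluorescence reading for titration dilution
#'
#' @param fRaw measured fluorescence (a.u.).
#' @param v0 initial sample volume (> 0, any unit).
#' @param vAdded cumulative added titrant volume (>= 0, same unit).
#' @return `fRaw * (v0 + vAdded) / v0`.
#' @examples
#' dilutionCorrect(100, 1000, 100)  # 110
#' @export
dilutionCorrect <- function(fRaw, v0, vAdded) {
  if (any(v0 <= 0)) stop("input error: v0 must be > 0")
  if (any(vAdded < 0)) stop("input error: vAdded must be >= 0")
  fRaw * (v0 + vAdded) / v0
}

#' Limiting fluorescence at complete binding by double-reciprocal
#' extrapolation
#'
#' Ordinary least squares of `1/F` against `1/(outerFraction * L)`;
#' `F_inf = 1/intercept`. The reading of the double-reciprocal plot is
#' ambiguous between total fluorescence and the binding-induced increment;
#' the default regresses `1/F` (literal total fluorescence), and
#' `subtractF0 = TRUE` selects the `1/(F - F0)` alternative (then
#' `F_inf = 1/intercept + f0`).
#'
#' @param lipidTotal total lipid concentrations (M), all > 0.
#' @param f fluorescence at each lipid concentration (a.u.).
#' @param outerFraction accessible-lipid fraction, default 0.6.
#' @param subtractF0 use the `1/(F - F0)` variant.
#' @param f0 free-peptide fluorescence, required when `subtractF0 = TRUE`.
#' @return `F_inf` (numeric) with attributes `intercept`, `slope`, `r2` of
#'   the double-reciprocal line.
#' @export
estimateFInf <- function(lipidTotal, f, outerFraction = 0.6,
                         subtractF0 = FALSE, f0 = NULL) {
  if (length(lipidTotal) < 3)
    stop("insufficient data: need >= 3 points with lipid > 0")
  if (any(lipidTotal <= 0)) stop("all lipid concentrations must be > 0")
  ctrend <- suppressWarnings(stats::cor(lipidTotal, f))
  if (!is.na(ctrend) && ctrend < 0)
    warning("fluorescence decreases with lipid; extrapolation is suspect")
  yv <- if (subtractF0) {
    if (is.null(f0)) stop("subtractF0 = TRUE requires f0")
    if (any(f <= f0)) stop("all F must exceed f0 for the 1/(F - F0) variant")
    1 / (f - f0)
  } else {
    if (any(f <= 0)) stop("all F must be > 0")
    1 / f
  }
  xv <- 1 / (outerFraction * lipidTotal)
  fit <- stats::lm(yv ~ xv)
  ic <- unname(stats::coef(fit)[1])
  if (ic <= 0)
    stop("extrapolation failure: non-positive double-reciprocal intercept (",
         format(ic), ")")
  fInf <- 1 / ic + if (subtractF0) f0 else 0
  attr(fInf, "intercept") <- ic
  attr(fInf, "slope") <- unname(stats::coef(fit)[2])
  sst <- sum((yv - mean(yv))^2)
  attr(fInf, "r2") <- if (sst == 0) 1
    else 1 - sum(stats::resid(fit)^2) / sst
  fInf
}

#' Fraction of membrane-bound peptide
#'
#' `f_b = (F - F0)/(F_inf - F0)`. Values outside \[0, 1\] (possible with
#' noisy data) are returned unclamped with an `outOfRange` attribute.
#'
#' @param f fluorescence in the presence of vesicles (a.u.).
#' @param f0 fluorescence of the free peptide.
#' @param fInf fluorescence at complete binding.
#' @return bound fraction(s).
#' @examples
#' boundFraction(100, f0 = 50, fInf = 250)  # 0.25
#' @export
boundFraction <- function(f, f0, fInf) {
  if (fInf == f0) stop("degenerate scale: fInf must differ from f0")
  fb <- (f - f0) / (fInf - f0)
  oor <- fb < 0 | fb > 1
  if (any(oor)) attr(fb, "outOfRange") <- oor
  fb
}

#' Build the binding isotherm from a lipid titration
#'
#' Per titration point: `f_b` from [boundFraction()], bound peptide
#' `f_b * P_total`, free peptide `C_f = (1 - f_b) * P_total`, bound-per-lipid
#' `X_b = f_b * P_total / L_total`, and the accessible-lipid correction
#' `X_b* = X_b / outerFraction`. Bound fractions outside \[0, 1\] are
#' clamped before the conversion (the `clamped` column records which), so
#' the isotherm invariants `C_f >= 0`, `X_b* >= 0` always hold; clamped
#' points land at `C_f = 0` and carry no weight in the initial-slope fit.
#'
#' @param series a `lipid_conc` [TitrationSeries-class].
#' @param peptideTotal total peptide concentration (M, > 0).
#' @param f0,fInf fluorescence scale, see [boundFraction()].
#' @param outerFraction accessible-lipid fraction, default 0.6.
#' @return a [BindingIsotherm-class].
#' @export
buildIsotherm <- function(series, peptideTotal, f0, fInf,
                          outerFraction = 0.6) {
  stopifnot(is(series, "TitrationSeries"))
  if (series@xKind != "lipid_conc")
    stop("isotherms require a lipid_conc series")
  if (peptideTotal <= 0) stop("peptideTotal must be > 0")
  if (!length(series@x)) stop("empty titration series")
  fb <- as.numeric(boundFraction(series@y, f0, fInf))
  clamped <- fb < 0 | fb > 1
  fb <- pmin(pmax(fb, 0), 1)
  L <- series@x
  xb <- ifelse(L > 0, fb * peptideTotal / L, 0)
  pts <- data.frame(
    lipid_total = L, f = series@y, fb = fb,
    cf = (1 - fb) * peptideTotal,
    xb = xb, xb_star = xb / outerFraction, clamped = clamped)
  new("BindingIsotherm", points = pts, f0 = f0, fInf = fInf,
      peptideTotal = peptideTotal, outerFraction = outerFraction)
}

#' Surface partition coefficient from the initial slope of the isotherm
#'
#' `Kp` is the slope at the origin of `X_b*` versus `C_f`, obtained by a
#' least-squares line through the origin over the initial region of the
#' isotherm. The initial region is the set of points with
#' `C_f <= initialSlopeFraction * max(C_f)` (default 30%); when fewer than
#' `initialSlopeMinPoints` qualify, the `initialSlopeFallbackPoints`
#' lowest-`C_f` points are used instead. Restricting the fit to the initial
#' region makes `Kp` insensitive to surface self-association, which only
#' bends the isotherm upward at higher `C_f`.
#'
#' @param isotherm a [BindingIsotherm-class].
#' @param config an [AnalysisConfig-class] supplying the selection rule.
#' @return a [PartitionFit-class].
#' @export
partitionCoefficient <- function(isotherm, config = AnalysisConfig()) {
  stopifnot(is(isotherm, "BindingIsotherm"))
  pts <- isotherm@points
  if (all(pts$xb_star == 0))
    stop("zero-slope diagnostic: all xb_star are 0; no partitioning detected")
  pts <- pts[pts$cf > 0 & !duplicated(pts$cf), , drop = FALSE]
  if (nrow(pts) < config@initialSlopeMinPoints)
    stop("insufficient data: need >= ", config@initialSlopeMinPoints,
         " isotherm points with distinct positive cf")
  sel <- pts$cf <= config@initialSlopeFraction * max(pts$cf)
  if (sum(sel) < config@initialSlopeMinPoints) {
    k <- min(config@initialSlopeFallbackPoints, nrow(pts))
    sel <- rank(pts$cf, ties.method = "first") <= k
  }
  use <- pts[sel, , drop = FALSE]
  if (all(use$xb_star == 0))
    stop("zero-slope diagnostic: all xb_star are 0; no partitioning detected")
  fit <- stats::lm(xb_star ~ 0 + cf, data = use)
  slope <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("zero-slope diagnostic: non-positive initial slope (",
         format(slope), ")")
  ss_res <- sum(stats::resid(fit)^2)
  dfree <- max(nrow(use) - 1L, 1L)
  new("PartitionFit", kp = slope, nPointsUsed = nrow(use),
      slopeSE = sqrt((ss_res / dfree) / sum(use$cf^2)),
      r2 = 1 - ss_res / max(sum(use$xb_star^2), .Machine$double.xmin))
}

#' Stern-Volmer quenching constant from an acrylamide titration
#'
#' Fits `F0/F - 1 = Ksv [Q]` by least squares constrained through the
#' origin (the Stern-Volmer intercept is exactly 1); a free-intercept refit
#' of `F0/F` is reported as a diagnostic.
#'
#' @param series a `quencher_conc` [TitrationSeries-class] with `[Q]` in M.
#' @param f0 fluorescence without quencher; if omitted the series must
#'   contain a `[Q] = 0` point, whose mean F is used.
#' @param maxQuencherM admissible quencher-concentration ceiling (M),
#'   default 0.2.
#' @return a [SternVolmerFit-class].
#' @export
sternVolmerFit <- function(series, f0 = NULL, maxQuencherM = 0.2) {
  stopifnot(is(series, "TitrationSeries"))
  if (series@xKind != "quencher_conc")
    stop("Stern-Volmer fits require a quencher_conc series")
  if (any(series@y <= 0)) stop("input error: all F must be > 0")
  if (any(series@x > maxQuencherM))
    stop("quencher concentration exceeds the admissible maximum of ",
         maxQuencherM, " M")
  if (is.null(f0)) {
    at0 <- series@x == 0
    if (!any(at0))
      stop("supply f0 or include a [Q] = 0 point in the series")
    f0 <- mean(series@y[at0])
  }
  q <- series@x[series@x > 0]
  fq <- series@y[series@x > 0]
  if (length(q) < 3)
    stop("insufficient data: need >= 3 points with [Q] > 0")
  y <- f0 / fq - 1
  ks <- sum(q * y) / sum(q * q)
  ss_res <- sum((y - ks * q)^2)
  r2 <- 1 - ss_res / max(sum(y^2), .Machine$double.xmin)
  free <- stats::lm(I(f0 / fq) ~ q)
  new("SternVolmerFit", ksv = ks,
      intercept = unname(stats::coef(free)[1]), r2 = r2)
}
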