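# Laurdan generalized polarization and FRET lipid-mixing / leakage
# normalization. GP = (I440 - I490)/(I440 + I490) with I440 the
# ordered-phase and I490 the disordered-phase emission band.

#' Laurdan generalized polarization from the two band intensities
#'
#' @param i440 intensity of the ordered-phase band (a.u., >= 0).
#' @param i490 intensity of the disordered-phase band (a.u., >= 0).
#' @return GP = (i440 - i490)/(i440 + i490), in \[-1, 1\]. Higher GP means a
#'   more ordered (less fluid) bilayer.
#' @examples
#' laurdanGP(150, 50)  # 0.5
#' @export
laurdanGP <- function(i440, i490) {
  if (any(i440 < 0) || any(i490 < 0))
    stop("band intensities must be >= 0")
  s <- i440 + i490
  if (any(s == 0))
    stop("degenerate input: i440 + i490 must be non-zero")
  (i440 - i490) / s
}

#' Generalized polarization from a Laurdan emission spectrum
#'
#' Band intensities are read at the canonical 440/490 nm positions (linear
#' interpolation; `bandMode = "window"` instead takes the maximum within
#' `bandWindowNm` of each position).
#'
#' @param spectrum an emission [Spectrum-class] covering both bands.
#' @param config an [AnalysisConfig-class]; `gpBandsNm`, `bandMode` and
#'   `bandWindowNm` are used.
#' @return a [GPResult-class].
#' @export
gpFromSpectrum <- function(spectrum, config = AnalysisConfig()) {
  stopifnot(is(spectrum, "Spectrum"))
  if (spectrum@kind != "emission")
    stop("GP requires an emission spectrum")
  bands <- config@gpBandsNm
  rng <- range(spectrum@wavelength)
  if (bands[1] < rng[1] || bands[2] > rng[2])
    stop(sprintf("spectrum [%g, %g] nm does not cover both bands %g and %g",
                 rng[1], rng[2], bands[1], bands[2]))
  readBand <- function(center) {
    if (config@bandMode == "point") return(valueAt(spectrum, center))
    w <- config@bandWindowNm
    sel <- spectrum@wavelength >= center - w & spectrum@wavelength <= center + w
    if (!any(sel)) stop("no grid points within the band window at ", center)
    max(spectrum@values[sel])
  }
  i440 <- readBand(bands[1])
  i490 <- readBand(bands[2])
  new("GPResult", i440 = i440, i490 = i490, gp = laurdanGP(i440, i490))
}

#' Percent lipid mixing (or leakage) from the assay fluorescence levels
#'
#' 0% is the initial residual fluorescence `f0`; 100% is the post-Triton
#' fluorescence `f100`. Values outside \[0, 100\] are returned unclamped
#' (with an `outOfRange` attribute) because dequenching artifacts are
#' diagnostic.
#'
#' @param f measured fluorescence (a.u.).
#' @param f0 zero-level fluorescence.
#' @param f100 complete-mixing fluorescence.
#' @return percent value(s); attribute `outOfRange` marks entries outside
#'   \[0, 100\].
#' @examples
#' mixingPercent(35, f0 = 10, f100 = 110)  # 25
#' @export
mixingPercent <- function(f, f0, f100) {
  if (f100 == f0)
    stop("degenerate scale: f100 must differ from f0")
  p <- 100 * (f - f0) / (f100 - f0)
  oor <- p < 0 | p > 100
  if (any(oor)) attr(p, "outOfRange") <- oor
  p
}

#' Normalize a P/L titration into a mixing (or leakage) curve
#'
#' Applies [mixingPercent()] point-wise. For the inner-monolayer assay the
#' supplied `f0`/`f100` must come from the dithionite-treated vesicle
#' population; the same 0-100 normalization serves the ANTS/DPX leakage
#' assay.
#'
#' @param series a [TitrationSeries-class] with `xKind`
#'   `"peptide_lipid_ratio"`.
#' @param f0,f100 assay fluorescence levels, see [mixingPercent()].
#' @param assay `"total"`, `"inner_monolayer"` or `"leakage"`.
#' @return a [MixingResult-class].
#' @export
mixingCurve <- function(series, f0, f100,
                        assay = c("total", "inner_monolayer", "leakage")) {
  assay <- match.arg(assay)
  stopifnot(is(series, "TitrationSeries"))
  if (series@xKind != "peptide_lipid_ratio")
    stop("mixing curves require a peptide_lipid_ratio series")
  p <- mixingPercent(series@y, f0, f100)
  oor <- attr(p, "outOfRange")
  if (is.null(oor)) oor <- rep(FALSE, length(p))
  curve <- data.frame(p_over_l = series@x, percent = as.numeric(p),
                      flagged = oor)
  new("MixingResult", f0 = f0, f100 = f100, curve = curve, assay = assay)
}

#' Plateau and saturation P/L of a mixing curve
#'
#' Fits a monotone saturating Hill curve
#' `percent = P x^h / (x^h + K^h)` to the normalized curve and reports the
#' plateau `P` and the saturation P/L, defined as the smallest ratio at
#' which the fitted curve reaches `saturationFraction` (default 95%) of the
#' plateau: `x_sat = K ((s/(1-s))^(1/h))`. A curve that never rises above
#' 2 percent in absolute value is reported as flat (plateau 0, saturation
#' NA) rather than fitted.
#'
#' @param result a [MixingResult-class] (or the equivalent data.frame with
#'   columns `p_over_l`, `percent`).
#' @param hillStart starting Hill exponent for the fit.
#' @param config an [AnalysisConfig-class]; `saturationFraction` is used.
#' @return list with `plateau`, `saturationPL`, `k`, `hill`, `fit` (the
#'   `nls` object or NULL for a flat curve).
#' @export
fitSaturation <- function(result, hillStart = 2,
                          config = AnalysisConfig()) {
  curve <- if (is(result, "MixingResult")) result@curve else result
  x <- curve$p_over_l
  y <- curve$percent
  if (length(x) < 3) stop("insufficient data: need >= 3 curve points")
  if (max(abs(y)) < 2)
    return(list(plateau = 0, saturationPL = NA_real_, k = NA_real_,
                hill = NA_real_, fit = NULL))
  xhalf <- x[which.min(abs(y - max(y) / 2))]
  fit <- minpack.lm::nlsLM(
    y ~ P * x^h / (x^h + K^h),
    start = list(P = max(y), K = max(xhalf, min(x[x > 0])), h = hillStart),
    lower = c(P = 0, K = 1e-12, h = 0.2), upper = c(Inf, Inf, 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  s <- config@saturationFraction
  sat <- unname(cf["K"] * (s / (1 - s))^(1 / cf["h"]))
  list(plateau = unname(cf["P"]), saturationPL = sat,
       k = unname(cf["K"]), hill = unname(cf["h"]), fit = fit)
}
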