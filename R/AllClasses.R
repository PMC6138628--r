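#' @import methods
NULL

#' Spectrum: a wavelength-indexed trace
#'
#' Container for a single emission or circular-dichroism trace sampled on a
#' strictly increasing wavelength grid. Emission values are fluorescence
#' intensities (a.u.); CD values are observed ellipticities in millidegrees.
#'
#' @slot wavelength numeric, strictly increasing wavelengths in nm.
#' @slot values numeric, same length as `wavelength`.
#' @slot kind `"emission"` or `"cd"`.
#' @slot meta list of acquisition metadata (`excitation_nm`, `temperature_C`,
#'   `label`). Temperature is carried as metadata only; it never enters a
#'   computation.
#'
#' @seealso [Spectrum()], [valueAt()], [loadSpectrum()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    wavelength = "numeric",
    values = "numeric",
    kind = "character",
    meta = "list"
  ),
  prototype(kind = "emission", meta = list())
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@values))
    msg <- c(msg, "wavelength and values must have the same length")
  if (length(object@wavelength) >= 2 &&
      any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!object@kind %in% c("emission", "cd"))
    msg <- c(msg, "kind must be 'emission' or 'cd'")
  if (anyNA(object@wavelength) || anyNA(object@values))
    msg <- c(msg, "wavelengths and values must be finite")
  if (length(msg)) msg else TRUE
})

#' TitrationSeries: an independent variable paired with fluorescence
#'
#' One titration: lipid concentration (M), quencher concentration (M) or
#' peptide-to-lipid mole ratio against the measured fluorescence response.
#'
#' @slot x numeric, non-negative, sorted ascending.
#' @slot y numeric fluorescence (a.u.), same length as `x`.
#' @slot xKind one of `"lipid_conc"`, `"quencher_conc"`,
#'   `"peptide_lipid_ratio"`.
#' @slot replicates logical; `TRUE` permits duplicated `x` values.
#' @slot label character label.
#'
#' @seealso [TitrationSeries()]
#' @exportClass TitrationSeries
setClass("TitrationSeries",
  representation(
    x = "numeric",
    y = "numeric",
    xKind = "character",
    replicates = "logical",
    label = "character"
  ),
  prototype(replicates = FALSE, label = "")
)

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have the same length")
  if (any(object@x < 0))
    msg <- c(msg, "x must be non-negative")
  if (is.unsorted(object@x))
    msg <- c(msg, "x must be sorted ascending")
  if (!object@replicates && anyDuplicated(object@x))
    msg <- c(msg, "duplicate x values require replicates = TRUE")
  if (!object@xKind %in% c("lipid_conc", "quencher_conc",
                           "peptide_lipid_ratio"))
    msg <- c(msg, "unknown xKind")
  if (length(msg)) msg else TRUE
})

#' LipidComposition: mole-fraction recipe of a model membrane
#'
#' @slot components data.frame with columns `name` (character) and
#'   `mole_fraction` (numeric, non-negative, summing to one).
#' @slot label character label, e.g. `"BBB"`.
#'
#' @seealso [presetComposition()]
#' @exportClass LipidComposition
setClass("LipidComposition",
  representation(components = "data.frame", label = "character"))

setValidity("LipidComposition", function(object) {
  msg <- character()
  cmp <- object@components
  if (!all(c("name", "mole_fraction") %in% names(cmp)))
    msg <- c(msg, "components needs columns 'name' and 'mole_fraction'")
  else {
    if (any(cmp$mole_fraction < 0))
      msg <- c(msg, "mole fractions must be >= 0")
    if (abs(sum(cmp$mole_fraction) - 1) > 1e-9)
      msg <- c(msg, "mole fractions must sum to 1 within 1e-9")
  }
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: shared analysis settings
#'
#' Bundles the few tunables the assay analyses share. All defaults follow the
#' study conditions this package models: Laurdan band positions 440/490 nm,
#' outer-leaflet lipid fraction 0.6, initial-slope region at 30% of the
#' maximal free-peptide concentration, partition fits requiring at least 3
#' points (falling back to the 4 lowest-Cf points), saturation read at 95% of
#' the fitted plateau, and the literal MRE = Obsd/(l c n) convention.
#'
#' @slot gpBandsNm numeric(2), ordered/disordered Laurdan band positions (nm).
#' @slot bandMode `"point"` (interpolate at the band position, default) or
#'   `"window"` (maximum within `bandWindowNm` of the band position).
#' @slot bandWindowNm numeric half-width (nm) for `"window"` mode.
#' @slot outerLeafletFraction numeric in (0, 1]; lipid fraction accessible to
#'   peptide initially (outer leaflet), default 0.6.
#' @slot initialSlopeFraction numeric; isotherm points with
#'   Cf <= this fraction of max(Cf) form the initial-slope region.
#' @slot initialSlopeMinPoints integer; minimum points for a partition fit.
#' @slot initialSlopeFallbackPoints integer; if fewer qualify, take this many
#'   lowest-Cf points instead.
#' @slot saturationFraction numeric; a mixing curve is saturated at the
#'   smallest P/L reaching this fraction of the fitted plateau.
#' @slot thresholdMethod `"positive"` or `"otsu"` image threshold default.
#' @slot mreConvention `"paper"` (Obsd/(l c n)) or `"factor10"`
#'   (Obsd/(10 l c n)).
#' @slot maxQuencherM numeric; maximum admissible quencher concentration (M).
#' @slot seed integer random seed for downstream simulation helpers.
#'
#' @seealso [AnalysisConfig()], [readAnalysisConfig()]
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(
    gpBandsNm = "numeric",
    bandMode = "character",
    bandWindowNm = "numeric",
    outerLeafletFraction = "numeric",
    initialSlopeFraction = "numeric",
    initialSlopeMinPoints = "integer",
    initialSlopeFallbackPoints = "integer",
    saturationFraction = "numeric",
    thresholdMethod = "character",
    mreConvention = "character",
    maxQuencherM = "numeric",
    seed = "integer"
  ),
  prototype(
    gpBandsNm = c(440, 490),
    bandMode = "point",
    bandWindowNm = 5,
    outerLeafletFraction = 0.6,
    initialSlopeFraction = 0.3,
    initialSlopeMinPoints = 3L,
    initialSlopeFallbackPoints = 4L,
    saturationFraction = 0.95,
    thresholdMethod = "positive",
    mreConvention = "paper",
    maxQuencherM = 0.2,
    seed = 0L
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@outerLeafletFraction <= 0 || object@outerLeafletFraction > 1)
    msg <- c(msg, "outerLeafletFraction must be in (0, 1]")
  if (object@seed < 0)
    msg <- c(msg, "seed must be a non-negative integer")
  if (!object@bandMode %in% c("point", "window"))
    msg <- c(msg, "bandMode must be 'point' or 'window'")
  if (!object@mreConvention %in% c("paper", "factor10"))
    msg <- c(msg, "mreConvention must be 'paper' or 'factor10'")
  if (!object@thresholdMethod %in% c("positive", "otsu"))
    msg <- c(msg, "thresholdMethod must be 'positive' or 'otsu'")
  if (length(msg)) msg else TRUE
})

#' GPResult: Laurdan generalized polarization
#'
#' @slot i440 intensity at the ordered-phase band (a.u.).
#' @slot i490 intensity at the disordered-phase band (a.u.).
#' @slot gp generalized polarization (I440 - I490)/(I440 + I490), in [-1, 1].
#'
#' @seealso [gpFromSpectrum()], [laurdanGP()]
#' @exportClass GPResult
setClass("GPResult",
  representation(i440 = "numeric", i490 = "numeric", gp = "numeric"))

setValidity("GPResult", function(object) {
  msg <- character()
  if (object@gp < -1 - 1e-12 || object@gp > 1 + 1e-12)
    msg <- c(msg, "gp must lie in [-1, 1]")
  expect <- (object@i440 - object@i490) / (object@i440 + object@i490)
  if (abs(object@gp - expect) > 1e-12)
    msg <- c(msg, "gp must equal (i440 - i490)/(i440 + i490) to 1e-12")
  if (length(msg)) msg else TRUE
})

#' MixingResult: normalized lipid-mixing / leakage curve
#'
#' Percent values are not clamped: out-of-range percentages (dequenching
#' artifacts) are kept and flagged, because they are diagnostic.
#'
#' @slot f0 initial residual fluorescence (0% level).
#' @slot f100 post-Triton fluorescence (100% level).
#' @slot curve data.frame with columns `p_over_l`, `percent`, `flagged`.
#' @slot assay `"total"`, `"inner_monolayer"` or `"leakage"`.
#'
#' @seealso [mixingCurve()], [fitSaturation()]
#' @exportClass MixingResult
setClass("MixingResult",
  representation(f0 = "numeric", f100 = "numeric", curve = "data.frame",
                 assay = "character"))

setValidity("MixingResult", function(object) {
  msg <- character()
  if (object@f100 == object@f0)
    msg <- c(msg, "f100 must differ from f0")
  if (!object@assay %in% c("total", "inner_monolayer", "leakage"))
    msg <- c(msg, "unknown assay")
  if (!all(c("p_over_l", "percent") %in% names(object@curve)))
    msg <- c(msg, "curve needs columns 'p_over_l' and 'percent'")
  if (length(msg)) msg else TRUE
})

#' BindingIsotherm: bound peptide per accessible lipid vs free peptide
#'
#' Each row pairs the equilibrium free-peptide concentration `cf` (M) with
#' `xb_star`, the mole ratio of bound peptide per accessible (outer-leaflet)
#' lipid: X_b* = X_b / outer_fraction.
#'
#' @slot points data.frame with columns `lipid_total`, `f`, `fb`, `cf`, `xb`,
#'   `xb_star`, `clamped`.
#' @slot f0 fluorescence of the free peptide (a.u.).
#' @slot fInf fluorescence at complete binding (a.u.).
#' @slot peptideTotal total peptide concentration (M).
#' @slot outerFraction lipid fraction accessible to the peptide, in (0, 1].
#'
#' @seealso [buildIsotherm()], [partitionCoefficient()]
#' @exportClass BindingIsotherm
setClass("BindingIsotherm",
  representation(points = "data.frame", f0 = "numeric", fInf = "numeric",
                 peptideTotal = "numeric", outerFraction = "numeric"))

setValidity("BindingIsotherm", function(object) {
  msg <- character()
  pts <- object@points
  need <- c("cf", "xb_star")
  if (!all(need %in% names(pts)))
    msg <- c(msg, "points needs columns 'cf' and 'xb_star'")
  else {
    if (any(pts$cf < 0)) msg <- c(msg, "all cf must be >= 0")
    if (any(pts$xb_star < 0)) msg <- c(msg, "all xb_star must be >= 0")
  }
  if (object@fInf == object@f0) msg <- c(msg, "fInf must differ from f0")
  if (object@outerFraction <= 0 || object@outerFraction > 1)
    msg <- c(msg, "outerFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' PartitionFit: surface partition coefficient from the initial slope
#'
#' @slot kp apparent partition coefficient (M^-1); slope at the origin of
#'   X_b* vs C_f.
#' @slot nPointsUsed number of initial-region points entering the fit.
#' @slot slopeSE standard error of the constrained slope.
#' @slot r2 coefficient of determination of the origin-constrained fit.
#'
#' @seealso [partitionCoefficient()]
#' @exportClass PartitionFit
setClass("PartitionFit",
  representation(kp = "numeric", nPointsUsed = "integer",
                 slopeSE = "numeric", r2 = "numeric"))

setValidity("PartitionFit", function(object) {
  if (object@kp <= 0) "kp must be > 0 for a successful fit" else TRUE
})

#' SternVolmerFit: acrylamide quenching constant
#'
#' The primary estimate constrains the Stern-Volmer intercept to its
#' theoretical value 1; the free-intercept refit is kept as a diagnostic.
#'
#' @slot ksv Stern-Volmer constant (M^-1), origin-constrained fit of
#'   (F0/F - 1) vs quencher concentration.
#' @slot intercept intercept of the free-intercept diagnostic fit of F0/F.
#' @slot r2 coefficient of determination of the constrained fit.
#'
#' @seealso [sternVolmerFit()]
#' @exportClass SternVolmerFit
setClass("SternVolmerFit",
  representation(ksv = "numeric", intercept = "numeric", r2 = "numeric"))

#' HelixEstimate: CD-derived helix content and association state
#'
#' @slot mre222 mean residue ellipticity at 222 nm (deg cm^2 dmol^-1 res^-1).
#' @slot mre208 mean residue ellipticity at 208 nm.
#' @slot helixFraction helix fraction in [0, 1] (clamped when the raw value
#'   overshoots; see `clamped`).
#' @slot ratio222_208 theta222/theta208 on MRE values.
#' @slot state `"monomeric"` (< 0.8), `"oligomeric"` (> 1.0) or
#'   `"indeterminate"` ([0.8, 1.0]).
#' @slot clamped logical; TRUE if the raw fraction fell outside [0, 1].
#' @slot convention MRE convention used (`"paper"` or `"factor10"`).
#'
#' @seealso [analyzeCD()], [helixFraction()], [oligomerState()]
#' @exportClass HelixEstimate
setClass("HelixEstimate",
  representation(mre222 = "numeric", mre208 = "numeric",
                 helixFraction = "numeric", ratio222_208 = "numeric",
                 state = "character", clamped = "logical",
                 convention = "character"))

setValidity("HelixEstimate", function(object) {
  msg <- character()
  if (object@helixFraction < 0 || object@helixFraction > 1)
    msg <- c(msg, "helixFraction must be clamped to [0, 1]")
  if (!object@state %in% c("monomeric", "oligomeric", "indeterminate"))
    msg <- c(msg, "unknown state")
  if (length(msg)) msg else TRUE
})

#' VesselImage: micrograph with a blood-vessel mask
#'
#' Pixel grid is row-major `(row, col)`; masks are boolean matrices of the
#' same shape (the hand-drawn ROI outlines of the original workflow are
#' abstracted as caller-supplied masks).
#'
#' @slot pixels numeric matrix of non-negative intensities (a.u.).
#' @slot vesselMask logical matrix, same shape; TRUE inside vessels.
#' @slot pixelAreaUm2 area of one pixel in um^2 (> 0).
#' @slot label character label.
#'
#' @seealso [VesselImage()], [insideOutsideSplit()]
#' @exportClass VesselImage
setClass("VesselImage",
  representation(pixels = "matrix", vesselMask = "matrix",
                 pixelAreaUm2 = "numeric", label = "character"),
  prototype(label = ""))

setValidity("VesselImage", function(object) {
  msg <- character()
  if (!identical(dim(object@pixels), dim(object@vesselMask)))
    msg <- c(msg, "pixels and vesselMask must have the same shape")
  if (!is.logical(object@vesselMask))
    msg <- c(msg, "vesselMask must be logical")
  if (any(object@pixels < 0))
    msg <- c(msg, "pixel intensities must be non-negative")
  if (object@pixelAreaUm2 <= 0)
    msg <- c(msg, "pixelAreaUm2 must be > 0")
  if (length(msg)) msg else TRUE
})

#' IntegratedDensity: mean fluorescence times ROI area
#'
#' @slot meanFluorescence mean pixel intensity over the ROI (a.u.).
#' @slot areaUm2 ROI area in um^2.
#' @slot integratedDensity product of the two.
#'
#' @seealso [integratedDensity()]
#' @exportClass IntegratedDensity
setClass("IntegratedDensity",
  representation(meanFluorescence = "numeric", areaUm2 = "numeric",
                 integratedDensity = "numeric"))

setValidity("IntegratedDensity", function(object) {
  expect <- object@meanFluorescence * object@areaUm2
  tol <- 1e-9 * max(1, abs(expect))
  if (abs(object@integratedDensity - expect) > tol)
    "integratedDensity must equal meanFluorescence * areaUm2 (1e-9 relative)"
  else TRUE
})

#' CalibrationCurve: amount-to-integrated-density calibration
#'
#' Either a straight line or the four-parameter logistic ("Rodbard")
#' y = d + (a - d) / (1 + (x/c)^b).
#'
#' @slot amounts calibration amounts (uM or ug, caller's units).
#' @slot densities matching integrated densities.
#' @slot slope,intercept linear-model coefficients (NA for rodbard).
#' @slot r2 coefficient of determination of the fitted model.
#' @slot model `"linear"` or `"rodbard"`.
#' @slot coef named numeric of 4PL parameters a, b, c, d (length 0 for
#'   linear).
#'
#' @seealso [fitCalibration()], [percentDelivered()]
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(amounts = "numeric", densities = "numeric",
                 slope = "numeric", intercept = "numeric", r2 = "numeric",
                 model = "character", coef = "numeric"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (!object@model %in% c("linear", "rodbard"))
    msg <- c(msg, "model must be 'linear' or 'rodbard'")
  if (!is.na(object@r2) && (object@r2 < -1e-9 || object@r2 > 1 + 1e-9))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
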