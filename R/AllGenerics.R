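#' Interpolated value of a spectrum at a wavelength
#'
#' Linear interpolation between the bracketing grid points; an exact grid
#' point returns the stored value unchanged.
#'
#' @param x a [Spectrum-class].
#' @param wavelengthNm query wavelength(s) in nm, inside the spectral range.
#' @return numeric value(s) at `wavelengthNm`.
#' @examples
#' s <- Spectrum(c(440, 442), c(100, 120))
#' valueAt(s, 441)  # 110
#' @export
setGeneric("valueAt", function(x, wavelengthNm) standardGeneric("valueAt"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))

#' @rdname accessors
#' @export
setGeneric("xValues", function(x) standardGeneric("xValues"))

#' @rdname accessors
#' @export
setGeneric("yValues", function(x) standardGeneric("yValues"))

#' @rdname accessors
#' @export
setGeneric("xKind", function(x) standardGeneric("xKind"))

#' @rdname accessors
#' @export
setGeneric("gp", function(x) standardGeneric("gp"))

#' @rdname accessors
#' @export
setGeneric("kp", function(x) standardGeneric("kp"))

#' @rdname accessors
#' @export
setGeneric("ksv", function(x) standardGeneric("ksv"))

#' @rdname accessors
#' @export
setGeneric("helixFractionOf", function(x) standardGeneric("helixFractionOf"))

#' @rdname accessors
#' @export
setGeneric("oligomerStateOf", function(x) standardGeneric("oligomerStateOf"))

#' @rdname accessors
#' @export
setGeneric("mixingPercents", function(x) standardGeneric("mixingPercents"))

#' @rdname accessors
#' @export
setGeneric("idValue", function(x) standardGeneric("idValue"))

#' Accessors for pepmem result and data classes
#'
#' Small read-only accessors: `wavelengths()`, `intensity()` and
#' `spectrumKind()` for [Spectrum-class]; `xValues()`, `yValues()` and
#' `xKind()` for [TitrationSeries-class]; `gp()` for [GPResult-class];
#' `kp()` for [PartitionFit-class]; `ksv()` for [SternVolmerFit-class];
#' `helixFractionOf()` and `oligomerStateOf()` for [HelixEstimate-class];
#' `mixingPercents()` for [MixingResult-class]; `idValue()` for
#' [IntegratedDensity-class].
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)
#' @rdname accessors
setMethod("intensity", "Spectrum", function(x) x@values)
#' @rdname accessors
setMethod("spectrumKind", "Spectrum", function(x) x@kind)
#' @rdname accessors
setMethod("xValues", "TitrationSeries", function(x) x@x)
#' @rdname accessors
setMethod("yValues", "TitrationSeries", function(x) x@y)
#' @rdname accessors
setMethod("xKind", "TitrationSeries", function(x) x@xKind)
#' @rdname accessors
setMethod("gp", "GPResult", function(x) x@gp)
#' @rdname accessors
setMethod("kp", "PartitionFit", function(x) x@kp)
#' @rdname accessors
setMethod("ksv", "SternVolmerFit", function(x) x@ksv)
#' @rdname accessors
setMethod("helixFractionOf", "HelixEstimate", function(x) x@helixFraction)
#' @rdname accessors
setMethod("oligomerStateOf", "HelixEstimate", function(x) x@state)
#' @rdname accessors
setMethod("mixingPercents", "MixingResult", function(x) x@curve$percent)
#' @rdname accessors
setMethod("idValue", "IntegratedDensity", function(x) x@integratedDensity)

setMethod("show", "Spectrum", function(object) {
  rng <- range(object@wavelength)
  cat(sprintf("Spectrum (%s): %d points, %g-%g nm\n",
              object@kind, length(object@wavelength), rng[1], rng[2]))
  if (!is.null(object@meta$label) && nzchar(object@meta$label))
    cat("  label:", object@meta$label, "\n")
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries (%s): %d points, x in [%g, %g]\n",
              object@xKind, length(object@x),
              min(object@x), max(object@x)))
})

setMethod("show", "LipidComposition", function(object) {
  cat(sprintf("LipidComposition '%s': %d components\n", object@label,
              nrow(object@components)))
  cat(paste0("  ", object@components$name, " = ",
             format(object@components$mole_fraction), collapse = "\n"), "\n")
})

setMethod("show", "GPResult", function(object) {
  cat(sprintf("GP = %.4f (I440 = %.4g, I490 = %.4g)\n",
              object@gp, object@i440, object@i490))
})

setMethod("show", "MixingResult", function(object) {
  cat(sprintf("MixingResult (%s): %d points, F0 = %g, F100 = %g\n",
              object@assay, nrow(object@curve), object@f0, object@f100))
})

setMethod("show", "BindingIsotherm", function(object) {
  cat(sprintf(
    "BindingIsotherm: %d points, peptide %.3g M, outer fraction %.2f\n",
    nrow(object@points), object@peptideTotal, object@outerFraction))
})

setMethod("show", "PartitionFit", function(object) {
  cat(sprintf("PartitionFit: Kp = %.4g M^-1 (%d points, SE %.2g, R2 %.4f)\n",
              object@kp, object@nPointsUsed, object@slopeSE, object@r2))
})

setMethod("show", "SternVolmerFit", function(object) {
  cat(sprintf(
    "SternVolmerFit: Ksv = %.4g M^-1 (free intercept %.4f, R2 %.4f)\n",
    object@ksv, object@intercept, object@r2))
})

setMethod("show", "HelixEstimate", function(object) {
  cat(sprintf(
    "HelixEstimate: fH = %.3f%s, theta222/theta208 = %.3f -> %s (%s MRE)\n",
    object@helixFraction, if (object@clamped) " (clamped)" else "",
    object@ratio222_208, object@state, object@convention))
})

setMethod("show", "VesselImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "VesselImage '%s': %d x %d px, %.3g um^2/px, %d vessel px\n",
    object@label, d[1], d[2], object@pixelAreaUm2, sum(object@vesselMask)))
})

setMethod("show", "IntegratedDensity", function(object) {
  cat(sprintf("IntegratedDensity: mean %.4g x area %.4g um^2 = %.6g\n",
              object@meanFluorescence, object@areaUm2,
              object@integratedDensity))
})

setMethod("show", "CalibrationCurve", function(object) {
  if (object@model == "linear")
    cat(sprintf(
      "CalibrationCurve (linear): slope %.4g, intercept %.4g, R2 %.5f\n",
      object@slope, object@intercept, object@r2))
  else
    cat(sprintf(
      "CalibrationCurve (rodbard): a=%.4g b=%.4g c=%.4g d=%.4g, R2 %.5f\n",
      object@coef["a"], object@coef["b"], object@coef["c"],
      object@coef["d"], object@r2))
})
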