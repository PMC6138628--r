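# Inside/outside-vessel quantification of fluorescence micrographs.
# Integrated density = mean fluorescence x ROI area (um^2); the vessel mask
# defines the inbound ROI, its complement (restricted to above-threshold
# pixels, excluding background) the outbound ROI.

#' Construct a VesselImage
#'
#' @param pixels numeric matrix of non-negative pixel intensities (a.u.),
#'   row-major `(row, col)`.
#' @param vesselMask logical matrix of the same shape, TRUE inside vessels.
#' @param pixelAreaUm2 pixel area in um^2 (> 0).
#' @param label optional label.
#' @return a [VesselImage-class].
#' @export
VesselImage <- function(pixels, vesselMask, pixelAreaUm2 = 1, label = "") {
  storage.mode(pixels) <- "double"
  new("VesselImage", pixels = pixels, vesselMask = vesselMask,
      pixelAreaUm2 = pixelAreaUm2, label = label)
}

#' Foreground mask of a micrograph
#'
#' `"positive"` (default): pixels strictly above the background floor,
#' taken as the image mode (the most frequent intensity, the background
#' level in a fluorescence micrograph) — for an image whose most frequent
#' value is 0 this is simply the non-zero pixels. `"otsu"`: pixels above
#' the Otsu threshold computed on the intensity histogram.
#'
#' @param image a [VesselImage-class].
#' @param method `"positive"` or `"otsu"`.
#' @return logical matrix; all-FALSE (with a warning) for an all-background
#'   image.
#' @export
thresholdNonzero <- function(image, method = c("positive", "otsu")) {
  method <- match.arg(method)
  stopifnot(is(image, "VesselImage"))
  px <- image@pixels
  if (diff(range(px)) == 0) {
    warning("image has no contrast; returning an empty mask")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  thr <- if (method == "positive") .imageMode(px) else {
    mx <- max(px)
    EBImage::otsu(px / mx) * mx
  }
  mask <- px > thr
  if (!any(mask)) warning("empty foreground mask")
  mask
}

# Background floor: most frequent intensity (binned histogram mode).
.imageMode <- function(px) {
  v <- as.vector(px)
  if (length(unique(v)) <= 256) {
    tab <- table(v)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  h <- graphics::hist(v, breaks = 256, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Integrated density over a region of interest
#'
#' Mean pixel intensity over the ROI multiplied by the ROI area
#' (pixel count x pixel area), i.e. `sum(pixels in ROI) * pixelAreaUm2` —
#' exactly additive over disjoint ROIs.
#'
#' @param image a [VesselImage-class].
#' @param roi logical matrix, same shape as the image, with at least one
#'   TRUE pixel.
#' @return an [IntegratedDensity-class].
#' @export
integratedDensity <- function(image, roi) {
  stopifnot(is(image, "VesselImage"))
  if (!identical(dim(roi), dim(image@pixels)))
    stop("roi must have the same shape as the image")
  n <- sum(roi)
  if (n == 0) stop("degenerate ROI: no pixels selected")
  m <- mean(image@pixels[roi])
  area <- n * image@pixelAreaUm2
  new("IntegratedDensity", meanFluorescence = m, areaUm2 = area,
      integratedDensity = m * area)
}

#' Inbound / outbound integrated densities of a vessel image
#'
#' Inside (inbound): integrated density over the vessel mask. Outside
#' (outbound): integrated density over the above-threshold pixels that are
#' not vessel, i.e. thresholded so as to exclude both the vessels and the
#' background.
#'
#' @param image a [VesselImage-class] with a non-empty, non-full vessel
#'   mask.
#' @param thresholdMethod passed to [thresholdNonzero()].
#' @return list with elements `inside` and `outside`, both
#'   [IntegratedDensity-class] (outside has zero mean over an all-background
#'   complement).
#' @export
insideOutsideSplit <- function(image,
                               thresholdMethod = c("positive", "otsu")) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(is(image, "VesselImage"))
  vm <- image@vesselMask
  if (!any(vm)) stop("degenerate split: vessel mask is empty")
  if (all(vm)) stop("degenerate split: vessel mask covers the whole frame")
  inside <- integratedDensity(image, vm)
  fg <- suppressWarnings(thresholdNonzero(image, thresholdMethod))
  out <- fg & !vm
  outside <- if (any(out)) integratedDensity(image, out)
    else new("IntegratedDensity", meanFluorescence = 0,
             areaUm2 = 0, integratedDensity = 0)
  list(inside = inside, outside = outside)
}

#' Fit an amount-to-integrated-density calibration curve
#'
#' `"linear"`: least-squares straight line. `"rodbard"`: the ImageJ-style
#' four-parameter logistic `y = d + (a - d)/(1 + (x/c)^b)`, fitted by
#' Levenberg-Marquardt with starts a = y at the smallest amount, d = y at
#' the largest, c = median amount, b = 1. `"auto"` fits the line first and
#' keeps it when its R^2 >= 0.99, otherwise refits with the 4PL.
#'
#' @param amounts calibration amounts (>= 3 points for linear, >= 5 for
#'   rodbard), not all equal.
#' @param densities matching integrated densities.
#' @param model `"linear"`, `"rodbard"` or `"auto"`.
#' @return a [CalibrationCurve-class].
#' @export
fitCalibration <- function(amounts, densities,
                           model = c("linear", "rodbard", "auto")) {
  model <- match.arg(model)
  if (length(amounts) != length(densities))
    stop("amounts and densities must have the same length")
  if (diff(range(amounts)) == 0)
    stop("input error: degenerate amounts (all equal)")
  r2of <- function(pred) {
    sse <- sum((densities - pred)^2)
    sst <- sum((densities - mean(densities))^2)
    if (sst == 0) 1 else max(0, min(1, 1 - sse / sst))
  }
  fitLinear <- function() {
    if (length(amounts) < 3)
      stop("insufficient data: linear calibration needs >= 3 points")
    fit <- stats::lm(densities ~ amounts)
    co <- stats::coef(fit)
    new("CalibrationCurve", amounts = amounts, densities = densities,
        slope = unname(co[2]), intercept = unname(co[1]),
        r2 = r2of(stats::fitted(fit)), model = "linear",
        coef = numeric(0))
  }
  fitRodbard <- function() {
    if (length(amounts) < 5)
      stop("insufficient data: rodbard calibration needs >= 5 points")
    x <- amounts; y <- densities
    st <- list(a = y[which.min(x)], b = 1, c = max(stats::median(x), 1e-9),
               d = y[which.max(x)])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b), start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e)
        stop("rodbard fit failure: ", conditionMessage(e),
             " (starts: ", paste(names(st), unlist(st), sep = "=",
                                 collapse = ", "), ")"))
    co <- stats::coef(fit)
    new("CalibrationCurve", amounts = amounts, densities = densities,
        slope = NA_real_, intercept = NA_real_,
        r2 = r2of(stats::fitted(fit)), model = "rodbard",
        coef = co[c("a", "b", "c", "d")])
  }
  switch(model,
    linear = fitLinear(),
    rodbard = fitRodbard(),
    auto = {
      lin <- fitLinear()
      if (lin@r2 >= 0.99) lin else fitRodbard()
    })
}

#' Predicted integrated density at a given amount
#'
#' @param calibration a [CalibrationCurve-class].
#' @param amount amount(s) in the calibration's units.
#' @return predicted density value(s).
#' @export
predictDensity <- function(calibration, amount) {
  stopifnot(is(calibration, "CalibrationCurve"))
  if (calibration@model == "linear")
    calibration@intercept + calibration@slope * amount
  else {
    p <- calibration@coef
    p["d"] + (p["a"] - p["d"]) / (1 + (amount / p["c"])^p["b"])
  }
}

#' Percent of the administered amount that was delivered
#'
#' Inverts the calibration at the measured integrated density to read off
#' the delivered amount, then reports `100 * delivered / administered`.
#'
#' @param density an [IntegratedDensity-class] (or a bare density value).
#' @param calibration a [CalibrationCurve-class]; a linear calibration needs
#'   a non-zero slope, a rodbard calibration is only invertible strictly
#'   between its d and a asymptotes.
#' @param administeredAmount administered amount (> 0), same units as the
#'   calibration.
#' @return percent delivered (numeric).
#' @export
percentDelivered <- function(density, calibration, administeredAmount) {
  if (is(density, "IntegratedDensity")) density <- density@integratedDensity
  if (administeredAmount <= 0)
    stop("input error: administeredAmount must be > 0")
  stopifnot(is(calibration, "CalibrationCurve"))
  amount <- if (calibration@model == "linear") {
    if (calibration@slope == 0)
      stop("calibration slope is zero; cannot invert")
    (density - calibration@intercept) / calibration@slope
  } else {
    p <- calibration@coef
    lo <- min(p["a"], p["d"]); hi <- max(p["a"], p["d"])
    if (density <= lo || density >= hi)
      stop(sprintf(
        "range error: density %g outside the invertible range (%g, %g)",
        density, lo, hi))
    unname(p["c"] * ((p["a"] - p["d"]) / (density - p["d"]) - 1)^(1 / p["b"]))
  }
  100 * amount / administeredAmount
}
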