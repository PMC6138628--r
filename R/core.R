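# Shared constructors, tabular I/O and the lipid-composition presets.
# Units are normalized at the boundary: wavelengths nm, concentrations M,
# P/L ratios dimensionless mol/mol.

#' Construct a Spectrum
#'
#' Points are sorted by wavelength; negative emission intensities are legal
#' (baseline-corrected traces dip below zero) but produce a warning.
#'
#' @param wavelengthsNm numeric wavelengths in nm.
#' @param values numeric trace values (a.u. for emission, mdeg for CD).
#' @param kind `"emission"` or `"cd"`.
#' @param excitationNm optional excitation wavelength (metadata).
#' @param temperatureC optional temperature in Celsius (metadata only).
#' @param label optional character label.
#' @return a [Spectrum-class].
#' @examples
#' Spectrum(c(400, 450, 500), c(10, 50, 20))
#' @export
Spectrum <- function(wavelengthsNm, values, kind = c("emission", "cd"),
                     excitationNm = NA_real_, temperatureC = NA_real_,
                     label = "") {
  kind <- match.arg(kind)
  wavelengthsNm <- as.numeric(wavelengthsNm)
  values <- as.numeric(values)
  ord <- order(wavelengthsNm)
  wavelengthsNm <- wavelengthsNm[ord]
  values <- values[ord]
  if (kind == "emission" && any(values < 0))
    warning("negative emission intensities present; flagging but keeping them")
  new("Spectrum", wavelength = wavelengthsNm, values = values, kind = kind,
      meta = list(excitation_nm = excitationNm, temperature_C = temperatureC,
                  label = label))
}

#' Construct a TitrationSeries
#'
#' @param x independent variable (M lipid, M quencher, or mol/mol P/L),
#'   non-negative; the series is sorted by `x`.
#' @param y fluorescence responses (a.u.).
#' @param xKind `"lipid_conc"`, `"quencher_conc"` or `"peptide_lipid_ratio"`.
#' @param replicates set TRUE to allow duplicated `x`.
#' @param label optional label.
#' @param xUnit unit of the supplied `x`: `"M"` (default), `"mM"` or `"uM"`
#'   for concentrations; ignored for P/L ratios. Values are normalized to M.
#' @return a [TitrationSeries-class].
#' @export
TitrationSeries <- function(x, y,
                            xKind = c("lipid_conc", "quencher_conc",
                                      "peptide_lipid_ratio"),
                            replicates = FALSE, label = "", xUnit = "M") {
  xKind <- match.arg(xKind)
  x <- as.numeric(x)
  if (xKind != "peptide_lipid_ratio") {
    scale <- switch(xUnit, M = 1, mM = 1e-3, uM = 1e-6,
                    stop("unknown xUnit '", xUnit, "' (use M, mM or uM)"))
    x <- x * scale
  }
  ord <- order(x)
  new("TitrationSeries", x = x[ord], y = as.numeric(y)[ord], xKind = xKind,
      replicates = replicates, label = label)
}

#' Construct an AnalysisConfig
#'
#' @param ... named settings overriding the defaults; see
#'   [AnalysisConfig-class] for the slots and their defaults.
#' @return an [AnalysisConfig-class].
#' @examples
#' AnalysisConfig(outerLeafletFraction = 1)
#' @export
AnalysisConfig <- function(...) {
  args <- list(...)
  for (nm in c("initialSlopeMinPoints", "initialSlopeFallbackPoints", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("AnalysisConfig"), args))
}

#' Read an AnalysisConfig from a flat key-value file
#'
#' Each non-empty, non-comment line is `key = value`; keys are the
#' [AnalysisConfig-class] slot names. Unknown keys are an error.
#'
#' @param path path to the config file.
#' @return an [AnalysisConfig-class].
#' @export
readAnalysisConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(AnalysisConfig())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed config line: '", lines[which(bad)[1]], "'")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  slots <- slotNames("AnalysisConfig")
  unknown <- setdiff(keys, slots)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- suppressWarnings(as.numeric(strsplit(vals[i], ",")[[1]]))
    args[[keys[i]]] <- if (anyNA(v)) vals[i] else v
  }
  do.call(AnalysisConfig, args)
}

#' Load a two-column spectrum CSV
#'
#' Expects comma-separated `wavelength,value` rows with '.' decimals and an
#' optional single header row. Rows are re-sorted to ascending wavelength.
#'
#' @param path path to the CSV file.
#' @param kind `"emission"` or `"cd"`.
#' @param ... passed to [Spectrum()] (metadata).
#' @return a [Spectrum-class].
#' @export
loadSpectrum <- function(path, kind = c("emission", "cd"), ...) {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2)
    stop("spectrum CSV must have two columns (wavelength, value)")
  first <- suppressWarnings(as.numeric(unlist(raw[1, 1:2])))
  if (anyNA(first)) raw <- raw[-1, , drop = FALSE]  # header row
  if (nrow(raw) < 3)
    stop("insufficient data: a spectrum needs at least 3 points")
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  vals <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(wl) | is.na(vals))
  if (length(bad))
    stop("non-numeric value in row ", bad[1], " of ", path)
  Spectrum(wl, vals, kind = kind, ...)
}

#' Write a Spectrum to CSV
#'
#' Full-precision (17 significant digits) two-column CSV with a header, so
#' that `loadSpectrum(writeSpectrum(s, f))` round-trips exactly.
#'
#' @param spectrum a [Spectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  lines <- c("wavelength_nm,value",
             sprintf("%.17g,%.17g", spectrum@wavelength, spectrum@values))
  writeLines(lines, path)
  invisible(path)
}

#' Load a titration-series CSV
#'
#' Two numeric columns `x,y` with an optional header row.
#'
#' @param path path to the CSV file.
#' @param xKind,xUnit,... passed to [TitrationSeries()].
#' @return a [TitrationSeries-class].
#' @export
loadTitrationSeries <- function(path,
                                xKind = c("lipid_conc", "quencher_conc",
                                          "peptide_lipid_ratio"),
                                xUnit = "M", ...) {
  xKind <- match.arg(xKind)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  first <- suppressWarnings(as.numeric(unlist(raw[1, 1:2])))
  if (anyNA(first)) raw <- raw[-1, , drop = FALSE]
  x <- suppressWarnings(as.numeric(raw[[1]]))
  y <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("non-numeric value in row ", bad[1], " of ", path)
  TitrationSeries(x, y, xKind = xKind, xUnit = xUnit, ...)
}

# The two membrane-mimetic recipes (mole ratios given as x/100).
.presets <- list(
  BBB = data.frame(
    name = c("PI", "DOPE", "DPPC", "PS", "Chol", "SM"),
    mole_fraction = c(0.04, 0.23, 0.30, 0.08, 0.20, 0.15)),
  liver = data.frame(
    name = c("DSPC", "POPE", "PI", "PS", "lysoPC", "SM", "DOPG"),
    mole_fraction = c(0.37, 0.21, 0.07, 0.09, 0.03, 0.18, 0.05))
)

#' Preset lipid compositions of the model membranes
#'
#' `"BBB"` is the brain-endothelium mimic PI/DOPE/DPPC/PS/Chol/SM
#' (4/23/30/8/20/15 mole ratio): cholesterol- and sphingomyelin-rich, i.e.
#' raft-forming. `"liver"` is DSPC/POPE/PI/PS/lysoPC/SM/DOPG
#' (37/21/7/9/3/18/5).
#'
#' @param label `"BBB"` or `"liver"`.
#' @return a [LipidComposition-class].
#' @examples
#' presetComposition("BBB")
#' @export
presetComposition <- function(label) {
  if (!label %in% names(.presets))
    stop("unknown composition '", label, "'; valid labels: ",
         paste(names(.presets), collapse = ", "))
  new("LipidComposition", components = .presets[[label]], label = label)
}

#' @rdname valueAt
setMethod("valueAt", "Spectrum", function(x, wavelengthNm) {
  rng <- range(x@wavelength)
  if (any(wavelengthNm < rng[1] | wavelengthNm > rng[2]))
    stop(sprintf("wavelength %g nm outside spectral range [%g, %g]",
                 wavelengthNm[which(wavelengthNm < rng[1] |
                                    wavelengthNm > rng[2])[1]],
                 rng[1], rng[2]))
  stats::approx(x@wavelength, x@values, xout = wavelengthNm,
                method = "linear", ties = "ordered")$y
})
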