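# Circular dichroism: mean residue ellipticity, helix fraction from
# [theta]222 against the -40000(1 - 2.5/n) full-helix reference, and
# monomer/oligomer classification from theta222/theta208.

#' Mean residue ellipticity from an observed ellipticity
#'
#' The default (`"paper"`) convention is the literal `Obsd/(l c n)`; the
#' `"factor10"` convention divides by an additional factor of 10 (the common
#' deg cm^2 dmol^-1 normalization with c in mol/L and l in cm). The two
#' differ by exactly a factor of 10; every pipeline output records which
#' convention produced it, and generator and analyzer must share one.
#'
#' @param obsdMdeg observed ellipticity in millidegrees.
#' @param pathCm cuvette path length in cm (> 0).
#' @param concM peptide concentration in mol/L (> 0).
#' @param nRes number of amino-acid residues (>= 2).
#' @param convention `"paper"` or `"factor10"`.
#' @return mean residue ellipticity (deg cm^2 dmol^-1 per residue under
#'   `"factor10"`; the same up to the fixed factor under `"paper"`).
#' @examples
#' mre(-16, pathCm = 0.1, concM = 8e-6, nRes = 20)  # -1e6
#' @export
mre <- function(obsdMdeg, pathCm, concM, nRes,
                convention = c("paper", "factor10")) {
  convention <- match.arg(convention)
  if (pathCm <= 0 || concM <= 0)
    stop("input error: path length and concentration must be > 0")
  if (nRes < 2) stop("input error: nRes must be >= 2")
  denom <- pathCm * concM * nRes
  if (convention == "factor10") denom <- 10 * denom
  obsdMdeg / denom
}

#' Helix fraction from the mean residue ellipticity at 222 nm
#'
#' Uses reference values of 0 and `-40000 (1 - 2.5/n)` deg cm^2 dmol^-1 per
#' residue for 0% and 100% helicity; the chain-length correction makes the
#' full-helix reference -30000 at n = 10 and approach -40000 as n grows.
#' The raw ratio is clamped to \[0, 1\]; a `clamped` attribute records
#' whether clamping occurred (noisy spectra legitimately overshoot).
#'
#' @param mre222 mean residue ellipticity at 222 nm.
#' @param nRes number of residues (> 2, so the reference is negative).
#' @return helix fraction in \[0, 1\] with attribute `clamped`.
#' @examples
#' helixFraction(-20300, 20)  # 0.58
#' @export
helixFraction <- function(mre222, nRes) {
  if (nRes <= 2)
    stop("input error: nRes must exceed 2 for a negative helix reference")
  ref <- -40000 * (1 - 2.5 / nRes)
  raw <- mre222 / ref
  fh <- pmin(pmax(raw, 0), 1)
  attr(fh, "clamped") <- raw < 0 | raw > 1
  fh
}

#' Helix association state from the theta222/theta208 ratio
#'
#' Below 0.8 the helix is essentially monomeric; above 1.0 it is
#' oligomeric; the band \[0.8, 1.0\] (both boundaries included) is reported
#' as indeterminate.
#'
#' @param ratio222_208 ellipticity ratio theta222/theta208 (finite).
#' @return `"monomeric"`, `"oligomeric"` or `"indeterminate"`.
#' @examples
#' oligomerState(0.68)  # monomeric
#' @export
oligomerState <- function(ratio222_208) {
  if (!is.finite(ratio222_208))
    stop("input error: ratio must be finite")
  if (ratio222_208 < 0.8) "monomeric"
  else if (ratio222_208 > 1.0) "oligomeric"
  else "indeterminate"
}

#' Full CD analysis of a blank-corrected spectrum
#'
#' Converts the observed-ellipticity trace to mean residue ellipticity,
#' interpolates at exactly 222 and 208 nm, and derives the helix fraction
#' and the monomer/oligomer call. The ratio is computed on MRE values (the
#' l c n units cancel, so it equals the raw-ellipticity ratio).
#'
#' @param raw a blank-corrected CD [Spectrum-class] in millidegrees,
#'   covering 208 and 222 nm.
#' @param pathCm,concM,nRes,convention see [mre()].
#' @return a [HelixEstimate-class].
#' @export
analyzeCD <- function(raw, pathCm, concM, nRes,
                      convention = c("paper", "factor10")) {
  convention <- match.arg(convention)
  stopifnot(is(raw, "Spectrum"))
  if (raw@kind != "cd") stop("analyzeCD requires a CD spectrum")
  rng <- range(raw@wavelength)
  if (rng[1] > 208 || rng[2] < 222)
    stop(sprintf("spectrum [%g, %g] nm must cover 208 and 222 nm",
                 rng[1], rng[2]))
  m222 <- mre(valueAt(raw, 222), pathCm, concM, nRes, convention)
  m208 <- mre(valueAt(raw, 208), pathCm, concM, nRes, convention)
  fh <- helixFraction(m222, nRes)
  ratio <- m222 / m208
  new("HelixEstimate", mre222 = m222, mre208 = m208,
      helixFraction = as.numeric(fh), ratio222_208 = ratio,
      state = oligomerState(ratio), clamped = attr(fh, "clamped"),
      convention = convention)
}
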