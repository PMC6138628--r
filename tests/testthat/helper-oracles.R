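# Small fixture builders and independent closed-form oracles used across
# the suite. The oracles deliberately avoid the code paths they check.

# Gaussian emission spectrum on a dense grid.
gaussSpectrum <- function(center, sigma = 12, amplitude = 100,
                          wl = seq(300, 400, by = 0.2), kind = "emission") {
  Spectrum(wl, amplitude * exp(-(wl - center)^2 / (2 * sigma^2)),
           kind = kind)
}

# Origin-constrained least-squares slope, direct sum formula.
originSlopeOracle <- function(x, y) sum(x * y) / sum(x * x)

# Brute-force grid search for the limiting fluorescence of a hyperbolic
# saturation curve: for each candidate F_inf, the best double-reciprocal
# line with intercept fixed at 1/F_inf is scored by its residual sum of
# squares; the candidate with the smallest score wins.
bruteForceFInf <- function(lipid, f, outerFraction = 0.6,
                           candidates = seq(100, 600, by = 0.05)) {
  xv <- 1 / (outerFraction * lipid)
  yv <- 1 / f
  sse <- vapply(candidates, function(fi) {
    ic <- 1 / fi
    slope <- sum(xv * (yv - ic)) / sum(xv^2)
    sum((yv - ic - slope * xv)^2)
  }, numeric(1))
  candidates[which.min(sse)]
}
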