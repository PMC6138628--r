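---
title: "Models and methods behind pepmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmem)
```

`pepmem` quantifies how a membranotropic peptide interacts with model
lipid membranes. This vignette explains each model, its assumptions, the
tunable parameters, the synthetic-data generators used for validation,
and the numerical choices made where the design was genuinely open.

## Membrane fluidity: Laurdan generalized polarization

Laurdan partitions into bilayers and emits around 440 nm in ordered (gel)
phases and around 490 nm in disordered (liquid-crystalline) phases. The
generalized polarization

$$\mathrm{GP} = \frac{I_{440} - I_{490}}{I_{440} + I_{490}}$$

is bounded in $[-1, 1]$; higher values mean a more ordered, less fluid
bilayer. `gpFromSpectrum()` reads the two band intensities at exactly
440 and 490 nm by linear interpolation (`bandMode = "point"`, the
default). The alternative `"window"` mode takes the maximum within ±5 nm
of each band, for spectra whose band maxima drift; the point rule is the
default because the two canonical band positions are what defines GP.
Antisymmetry under swapping the bands, and the $[-1, 1]$ bounds, are
enforced by construction and checked by property tests.

## Vesicle fusion: FRET lipid mixing, inner monolayer, leakage

In the lipid-mixing assay, fusion of labelled with unlabelled vesicles
dilutes the NBD/rhodamine FRET pair and dequenches the donor. The raw
fluorescence $F$ is normalized as

$$\%\,\mathrm{mixing} = 100\,\frac{F - F_0}{F_{100} - F_0}$$

with $F_0$ the initial residual fluorescence and $F_{100}$ the
fluorescence after Triton X-100 solubilization. Percentages are **not
clamped**: values below 0 or above 100 are returned with a flag, because
dequenching artifacts are diagnostically useful. The identical
normalization serves the inner-monolayer assay (after dithionite
reduction of outer-leaflet NBD) and ANTS/DPX leakage. Whether the 100%
level should be re-measured after dithionite treatment is not fixed by
convention; `mixingCurve()` therefore requires caller-supplied
$F_0/F_{100}$ per assay, and both conventions are legitimate inputs.

`fitSaturation()` condenses a percent-vs-P/L curve into a plateau and a
saturation ratio by fitting the monotone Hill form
$P\,x^h/(x^h + K^h)$ (Levenberg–Marquardt, starts: $P$ at the maximal
percent, $K$ at the half-maximum abscissa, $h = 2$). The saturation P/L
is defined as the smallest ratio at which the fitted curve reaches 95% of
its plateau — a fitted, reproducible surrogate for the qualitative
"complete fusion" call. Curves that never exceed 2 percent in absolute
value (e.g. leakage-free conditions) are reported as flat rather than
fitted, since a Hill fit on pure noise is meaningless.

## Membrane partitioning: binding isotherm and K_p

Binding of the peptide (single tryptophan reporter) is modelled as a
surface partition equilibrium

$$X_b = K_p\,C_f,$$

where $X_b$ is the mole ratio of bound peptide per total lipid, $C_f$ the
free-peptide concentration, and $K_p$ (M⁻¹) the apparent partition
coefficient. Because the peptide initially sees only the outer leaflet
(60% of the lipid), the bound ratio is corrected to
$X_b^* = X_b / 0.6$; `outerLeafletFraction` is exposed in
`AnalysisConfig` with default 0.6 and applies to both vesicle classes.

The chain from fluorescence to isotherm is:
$f_b = (F - F_0)/(F_\infty - F_0)$, bound $= f_b P_\mathrm{tot}$,
$C_f = (1 - f_b) P_\mathrm{tot}$, $X_b = f_b P_\mathrm{tot}/L$,
$X_b^* = X_b/0.6$. With noisy data $f_b$ can fall slightly outside
$[0, 1]$; `buildIsotherm()` clamps it (recording which points were
clamped) so the isotherm invariants $C_f \ge 0$, $X_b^* \ge 0$ always
hold. Clamped points land at $C_f = 0$ and carry zero weight in the
origin-constrained fit, so the clamp cannot bias $K_p$.

$F_\infty$ (fluorescence at complete binding) comes from
`estimateFInf()`: ordinary least squares of $1/F$ against
$1/(0.6\,L)$, with $F_\infty = 1/\mathrm{intercept}$. The
double-reciprocal reading is ambiguous between total fluorescence and the
binding increment; the default is the literal $1/F$ variant and
`subtractF0 = TRUE` selects $1/(F - F_0)$, so the choice is explicit
rather than silent. A non-positive intercept is an extrapolation failure
and is reported as an error, never silently clamped.

$K_p$ is the **initial slope** of $X_b^*$ vs $C_f$: a least-squares line
through the origin over the points with
$C_f \le 0.3\,\max(C_f)$ (minimum 3 points; if fewer qualify, the 4
lowest-$C_f$ points are used). Restricting the fit to the initial region
makes $K_p$ insensitive to surface self-association, which only bends the
isotherm upward at higher $C_f$ — the package's tests verify ±5%
invariance of $K_p$ across association strengths spanning a factor of 25.
The 30% cut-off is a package choice (the initial-slope prescription fixes
no number); it balances bias from curvature against variance from too few
points.

## Tryptophan accessibility: Stern–Volmer quenching

Collisional quenching by aqueous acrylamide follows
$F_0/F = 1 + K_{sv}[Q]$. Since the theoretical intercept is exactly 1,
`sternVolmerFit()` fits $(F_0/F - 1)$ vs $[Q]$ **through the origin** and
reports the free-intercept refit only as a diagnostic (a free intercept
far from 1 flags scattering or inner-filter problems). Quencher
concentrations are capped at 0.2 M, the standard upper bound for
acrylamide titrations, and enforced at fit time. Lower $K_{sv}$ means a
more deeply buried tryptophan.

## Secondary structure: CD helicity and oligomer state

Mean residue ellipticity is computed as
$\mathrm{MRE} = \mathrm{Obsd}/(l\,c\,n)$ (`convention = "paper"`), with
`"factor10"` dividing by the additional conventional factor of 10. The
two conventions differ by exactly 10×; every result records which one
produced it, and generator and analyzer must share one (the helix
fraction is scale-consistent only then). The helix fraction uses
reference values of 0 and $-40000(1 - 2.5/n)$ deg cm² dmol⁻¹ res⁻¹ for
0% and 100% helicity ($-30000$ at $n = 10$, approaching $-40000$ as
$n \to \infty$), evaluated at 222 nm; fractions are clamped to $[0,1]$
with a flag because noisy spectra legitimately overshoot. The
$\theta_{222}/\theta_{208}$ ratio is computed on MRE values (units
cancel, so it equals the raw-ellipticity ratio) at exactly 222 and
208 nm by interpolation: below 0.8 the helix is classified monomeric,
above 1.0 oligomeric, and the closed band $[0.8, 1.0]$ — including both
boundary values — indeterminate. Full basis-set deconvolution
(CONTIN/SELCON-style) is out of scope.

## Imaging: integrated density and percent delivered

A micrograph is a non-negative pixel matrix with a boolean vessel mask
(hand-drawn ROIs abstracted as masks; segmentation is not this package's
job). Integrated density is mean fluorescence × ROI area (µm²), computed
as `sum(pixels) * pixelAreaUm2`, which makes it exactly additive over
disjoint ROIs. The inbound signal is the integrated density over the
vessel mask; the outbound signal is integrated over the above-threshold
pixels outside the vessels, excluding background. The default
`"positive"` threshold keeps pixels strictly above the image mode (the
background level of a fluorescence micrograph); Otsu's method is the
alternative for images with a nonzero noise floor.

Calibration curves map known spotted amounts (0–30 µM) to integrated
density. The linear model is preferred when its $R^2 \ge 0.99$
(`model = "auto"`), matching the observed linearity of such calibrations;
the ImageJ-style "Rodbard" option is implemented as the standard
four-parameter logistic $y = d + (a-d)/(1+(x/c)^b)$, fitted by
Levenberg–Marquardt from data-driven starts ($a$, $d$ at the extreme
responses, $c$ at the median amount, $b = 1$). `percentDelivered()`
inverts the calibration at a measured density and reports
$100 \times \mathrm{amount}/\mathrm{administered}$; the 4PL is only
invertible strictly between its asymptotes, and queries outside that
range are range errors.

## Synthetic data: what the generators emulate

Each generator is a pure function of (parameters, seed) — identical calls
are bit-identical — and returns the truth as a sidecar record, never
embedded in the data. Defaults encode the study conditions this package
models:

- **Laurdan** (`genLaurdanSpectrum`): two Gaussian bands at 440/490 nm,
  σ = 18 nm, on a 1-nm 400–550 nm grid; amplitudes are solved accounting
  for cross-band tails so the interpolated band reads give the target GP
  exactly at zero noise. The overlap bounds representable |GP| at ~0.96.
- **Fusion** (`genMixingSeries`): Hill curves (default exponent 2; the
  assay literature fixes endpoints, not a curve family) with the scale
  $K$ chosen so the extent reaches 95% of plateau exactly at the preset
  saturation P/L — 0.05 (BBB-like, total plateau 100%, inner-monolayer
  20%) vs 0.7 (liver-like, both 100%); leakage plateau 0 in both.
  Fluorescence levels default to $F_0 = 10$, $F_{100} = 110$ a.u.
- **Binding** (`genTrpTitration`): the partition balance is solved per
  lipid point (closed form $f_b = K_o L/(1 + K_o L)$,
  $K_o = K_p \times 0.6$, when there is no self-association; monotone
  root-finding otherwise, with an upward-curving term above a critical
  $C_f$ emulating in-membrane aggregation). Preset truths:
  $K_p = 4.24\times10^4$ (BBB-like) and $1.55\times10^3$ M⁻¹
  (liver-like); peptide 4 µM; 10 log-spaced lipid points from 10⁻⁵ to
  8×10⁻⁴ M, i.e. lipid-to-peptide ratios 2.5–200, a realistic titration
  reaching the standard 200:1 endpoint; $F_0 = 100$, $F_\infty = 300$
  (threefold enhancement on binding).
- **Quenching** (`genQuenchingSeries`): exact Stern–Volmer inversion
  $F = F_0/(1 + K_{sv} q)$ on a 9-point 0–0.2 M grid; preset truths
  10.21 (buffer), 3.04 (liver-like), 2.05 M⁻¹ (BBB-like).
- **CD** (`genCDSpectrum`): fixed analytic Gaussian-mixture bases — a
  helix basis with negative bands at 208/222 nm and a positive band near
  193 nm, and a coil basis with its trough near 198 nm and near-zero
  signal at 222 nm (self-contained shapes, not an experimental reference
  set). The two amplitudes are solved from the target helix fraction and
  222/208 ratio, so zero-noise round trips are exact; 208 and 222 nm are
  exact grid points (190–260 nm, 0.5-nm step). Preset truths: 58%
  helix/ratio 0.68 (BBB-like), 40%/0.45 (liver-like), coil in buffer.
- **Imaging** (`genBrainImage`): vessels as thick smoothed random-walk
  tubes whose pixels carry a total fluorescence of slope × inside-amount;
  parenchymal signal as Gaussian puncta carrying slope × outside-amount;
  optional constant background and additive Gaussian noise (clipped at
  zero). Integrated densities therefore invert exactly through a linear
  calibration of the same slope.

Noise defaults are multiplicative Gaussian (σ = 2%) on fluorescence —
photodetector-style — and additive Gaussian on images; the CD generator
additionally offers band-amplitude noise. What the generators do **not**
emulate: time-resolved fusion kinetics, FRET distance ($R^6$)
photophysics, inner-filter and scattering artifacts, instrument baseline
drift, realistic histology (cell nuclei, autofluorescence), or vessel
morphology beyond simple tubes. Passing round-trip tests therefore
demonstrates correctness of the estimators under the stated statistical
model, not robustness to every instrumental artifact of real spectra and
micrographs.

## Validation design and problem sizes

The test suite checks three layers: analytic identities (closed-form GP,
normalization endpoints, convention ratios, classification thresholds);
oracle equivalence on noiseless data (fits against independent
closed-form slope formulas and a brute-force $F_\infty$ grid search); and
statistical round trips (200 replicates per condition at 2%
multiplicative noise for parameter recovery, 100 end-to-end replicates
for the condition orderings, which complete in a few minutes on a single
CPU). `scripts/acceptance.R` reruns the full pipeline at 50 replicates
per condition and writes median recovered values as JSON.

## Known limitations

- The partition model is a single-site linear isotherm; Gouy–Chapman
  electrostatics and multi-site binding are out of scope.
- $K_p$ depends mildly on the initial-region rule when isotherms are
  strongly curved; the rule and its parameters are exposed in
  `AnalysisConfig` rather than hidden.
- The inner-monolayer analysis treats the dithionite-treated population's
  $F_0/F_{100}$ as given; dithionite reduction kinetics are not modelled.
- Image quantification assumes masks are correct; there is no vessel
  segmentation, DAPI counting, or autofluorescence correction.
- Temperature is carried as metadata only and never enters a computation.
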