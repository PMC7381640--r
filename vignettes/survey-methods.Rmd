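---
title: "Models and methods behind radsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radsurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`radsurvey` implements the analysis chain of a national car-borne
gamma-radiation survey: count rates logged inside a moving car are turned
into absorbed dose rates in air, fixed-point NaI(Tl) spectra are unfolded
into activity concentrations of the natural decay series, soil samples are
assayed on an HPGe detector, and both branches feed a common dose and
hazard calculus whose direct-vs-soil comparison quantifies how the built-up
environment shields terrestrial gamma rays or adds sources. This vignette
explains each model, its assumptions and its tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was open.

## 1. The dose-reconstruction model

A count rate `C_in` (cps) measured inside the car over a 30-s interval is
converted to the absorbed dose rate in air 1 m above a bare ground surface
by a purely multiplicative model,

```
D_air = C_in * SF_carbody * SF_asphalt * DCF     [nGy/h]
```

* `SF_carbody` (dimensionless, default truth 2.01) corrects for shielding
  by the car body, fitted as the through-origin slope of outside-car vs
  inside-car count rates over paired 2-min measurements.
* `SF_asphalt` (dimensionless) corrects from the asphalt surface to a bare
  surface. It is region-specific: about 1.37 where the asphalt layer
  shields the soil signal, and about 0.96 where a crushed-granite roadbed
  adds gamma flux, so bare-surface counts fall *below* asphalt counts.
  `estimateCalibration(paired, by = "region")` therefore fits one
  calibration per region.
* `DCF` (nGy/h per cps, default truth 0.14) is the empirical dose
  conversion factor: the slope of unfolded fixed-point dose rates against
  outside-car count rates.

Because the model has no additive term, all three factors are fitted
through the origin (`fitProportional()`); an ordinary fit with intercept is
available as a diagnostic but is never used for reconstruction. Records
are never filtered or despiked — the field procedure applies no outlier
rejection — and `reconstructDose()` is exactly linear and monotone in
`C_in`.

## 2. NaI(Tl) spectrometry and response-matrix unfolding

Fixed-point pulse-height spectra (default 1024 channels, 3.2 keV/channel,
10-min live time) are processed in four steps:

1. **Energy calibration** (`calibrateEnergy`): the K-40 (1.464 MeV) and
   Tl-208 (2.615 MeV) photopeaks are located by boxcar smoothing
   (`smoothSpectrum`, zero-padded moving average that conserves interior
   counts exactly) followed by a quadratic centroid fit over the five
   channels around the smoothed maximum, searching ±8% windows around the
   nominal energies. A two-point line through the centroids gives offset
   and gain. A peak missing from its window raises a `calibrationError`
   naming the peak; a noisy near-flat quadratic fit falls back to the raw
   maximum rather than extrapolating the vertex.
2. **Cosmic subtraction** (`subtractCosmic`): terrestrial gamma rays do not
   reach above 3.0 MeV, so the mean per-channel rate in the 3.0–3.2 MeV
   window estimates a flat cosmic floor, subtracted everywhere and clamped
   at zero. The energy-independent floor is an assumption; the true cosmic
   spectral shape is not modelled.
3. **Rebinning and unfolding**: the calibrated spectrum is rebinned by
   fractional channel overlap onto 22 unequal bins spanning 0–3.2 MeV.
   The four evaluation windows sit exactly at 1.39–1.54 (K-40), 1.69–1.84
   and 2.10–2.31 (Bi-214) and 2.51–2.72 MeV (Tl-208); the remaining ranges
   are split log-uniformly, with a 3.0 MeV edge so the cosmic window is
   resolved. The published account does not list the 22 edges, so these
   defaults are a reconstruction and remain configurable
   (`defaultEnergyBinning`). Unfolding solves the non-negative least
   squares problem `min ||R φ − c||², φ ≥ 0` with `pracma::lsqnonneg`; the
   residual norm is reported, and an ill-conditioned response raises a
   `conditioningWarning`.
4. **Evaluation**: `A_K` comes from the 1.464 MeV bin and `A_Th` from the
   2.615 MeV bin by division with their per-unit-activity coefficients;
   `A_U` combines the 1.765 and 2.205 MeV bins by inverse-variance
   weighting, with Poisson variances from the counts in each window.
   Dose is the dot product of the unfolded vector with per-bin
   flux-to-dose coefficients. Both a peak-bins-only and an all-bins dose
   are exposed; under the default coefficients (zero away from the
   evaluation lines) they coincide.

**The forward model and its deliberate simplification.** The detector
response of the original instrument came from a Monte Carlo code that is
not available, so the package ships its own self-consistent forward model:
each library line contributes a Gaussian photopeak with FWHM scaling as
`r·sqrt(E)` (resolution coefficient `r`, default 7.5% at 0.662 MeV) plus a
flat Compton continuum from zero to the line's Compton edge carrying a
configurable fraction (default 0.55) of the detected counts, on top of the
flat cosmic floor. The response matrix used for unfolding is built from
the *same* model (`buildResponseMatrix`), which is what makes unfolding
correctness testable: noise-free forward-then-invert chains recover
activities to better than 0.1% across three decades. The NaI line library
is restricted to the four evaluation lines, one per window, so each
unfolding window is single-series and the flux-to-dose coefficients are
exactly consistent with the soil dose-rate model (Section 4) by
construction: `e_series / Σ yields_series` per bin. This is a physics
simplification, not a calibrated detector model — absolute yields
(cps per Bq/kg) are nominal constants, and escape peaks, summing,
dead time, angular response and soil moisture are all out of scope. Under
Poisson noise at survey counting statistics the non-negativity constraint
introduces a small negative bias in the weakest windows (about −5% for the
U-series at 10-min spectra, under −1% for K); this is inherent to NNLS on
overlapping response columns and is visible in, and accepted by, the
end-to-end recovery tests.

## 3. HPGe soil assay

Soil activity concentrations use the absolute-efficiency method on
30,000-s spectra of 0.12-kg samples (4096 channels, 0.5 keV/channel):

* **Net areas** (`netPeakArea`): gross counts in a region of interest of
  ±3 peak sigmas minus a linear baseline through the mean of three
  flanking channels on each side; Poisson uncertainty from gross counts
  plus the propagated baseline. Negative nets are clamped to zero and
  flagged.
* **Efficiency** (`efficiencyAt`): log-log linear interpolation between
  calibration points. The default curve uses the energies of a certified
  nine-nuclide volume source with plausible nominal efficiencies for a
  17.5%-relative-efficiency p-type detector with the sample on the endcap;
  it is synthetic, clearly so named, and replaceable by a measured curve.
  Queries beyond ±5% of the calibrated span raise an `extrapolationError`.
* **Activities** (`activityFromPeak`):
  `A = net / (eff · p · t · m)`, uncertainties combined in quadrature from
  the net area and the curve's relative uncertainty (default 1%).
* **U-238 series** (`u238WeightedAverage`): inverse-variance weighted mean
  of the Pb-214 (352 keV) and Bi-214 (609 keV) estimates, combined
  uncertainty `(Σw)^(-1/2)`; an equal-weight option is retained. The
  Th-232 series uses Ac-228 (911 keV) alone, and K-40 its 1461 keV line.

At the default live time and typical activities the recovered relative
uncertainties stay below 8% (U), 3% (Th) and 2.3% (K), asserted as bounds
in the tests. True-coincidence summing and self-absorption corrections are
out of scope.

## 4. Dose and hazard calculus

With activities in Bq/kg and dose rates in nGy/h:

```
D_soil = 0.43 A_U + 0.666 A_Th + 0.042 A_K
OAED   = D_air · 0.7 · 8760 · 0.2 · 1e-6      [mSv/year]
IAED   = D_air · 0.7 · 8760 · 0.8 · 1e-6
Ra_eq  = A_U + 1.43 A_Th + 0.077 A_K
H_ex   = A_U/370 + A_Th/259 + A_K/4810   (≤ 1 acceptable)
```

The 0.7 Sv/Gy adult conversion coefficient and the 0.8/0.2 occupancy split
give `IAED/OAED = 4` identically and `IAED + OAED = D·0.7·8760·1e-6`.
`H_ex` equals `Ra_eq/370` to within 0.3% for every non-negative
composition — a coefficient identity the tests exercise under random
inputs. All five formulas are homogeneous of degree 1, so regional means
commute with the formulas exactly. The **ratio of difference**
`D_direct / D_soil` classifies each site: below 1, construction materials
shield terrestrial gamma rays; above 1, they act as sources
(`classifyBuiltUp`, with a configurable neutral band). Internal arithmetic
is never rounded; `presentationRound()` mirrors reporting conventions
(doses to 2 decimals, dose rates and Ra_eq to integers, ratios and H_ex to
1 decimal) and exists only for display. Totals are also flagged against a
1–20 mSv/year reference band (lower edge configurable).

## 5. The synthetic survey generator

No raw survey data are publicly deposited, so the generator
(`truthConfig`, `generateSites`, `simulateNaiSpectrum`,
`simulatePairedCounts`, `simulateTrack`, `simulateHpgeSpectrum`) replaces
them with campaigns whose ground truth is known exactly:

* **Activity fields.** Two regions (north, weight 178; south, weight 284)
  with per-nuclide truncated-at-zero normal distributions. Each site
  carries *two* linked triplets: the soil composition (north 39/63/551,
  south 32/54/551 Bq/kg for U/Th/K) and the direct-field composition seen
  by the detector above ground (north 60/44/415, south 44/43/531), drawn
  comonotonically — the same standard-normal deviate per nuclide drives
  both — so a site rich in soil uranium is rich above ground too. Keeping
  both distributions is what makes the direct-vs-soil comparison
  reproducible at its observed level (mean ratio ≈ 0.92) without any
  artificial perturbation; a purely single-triplet design would force the
  ratio to 1. The truncated draws are *mean-corrected*: the location
  parameter is solved (via the Mills ratio) so the truncated mean equals
  the configured mean, which keeps the configured values interpretable as
  population means and makes sample-mean recovery tests exact in
  expectation.
* **Built-up multiplier.** Optionally, a per-site lognormal factor
  (clamped to 0.5–2.1, the observed range of the ratio of difference)
  multiplies the direct truth only; its `fractionBelow` parameter plants
  an exact below-unity probability, which the paired cumulative analysis
  must recover. Disabled by default.
* **Counting.** All counts are Poisson: 30-s track intervals draw
  `Poisson(cps·30)/30`, paired measurements integrate 120 s, NaI and HPGe
  spectra sample per-channel expected counts. Every generator accepts a
  `noise = FALSE` flag returning expected values, the anchor for the
  exact round-trip tests, and a seed making output bit-reproducible.
* **Paired contract.** Outside-car counts are defined by
  `outside = D_air/DCF` with `inside = outside/SF_carbody`, the asphalt
  column equal to outside in expectation, and `bare = asphalt·SF_asphalt`;
  track counts are drawn around `D_air/(DCF·SF_carbody·SF_asphalt)` so the
  reconstruction model inverts the noise-free track identically.
* **Not emulated:** real road networks and GPS error, detector gain drift
  and temperature effects, radon-progeny washout, soil moisture, angular
  response, spatial autocorrelation of activities within a region, and the
  heavy tails of real dose-rate distributions. Passing tests therefore
  demonstrate the correctness of the *analysis chain* under the stated
  forward model, not field performance of an instrument.

## 6. Regional aggregation and gridding

`assignRegion` performs even-odd point-in-polygon assignment against
GeoJSON boundaries (WGS84, lon-lat), attaching near-miss points within a
tolerance (default 0.25°) to the nearest boundary and flagging the rest
unassigned. `summarizeByRegion` reports n/mean/SD/min/max with an `NA` SD
sentinel for single-record groups, computed before any presentation
rounding. `cumulativeDistribution` returns a right-continuous empirical
CDF with fractions `k/n` and, for paired (direct, soil) input, the
strict below-unity fraction.

`gridMinimumCurvature` interpolates scattered dose data as the discrete
minimum-curvature (biharmonic) surface: cells holding data are fixed to the
cell-averaged datum and free cells satisfy
`(1−t)·∇⁴u − t·∇²u = 0` with tension `t` (default 0: pure minimum
curvature, exact for linear fields — a plane through the data is
reproduced to solver precision). Boundary conditions are "natural" (zero
second derivative normal to the edge, i.e. ghost nodes extrapolated
linearly), with degenerate corner nodes closed by planar extrapolation
from their three neighbours. The solver is conjugate gradients on the
normal equations of the constrained system, implemented in C++; plain
relaxation sweeps diverge on this non-symmetric operator, and CGNR is
guaranteed to converge to the same solution a dense direct solve gives
(the tests verify agreement to 1e-6 on small grids). Iteration stops when
the largest cell update falls below `tol` (default 1e-10 relative to the
data scale). Grid spacing (default 0.1°) and the mask radius (default 3
cells beyond any datum) are configuration values; the treatment of
coordinates is equirectangular, appropriate for the sub-degree cell sizes
used here, and no map projection or kriging is attempted.

## 7. The pipeline and reproducibility

`runPipeline(defaultRunConfig(...))` executes simulate → unfold →
calibrate → carborne → soil → assess → report, writing every stage's
table as CSV plus a `manifest.json` with the package version, seed, a hash
of the scientific configuration (output paths excluded) and per-output
checksums. Identical config and seed reproduce every output byte for
byte; stage failures raise a `pipelineStageError` naming the stage.
`validateInputs` checks schemas, coordinate ranges, count signs and
timestamp monotonicity, returning a per-file, per-row report rather than
throwing. Configurations can be read from YAML (`readRunConfig`), putting
every constant of the analysis in one inspectable file.

**Problem sizes.** The package defaults reproduce the study design at desk
scale: 462 fixed-point sites with 10-min NaI and 30,000-s HPGe spectra,
2-min paired measurements, and a 1,000-record track standing in for the
full multi-campaign log (which is two orders of magnitude longer but
statistically equivalent for calibration purposes, since the calibration
uses only the 462 paired sites). A full default run takes a few seconds.

## 8. Known limitations

* The forward spectral model is self-consistent but nominal; absolute
  activity recoveries on real spectra would require measured response and
  efficiency data, supplied via the configurable line libraries, response
  matrix and efficiency curve.
* NNLS unfolding carries a small noise-induced negative bias in weak
  windows (Section 2).
* The cosmic floor is assumed flat in energy.
* Region assignment uses planar geometry; fine near polygon boundaries at
  continental scales it is not.
* The two published car-body factors (2.01 and 1.71) are exposed as
  campaign-keyed truths; no assignment rule to specific campaigns is
  encoded because none is recorded.
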