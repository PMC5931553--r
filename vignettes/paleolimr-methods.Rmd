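---
title: "Models and methods behind paleolimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleolimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleolimr implements the analysis chain used to link recent ecological
change recorded in a high-Arctic lake sediment core to instrumental
climate series: a radiometric chronology, marker-spike proxy
quantification, significance-tested stratigraphic zonation, and sea-ice
and temperature metrics with decadal trends. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Radiometric chronology

### Unsupported ²¹⁰Pb and the CRS model

Total ²¹⁰Pb in a slice is the sum of the ²²⁶Ra-supported component and
the atmospherically delivered (unsupported, "excess") component, which
decays with half-life 22.3 yr once buried. `excess_pb210()` subtracts
the *per-slice* ²²⁶Ra activity from total ²¹⁰Pb (sigmas combined in
quadrature). We deliberately use the per-slice supported level rather
than a core-wide mean, matching the subtraction as practised with
multi-line gamma assays. Negative excess values — possible at depth
where the unsupported component has decayed away — are clamped to zero
and flagged, because inventories must be non-negative; the flag
preserves auditability.

The constant-rate-of-supply (CRS) model assumes a constant flux
\(P\) (Bq cm⁻² yr⁻¹) of unsupported ²¹⁰Pb to the sediment surface.
Integrating the decay of buried material, the excess inventory below a
horizon of age \(t\) is \(A(t) = (P/\lambda)\,e^{-\lambda t}\), so

\[ t(z) = \frac{1}{\lambda}\,\ln\frac{A(0)}{A(z)}, \qquad
   \lambda = \ln 2 / 22.3\ \mathrm{yr}^{-1}. \]

Inventories are integrated on the cumulative dry-mass scale
(Bq cm⁻²); the core cross-sectional area cancels from the age equation
provided mass-depth units are used consistently. Three numerical
choices matter:

* **Deep-tail correction.** CRS ages are sensitive to inventory below
  the deepest measured slice. We extrapolate the deepest three positive
  excess activities exponentially against cumulative mass and integrate
  the fitted curve to infinity. When the deep slices straddle a change
  in accumulation rate the fitted decay constant is biased and the tail
  (hence the deepest ages) inherits that bias; this is the dominant
  error source in deep horizons and the reason horizons retaining
  ≤ 5 % of the total inventory are flagged unreliable and excluded.
* **Within-slice interpolation.** The inventory at a slice midpoint is
  the *geometric* mean of its boundary inventories. Inventory decays
  exponentially on the mass scale under constant accumulation, so this
  is exact in that case; linear interpolation instead produces errors
  of order \(\lambda \Delta t^2/8\) for slices spanning \(\Delta t\)
  years, which exceeds a year once a slice spans two decades.
  `crs_age_at()` exposes the same log-linear interpolation at arbitrary
  horizons.
* **Measurement gaps.** Where ²¹⁰Pb is unmeasured (gamma assays are
  often run every ~5 cm on 1 cm slices), excess activity is linearly
  interpolated on cumulative mass between measured slices. The exact
  scheme used by any particular lab is rarely reported; interpolation
  on mass rather than depth is the choice consistent with the CRS
  mass-flux formulation.

Age uncertainties come from Monte-Carlo perturbation of every slice
activity by its reported sigma, re-deriving inventories *and the tail
fit* in each replicate (default 1000 replicates, seeded). With zero
measurement sigma the Monte-Carlo sigma is exactly zero. Because the
three-point tail refit responds nonlinearly to large perturbations, the
age sigma grows proportionally with activity sigma only in the
small-noise regime; at large assay noise the tail term dominates and
uncertainty grows faster than linearly.

### Independent tie points

* **¹³⁷Cs.** The activity maximum is assumed to mark the 1962–1963
  culmination of atmospheric nuclear testing and is dated 1962.5 ± 1 yr
  (the midpoint of the two candidate years). Ties break toward the
  shallower slice, and a maximum on the first or last measured slice is
  flagged as lacking an interior peak. The contiguous half-maximum
  window is reported because real fallout peaks are broad.
* **Post-bomb ¹⁴C.** A fraction-modern measurement above 100 % is
  matched against a user-supplied atmospheric bomb curve. Because the
  curve rises to its mid-1960s peak and falls afterwards, a sample
  below the peak intersects it twice; `calibrate_bomb_14c()` reports
  every maximal year window within \(k\) combined standard deviations
  (default \(k=1\)), leaving the rising/falling-limb choice to the
  analyst. The pipeline adopts the falling-limb window when a ¹³⁷Cs
  peak lies deeper than the ¹⁴C sample, since the rising-limb window
  would then be older than a shallower, stratigraphically younger
  horizon.

### The age-depth model

`fit_age_depth()` fits \( \mathrm{age}(d) = a d^2 + b d + c \) by
weighted least squares (weights \(1/\sigma^2\), unit weight where no
sigma is available) through the CRS ages and tie points jointly, plus a
surface tie point (0 cm, collection year, σ = 0.5 yr). Whether the
polynomial should be fitted to CRS ages alone or jointly with the
independent tie points is genuinely open; the joint fit is the default
because the tie points are the only anchors that do not share the CRS
model's tail sensitivity, and fitting them jointly regularises the
deep extrapolation. The fitted curve must be strictly decreasing in
depth on a 0.1 cm grid; violation signals incompatible tie points and
is an error rather than a warning, because every downstream product
depends on invertibility. Evaluation outside the fitted depth range is
an error (no extrapolation). The sedimentation rate is the reciprocal
age gradient \(-1/(2ad+b)\).

## Proxy quantification

Spike-based concentrations follow the standard exotic-marker ratio: if
\(n\) microfossils are counted alongside \(m\) of the \(M\) added
marker particles in \(w\) grams of sediment,
\( C = (n/m)\,M/w \) per gram. The sigma carries Poisson counting
error on both counts via the delta method,
\( \sigma_C/C = \sqrt{1/n + 1/m} \); weighing error is ignored because
counts of tens to hundreds dominate the error budget. Counting-stop
rules (e.g. "count to 300 coenobia or 100 markers") are laboratory
procedure, not computation: the functions accept whatever counts are
supplied and flag samples whose included total falls below a reporting
threshold (default 50) rather than dropping them.

Relative abundances are computed under a *sum rule*: the percentage
base may exclude taxa (for pollen, aquatic types) supplied as an
explicit exclusion list, since no universal aquatic-taxon registry
exists. Rows of the resulting assemblage matrix sum to 1 and are
invariant to uniform count scaling. Loss on ignition is
\(100\,( \mathrm{dry} - \mathrm{ashed})/\mathrm{dry}\) from the 105 °C
and 550 °C weights, with ashed > dry rejected as a weighing error.

## Zonation by information content

For a contiguous block of samples with proportion rows \(p_{ij}\) and
block-mean composition \(q_j\), the information content is the summed
Kullback–Leibler deviance

\[ I = \sum_i \sum_j p_{ij} \ln (p_{ij}/q_j) \ \ge 0, \]

zero exactly when all rows are identical (zero proportions contribute
nothing, and \(q_j = 0\) forces \(p_{ij} = 0\)). A cut's *reduction* is
\(I(\mathrm{block}) - I(\mathrm{left}) - I(\mathrm{right})\), never
negative. `recursive_zonation()` splits greedily: each step evaluates
every cut of every current block exhaustively and applies the best one
(ties toward the shallower cut), which matches the sequential-splitting
character of optimal-splitting zonation while remaining exact within
each step. The information measure sits behind a single function so a
different splitting criterion can be substituted; a transform hook
(e.g. square root, renormalised) is available but off by default, as
there is no consensus that abundance transformation belongs in the
zonation itself.

Significance uses the broken-stick null: the expected proportion of the
\(k\)-th largest of \(n\) random pieces of a unit stick is
\( b_k = (1/n)\sum_{j=k}^{n} 1/j \), with \(n\) set to the number of
samples (the stick cannot be resolved more finely than the sampling).
Split \(k\) is significant while its proportional reduction
\(r_k / I(\mathrm{whole})\) exceeds \(b_k\), and the reported number of
significant zones boundaries is the longest all-significant prefix.
Zone-boundary ages are midpoints of the bracketing samples' ages, since
a boundary falls between slices.

A caveat found while validating the screen: with very taxon-poor
matrices (≲ 4 taxa) the screen is anticonservative (about 20 % false
positives on pure counting noise), while at realistic assemblage
richness (≥ 10 taxa, as on any diatom count sheet) false positives are
near zero and strong boundaries are recovered essentially always. The
package's fixtures therefore use 12-taxon assemblages; users zoning
matrices collapsed to a handful of taxa should treat marginal
significance with suspicion.

## Climate metrics

* **Regional sea-ice series.** Daily concentration fields on an
  equal-area grid are averaged without weights over the ocean cells of
  a configurable region box (equal cell areas make the unweighted mean
  the areal mean); days with under half the region reporting are
  missing.
* **Phenology.** The ice-free season is operationalised as the *count*
  of days below the 55 % concentration threshold, not the span between
  first and last crossing — robust to mid-season excursions and
  consistent with reporting high-ice conditions as day counts (the
  > 75 % count is reported alongside). Melt and freeze onsets are the
  first day of, and the first day after, the longest run of
  sub-threshold days; daily series define a season but no onset by
  themselves, and the longest-run rule is the least parameterised one.
  Missing days break runs and are excluded from counts. Years with
  fewer than 300 valid days are flagged and excluded from period means,
  mirroring the partial coverage of early passive-microwave years.
* **Site temperature.** Stations are stacked by per-day averaging
  (means and maxima separately; days with fewer than 2 stations are
  missing), then shifted by a constant offset, default −1.6 ± 0.5 °C,
  representing the climatological difference between the blended
  stations and the site. The daily maxima used for the melting season
  are taken from the blended-then-offset record; offsetting after
  blending is the default because the offset is defined against the
  blended climatology. The melting-season length is the annual count of
  days with maximum temperature above 0 °C.
* **Trends.** Decadal trends are ordinary least squares of annual
  values on year, scaled ×10, with the slope's standard error, R², and
  a two-sided t-test on \(n-2\) degrees of freedom. No autocorrelation
  correction is applied — annual means of these series are only weakly
  autocorrelated and plain OLS is what the reported R²/p convention
  implies. At least 10 years are required.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class with analytic ground truth:

* `gen_core()` integrates a prescribed piecewise-constant mass
  accumulation history under constant ²¹⁰Pb flux, slicing at 1 cm (the
  field slicing protocol). Slice activities are *exact mass averages*
  of the decayed flux, so CRS applied to a noise-free profile is exact
  up to the tail correction. The ¹³⁷Cs pulse is Gaussian in deposition
  age (σ = 2 yr), producing the broad maxima seen in real profiles
  rather than a one-slice spike. Activities get multiplicative
  lognormal noise (activities are positive); the default 5 % CV is a
  typical good gamma-assay precision. The default history raises the
  accumulation rate ~eightfold from 1900 to 2015 (0.03 → 0.25 cm/yr at
  0.2 g cm⁻³ dry bulk density), the behaviour of a rapidly changing
  Arctic catchment. Dry mass per slice is prescribed directly; there is
  no compaction, mixing, or bioturbation model, so recovery tests say
  nothing about cores with significant surface mixing.
* `gen_assemblage()` draws Dirichlet–multinomial counts around per-zone
  compositions with hard boundaries, plus a Poisson marker count
  consistent with an implied true concentration. Real assemblages turn
  over gradually; hard boundaries make ground truth unambiguous but
  mean recovery rates here are upper bounds for diffuse transitions.
* `gen_daily_climate()` builds the sea-ice year as plateaus (full
  winter cover, low summer cover) joined by cosine ramps whose phases
  shift independently — melt earlier, freeze later, by set days per
  decade. A single globally phase-shifted sinusoid cannot move the two
  onsets in opposite directions, which is precisely the observed
  behaviour the generator must emulate; with the default 100 %/10 %
  plateaus the 55 % threshold crossing is the analytic ramp centre.
  Station temperature is a seasonal cosine plus linear trend plus AR(1)
  noise with per-station offsets; the default trend (0.7 °C/decade),
  onset shifts (20 and 19 d/decade), four stations within a 1 °C
  offset band, and 1960–2015 span reflect the study-era conditions the
  package targets. The generator's seasonality is a pure cosine, so
  derived quantities whose value depends on the *shape* of the real
  Svalbard seasonal cycle (e.g. the exact melting-season trend implied
  by a given warming rate) differ between generator and reality; tests
  validate estimator calibration, not those shape-dependent magnitudes.

All generators are bit-reproducible under a fixed seed, and write the
same CSV dialects the pipeline reads, so synthetic outputs are drop-in
fixtures.

## Problem sizes and runtime choices

The test-suite and acceptance workloads are sized to validate each
statistical claim at useful power while staying lightweight: 100-seed
batches for zonation recovery and false positives (16 samples × 12
taxa × 300 counts), 200-seed batches for trend-estimator coverage and
type-I calibration (36–56 year series, 2 stations for the repeated
batch), 1000 Monte-Carlo replicates for chronology uncertainties in
production use (reduced in repeated tests), and 20-scenario batches for
noisy-chronology parameter recovery. These sizes are stated here so
that anyone re-running the checks knows what was actually measured.

## Known limitations

* The CRS deep-tail extrapolation is the weakest link: where the
  deepest slices straddle an accumulation-rate change the tail, and
  with it ages older than ~3 half-lives, can be biased by decades. The
  ≤ 5 % inventory cutoff and the quadratic fit through independent tie
  points are the mitigations.
* Alternative ²¹⁰Pb models (CIC, CFCS) and Bayesian age-depth models
  are out of scope; so are retrieval algorithms for sea-ice products
  and any vegetation reconstruction from pollen percentages.
* The broken-stick screen is a null model, not an error-controlled
  test; its behaviour depends on taxon richness as described above.
* The exact information measure used by legacy zonation software may
  differ in detail from the Kullback–Leibler deviance used here; the
  measure is isolated behind one function precisely so it can be
  swapped.
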