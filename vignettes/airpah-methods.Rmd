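---
title: "Methods: source apportionment and inhalation risk for PM2.5-bound PAHs"
author: "airpah"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source apportionment and inhalation risk for PM2.5-bound PAHs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`airpah` packages the standard analysis chain applied to multi-year daily
series of PM2.5-bound polycyclic aromatic hydrocarbons (PAHs): descriptive
and exceedance statistics, molecular diagnostic ratios (MDR), a positive
matrix factorization (PMF) receptor model written from scratch, potential
source contribution function (PSCF) gridding of back trajectories, and a
Monte Carlo incremental lifetime cancer risk (ILCR) model.  This vignette
records the models, the tunable parameters, and the design decisions taken
where the methodology is genuinely open.

## Data model and censoring

A sample table holds one row per site-day: PM2.5 mass (µg/m³), the 16
US-EPA priority PAH concentrations (ng/m³), optional temperature, pressure
and relative humidity, and per-species below-detection flags.  The species
catalogue carries ring count, molecular-weight class (LMW = 2–3 rings,
MMW = 4, HMW = 5–6), toxic equivalency factor and method detection limit
(MDL).

TEFs follow the Nisbet–LaGoy assignment: 0.001 for Nap, Acy, Ace, Flu, Phe,
Flua and Pyr; 0.01 for Ant, Chr and BghiP; 0.1 for BaA, BbF, BkF and IcdP;
1 for BaP and DahA.  The catalogue is a plain CSV and every value can be
overridden.

Default MDLs (e.g. Nap 0.06, Acy 0.01, Flu 0.04, Ace 0.15, Phe 0.10 ng/m³)
are inferred from the constant low medians that long urban series show for
these species once below-detection values are substituted; they are
documented as inferences, not instrument specifications, and should be
replaced with laboratory values when available.

Three censoring policies are offered: `substitute-mdl` (default — matches
series whose low quantiles sit exactly at the MDL), `substitute-half-mdl`,
and `leave-zero`.  All are idempotent; flags are preserved so downstream
stages can treat substituted values differently (the PMF uncertainty matrix
and the MDR low-confidence flags both do).

## Descriptive statistics

Summaries report median and quartiles with linear interpolation between
order statistics (`quantile` type 7), fixed so tables are reproducible.
Exceedance counting uses a strict `>` convention — a day exactly at the
limit does not exceed — configurable via `strict = FALSE`.  Two-group
comparisons use the Wilcoxon rank-sum test with mid-ranks, tie-corrected
variance and no continuity correction (so identical groups give p = 1, and
tie-free small samples take the exact enumeration path); more than two
groups use Kruskal–Wallis.  Correlations are Spearman throughout, with
constant variables flagged as undefined rather than raising errors.

## Molecular diagnostic ratios

Each ratio is a/(a+b) on censor-substituted concentrations: Ant/(Ant+Phe),
Flua/(Flua+Pyr), BaA/(BaA+Chr), IcdP/(IcdP+BghiP).  A ratio is undefined
when the denominator is zero or both components are censored, and flagged
low-confidence when either component is censored (the substitution constant
can dominate the ratio).  Band boundaries are assigned so that an exact
lower cut-off belongs to the higher class and middle bands are closed on
both ends, e.g. Flua/(Flua+Pyr): < 0.4 petrogenic/unburned petroleum,
[0.4, 0.5] fossil fuel combustion, > 0.5 biomass and coal combustion.  The
band tables are data (`mdr_bands()`) and configurable.  Classification is
total: every value in [0, 1] receives exactly one label, undefined values
none.

## Positive matrix factorization

The model is `x = G F + E` with nonnegative sample-by-factor contributions
`G` and factor-by-species profiles `F`, fitted by minimizing the weighted
objective `Q = sum((x - G F)^2 / S^2)` over an uncertainty matrix `S`.

The uncertainty construction is the standard error-fraction formula used
when per-sample analytical uncertainties are unavailable: observed cells
`s = sqrt((ef * x)^2 + (0.5 * MDL)^2)` with error fraction `ef = 0.10` by
default; censored cells `s = (5/6) * MDL`.

The solver runs, per random start, multiplicative updates generalized to
elementwise weights (monotone nonincreasing in Q) until the relative Q
change drops below `tol = 1e-6` or 2000 iterations, then an exact
alternating nonnegativity-constrained least-squares polish (one NNLS
problem per sample row and species column, via `pracma::lsqnonneg`, 30
passes).  The best of 20 starts receives an extended polish (up to 500
passes).  Initialization is uniform(0.1, 1) scaled to the data magnitude.
These settings are the package's own choices — receptor-model literature
does not pin them down — and every one is an argument of `fit_pmf()`.

Scale indeterminacy is resolved by normalizing each profile row to sum 1
and absorbing the scale into `G`; factors are ordered by contribution
percentage (share of reconstructed mass) so output is deterministic.
Rotational ambiguity is *not* resolved — no Fpeak-style tools are provided
— which is why factor labels from `label_factors()` are reported with their
marker scores and never asserted as ground truth.  `q_expected`, the
degrees-of-freedom reference `n*m - k*(n+m)`, is reported for the usual
Q/Qexp diagnostic, and `pmf_factor_scan()` gives Q as a function of the
factor count.

## Potential source contribution function

Endpoints are binned on a latitude–longitude grid (default 0.5°, domain
auto-fitted with a one-cell margin).  `n` counts trajectories with at least
one endpoint in a cell (once per trajectory per cell, the common
convention; an endpoint-count mode is available), `m` the subset arriving
on days whose PM2.5 exceeds the threshold (default 35 µg/m³, strict).
PSCF = m/n where n > 0 and is undefined elsewhere.  The weighting
`WPSCF = W(n) * PSCF` damps sparsely visited cells with the usual piecewise
scheme relative to the mean count over nonempty cells: 1.0 above 3×, 0.7 on
(1.5×, 3×], 0.42 on (1×, 1.5×], 0.05 at or below the mean.

A structural limitation worth stating: with trajectories that run in
straight lines from a source region to the receptor, the cells *between*
source and receptor (the transport corridor) are crossed by every polluted
trajectory and can score as high as the source cells themselves — the
well-known trailing effect.  The package's end-to-end localization check
therefore uses a compact one-cell source sector at the upwind edge of the
trajectory domain, where the corridor is diluted by clean trajectories but
the sector is not, and breaks score ties toward the cell supported by the
most trajectories.  On real data the same caution applies when reading
WPSCF maps: elongated high-value plumes point *toward* sources rather than
outlining them.

## Health risk

TEQ converts the 16 concentrations to a BaP-equivalent
(`TEQ = sum(C_i * TEF_i)`, ng/m³).  The inhalation risk is

    ILCR = (TEQ * CSF * IR * EF * ED * CF) / (BW * AT)

with the unit convention chosen to make the product dimensionless: TEQ
ng/m³, cancer slope factor CSF = 3.14 (kg·d)/mg, inhalation rate IR m³/d,
exposure frequency EF d/a, exposure duration ED a, conversion factor
CF = 1e-6 mg/ng, body weight BW kg, averaging time AT = 25550 d.  (Published
unit listings for this formula are frequently inconsistent — EF sometimes
appears as h/d — so the convention is stated here once and used
everywhere.)

The default receptor profiles (adult IR 15.7 m³/d, BW 60.6 kg, ED 24 a;
child IR 8.7, BW 21.7, ED 6; EF 350 d/a for both) are placeholders in the
range of the Chinese exposure-factor handbooks, which are not reproduced
here; any real assessment must substitute authoritative values via
`exposure_profile()`.

The Monte Carlo (default 10,000 iterations, seeded) resamples TEQ from the
daily series (or from a fitted lognormal), draws IR and BW from normal
distributions truncated at zero with CV 0.2, and keeps EF and ED fixed —
distribution shapes are again package choices, all configurable.
Sensitivity is the Spearman correlation of each varying input with the
draws plus the variance-contribution normalization `100 * rho^2 /
sum(rho^2)` used by tornado-chart tools.  The 1e-6 acceptable-risk line is
the conventional reference for reading the percentiles.

## Synthetic data generator

The generator exists so that every stage is testable against known ground
truth.  It emulates a six-year, two-site urban campaign: 446 sampling days
× 2 sites = 892 records over 2017–2022, five latent source factors with
marker-structured profiles (biomass burning, gasoline traffic, steel
industry, coal combustion, diesel traffic), winter-peaking seasonal cycles
for the combustion-type factors with slightly staggered peak days (5, 30
and 15 January for biomass, steel and coal), flat cycles for traffic,
independent lognormal day-to-day contribution variation with sdlog 1.0,
multiplicative lognormal measurement noise with CV 0.3, below-MDL
censoring, temperature with a summer-peaking cycle (hence negative rank
correlation with total PAHs), and PM2.5 as total PAHs divided by a mass
ratio of 0.25 ng/µg plus noise.

Two generator choices deserve their rationale.  The contribution sdlog of
1.0 reproduces the strong right skew of real daily series, whose 75th
percentiles run several times the medians; it also keeps the factor
contributions far from collinear.  That matters because phase-locked
seasonal factors with little independent variation make the factorization
rotationally under-determined: many nonnegative decompositions then fit
equally well, and no solver can recover the generating profiles.  Profile
recovery tests are therefore statements about the solver *under
identifiable conditions*, not a guarantee for arbitrary real data, where
collinear sources are a genuine and well-known PMF limitation.

Trajectories are schematic: one per site-day, straight line from a sampled
origin to the receptor (default 40.8°N, 111.7°E) with Gaussian jitter
(sd 0.3°) on the transit points only — origin and receptor anchor the
interpolation.  Exceedance-day origins are drawn from designated source
sectors by emission weight; other days draw uniform origins over the
domain.  No dispersion, wind fields or reanalysis are emulated: PSCF
consumes only endpoint positions, so higher fidelity would not change what
the tests exercise.

What the generator does *not* emulate — serial autocorrelation, shared
meteorological driving of all factors, species-correlated measurement
error, site heterogeneity, long-term emission trends — bounds what passing
tests show about real campaigns.

## Reproducibility and problem sizes

All stochastic stages take explicit integer seeds; the pipeline driver
derives per-stage seeds from one global seed by fixed offsets (synthesis
+1, PMF +2, risk +3...) so stages are independently reproducible.  Results
are written as CSV with 17 significant digits, so a write–read round trip
is exact.

The test-suite and acceptance-script problem sizes are chosen as the
smallest that still exercise the claimed behaviour: PMF profile recovery on
150 samples × 16 species at noise CV 0.10 with 20 starts; the noiseless
factorization limit on campaigns of 20–60 samples; PSCF localization on
five seeded
200-day campaigns at 1° resolution; Monte Carlo risk at the full 10,000
iterations; the full 892-record campaign for descriptive, MDR and risk
quantities.

## Known limitations

* PMF: no bootstrap/displacement error estimation and no rotational
  controls; contribution percentages carry no uncertainty intervals.
* PSCF: the trailing effect discussed above; degree-grid binning treats
  cells as rectangles, adequate at the scales involved but not a geodesic
  treatment.
* Risk: inhalation pathway only; no dermal or ingestion routes, no
  non-cancer hazard quotients; exposure-factor defaults are placeholders.
* MDR: band classifications assume source ratios survive atmospheric
  aging, a strong assumption at long transport distances.
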