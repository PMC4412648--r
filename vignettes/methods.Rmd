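---
title: "Comparing and fusing LUE and DVM productivity estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and fusing LUE and DVM productivity estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luefusion)
```

## The problem

Satellite-driven light-use-efficiency (LUE) models and process-based
dynamic vegetation models (DVMs) are the two workhorse approaches for
mapping terrestrial gross and net primary production (GPP, NPP) at
continental scale. They disagree systematically: LUE products tend to
report higher GPP (especially over cloudy evergreen broadleaf forest,
where their FAPAR input degrades) yet lower NPP, because the two model
families assume very different carbon use efficiencies (CUE = NPP/GPP) —
i.e. different shares of assimilation lost to autotrophic respiration.
`luefusion` provides the machinery to (i) quantify those disagreements
per land-cover class, (ii) fuse the two approaches by applying the DVM's
CUE to the fine-grid LUE GPP, and (iii) validate the products against
in-situ aboveground NPP. This vignette documents the models, the tunable
parameters, the synthetic study domain, and the numerical and design
choices.

## The LUE engine

Daily GPP per cell is

$$\mathrm{GPP} = \varepsilon_{max} \cdot 0.45 \cdot SW_{rad} \cdot
\mathrm{FAPAR} \cdot f(\mathrm{VPD}) \cdot f(T_{min})$$

with $\varepsilon_{max}$ the biome-specific maximum light-use efficiency
(g C MJ⁻¹), $SW_{rad}$ incoming shortwave radiation (MJ m⁻² d⁻¹, 45%
assumed photosynthetically active), FAPAR the fraction of absorbed PAR,
and two *clamped linear ramps*: $f(T_{min})$ rises from 0 at
`tmin_min` to 1 at `tmin_max`; $f(\mathrm{VPD})$ falls from 1 at
`vpd_min` to 0 at `vpd_max`. The ramp form is the standard operational
choice for this model family; since the operational endpoint values are
not part of this package's scope, the shipped BPLUT
(`inst/extdata/bplut_default.csv`) is documented example configuration
producing plausible tropical magnitudes, and users calibrating against a
specific satellite product should substitute their own table via
`read_bplut()`.

### Respiration partitioning

The annual balance is

$$\mathrm{NPP} = \max\!\Big(0,\ \sum_{d=1}^{365} \mathrm{PsnNet}_d -
(R_{mo} + R_g)\Big), \qquad
\mathrm{PsnNet} = \mathrm{GPP} - R_{ml} - R_{mr}.$$

The named components fix the structure but not the sub-model, so the
package adopts the conventional pool-based closure and documents it as
its own choice:

* **LAI from FAPAR** by Beer–Lambert inversion,
  $\mathrm{LAI} = -\ln(1-\mathrm{FAPAR})/k$ with extinction $k = 0.5$
  (FAPAR capped at $1 - 10^{-9}$ to keep LAI finite);
* **leaf carbon** $= 1000 \cdot \mathrm{LAI} / \mathrm{sla}$ (g C m⁻²),
  **fine-root carbon** $=$ leaf carbon $\times$ `froot_leaf_ratio`;
* each pool respires daily at its base rate (g C (g C)⁻¹ d⁻¹, referenced
  to 20 °C) scaled by $Q_{10}^{(T_{avg}-20)/10}$;
* $R_{mo}$ is a per-biome live-wood pool respiring the same way, summed
  annually;
* $R_g = r_g \cdot \max(0, \sum \mathrm{PsnNet} - R_{mo})$ with growth
  fraction $r_g$ (default 0.25).

Daily PsnNet may be negative (high-respiration days); annual NPP is
clamped at zero following annual-product convention, with the unclamped
value retained (`npp_unclamped`) for diagnostics. Consequently the
invariant NPP ≤ ΣPsnNet holds for the unclamped balance everywhere and
for the reported NPP wherever ΣPsnNet ≥ 0. Leap years: a 366-day series
is accepted and the extra day processed; the QC denominator follows the
actual series length. The synthetic generators use 365-day years.

### Gap-fill QC

$QC = 100 \cdot NU_g / TOTAL_g$: the percentage of growing-season days
(all days with $T_{min} > -8$ °C) whose FAPAR input was gap-filled.
Higher QC = poorer input quality. In the emulated tropical domain
$TOTAL_g = 365$ essentially everywhere; if a cell ever has an empty
growing season its QC is reported missing, not zero.

## Grids, masks and zonal statistics

Grids are equal-area, top-left-origin, row-major, cell-center registered;
the source products' projection is carried as a free-text label and never
re-projected. Coarse-to-fine resampling is nearest-neighbour block
replication: the fields are per-area intensities, so replication
preserves their meaning exactly, and area-weighted aggregation of the
children reproduces the coarse cell (tested). Masks of paired products
are always intersected before any statistic, and `Barren`, `Water`,
`Urban` cells — for which the LUE product computes no flux — are dropped
everywhere by default. Cells are treated atomically at coastlines and
class boundaries (no fractional coverage). Per-class totals are
$\sum v \cdot A_{cell}$ converted at 1 Pg = 10¹⁵ g; an empty class
reports a missing mean (never 0) and a zero total, so the sum of class
totals always equals the domain total.

Raster exchange uses the Esri ASCII grid: a plain-text single-band format
whose 17-significant-digit values round-trip doubles exactly, with a JSON
sidecar for units, CRS label and cell area. Land cover is an
integer-coded grid plus a JSON legend.

## Fusion

The CUE field is the *ratio of multi-year means* per coarse cell,
$\overline{\mathrm{NPP}} / \overline{\mathrm{GPP}}$ — not the mean of
annual ratios; the two differ whenever GPP varies between years, and the
ratio-of-means form is the one the fused product is defined by. CUE is
computed on the coarse grid first and then resampled (under
nearest-neighbour replication the order is numerically irrelevant, but it
is fixed this way for auditability). `NPP_Combined = GPP_fine × CUE`
cell-wise. DVM cells with negative NPP keep their ratio but are flagged
(`flagged_negative`); an optional clamp of ratios into [0, 1] is off by
default and logs how many cells it touches. No QC-based masking is
applied to the fused product. No feedback of fused NPP into respiration,
and no per-year fusion — only the period-mean ratio.

## Comparison machinery

Annual continental totals, per-class and continental period means/totals
and their differences (always A − B, exactly antisymmetric), and CUE
summaries computed from *totals* (Σ NPP / Σ GPP), not area-weighted means
of cell ratios. Significance per class uses a **paired two-sided t-test
on co-located cell period means** — the natural pairing since both
products cover identical cells after harmonization; a Welch two-sample
variant is available. The sampling unit (cells, not years or cell-years)
and the absence of multiple-testing correction across classes are
recorded in the report metadata. A constant non-zero per-cell difference
has no usable variance; that degenerate case reports p = 0 with a flag
rather than an unstable statistic. The inter-product relation is
summarized as `100 × CUE_A / CUE_B` (e.g. 0.46 / 0.58 ≈ 79%), and annual
anomalies as `100 × |annual − mean| / mean`, rounded to one decimal for
reporting only.

## Validation

Sites (~300 × 300 m plots, sub-cell at any resolution handled here) map
to the single cell containing their coordinate under half-open cell
intervals — no interpolation. `same_year` mode pairs each site with its
sampling year's cell value; `period_mean` mode with the cell's mean over
the period, excluding sites whose cell lacks valid data in *any* year.
Exclusions are bookkept with reasons, never fatal, and
n + |excluded| = |sites| always. Dry biomass converts to carbon at 50%,
guarded against double conversion. The systematic offset between
aboveground NPP (what field plots measure) and total NPP (what the models
produce) is *not* corrected — the generator's `aboveground_fraction`
exists to emulate it, and correcting it in the statistics would hide a
real property of such comparisons. Agreement is Pearson *r* plus
RMSE = √(mean(predicted − observed)²) on g C m⁻² yr⁻¹.

## The synthetic study domain

The generators emulate the structure of an African-style domain, not its
geography:

* **Land cover**: class areas scaled from the study-area listing
  (savanna 5.6, woody savanna 3.9, open shrubland 3.7, evergreen
  broadleaf forest 3.0, grassland 2.2, cropland 0.89, closed shrubland
  0.18, minor forest types 0.37 combined, barren 9.8, water 0.25, urban
  0.054 — in million km², ~30 total), allocated by largest remainder
  (every class within one cell of its quota), laid out as north–south
  bands (desert north, forest near the "equator") and speckled by seeded
  disjoint-pair swaps, which preserve the quotas exactly.
* **Meteorology**: seasonal sinusoids (stated in closed form in
  `?generate_meteo`, and tested against them at zero noise) with VPD
  anti-correlated with a 200 → 600 mm yr⁻¹ north-to-south precipitation
  gradient; the domain is tropical, so Tmin never nears −8 °C.
* **FAPAR**: class-specific seasonal curves bounded in [0, 1]; each
  cell-day is gap-filled with a per-class cloud probability (0.65 for
  EBF, matching the rate the QC metric should recover); flagged days
  carry the smooth curve as the interpolation stand-in, the fill method
  itself being outside the QC contract.
* **DVM product**: coarse cells take their block's majority fine class;
  GPP is the class mean (LPJ-style values, e.g. EBF 1.61 kg C m⁻² yr⁻¹)
  with a small interannual factor and multiplicative noise; NPP is GPP ×
  the prescribed class CUE (0.55–0.62, GPP-weighted mean ≈ 0.58) with
  independent half-amplitude noise — so zero noise recovers the
  prescription exactly.
* **Sites**: 35 by default, spread along the gradient, 4 deliberately on
  masked cells to exercise exclusion; observed ANPP =
  `aboveground_fraction` × cell NPP × noise, stored as biomass (twice
  the carbon value).
* **Noise** is multiplicative lognormal with mean 1 and stated relative
  SD (default 0.05), chosen to keep fluxes positive.

The LUE-side product is generated by *running the LUE engine* on the
synthetic drivers — not by prescribing its fields — with the domain CUE
calibrated to its 0.46 target by a one-dimensional bisection on a global
growth-respiration fraction override (`tune_rg_frac()`, tolerance 10⁻³ on
$r_g$; the domain CUE is monotone decreasing in $r_g$, so the solve is
unconditional, and unattainable targets fall back to the nearest endpoint
with a warning). Calibrating $r_g$ rather than the maintenance rates
keeps one interpretable dial and reuses the cached annual components, so
no daily recomputation is needed.

### What passing tests do and do not show

The synthetic domain exercises every contract — unit conversions, mask
algebra, CUE recovery, QC counting, exclusion bookkeeping, determinism —
but it is *not* real data: drivers are smooth sinusoids, noise is
uncorrelated between cells and days, land-cover classes are bands with
speckle rather than realistic patch structure, FAPAR gaps are independent
Bernoulli draws rather than persistent cloud systems, and the DVM product
is statistically prescribed rather than process-simulated. Recovery of
prescribed parameters on this domain demonstrates correctness of the
machinery, not skill of the models on real observations.

## Reproducibility and problem sizes

Every generator derives its RNG stream from the single configured seed
plus a fixed per-generator offset; two runs with one seed produce
bit-identical output files, verified by MD5 in the run manifest (which
deliberately contains no timestamps — config hash, seed, versions and
per-file checksums only). The default domain is 120 × 120 fine cells,
coarse factor 10, three years — sizes chosen so class statistics are
well-populated while a full end-to-end run completes in seconds; the test
suite uses 40 × 40 domains for the same reason. All statistics retain
full precision internally; rounding (one decimal for Pg-scale summaries,
three for CUE) is applied at reporting only.

## Known limitations

* No reprojection, mosaicking, or multi-band rasters; grids must nest
  exactly for resampling.
* The raster format is text-based ASCII grid — robust and exact, but
  larger on disk than binary formats.
* Spatial autocorrelation is ignored by the per-class t-tests (cells are
  treated as independent), matching standard practice in such
  comparisons but inflating significance on smooth fields.
* Meteorology enters on the fine grid as given; no reanalysis
  interpolation is emulated.
* The respiration closure is a conventional pool model with configurable
  rates, not a calibrated reproduction of any operational product's
  coefficients.
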