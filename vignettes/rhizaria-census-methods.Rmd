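---
title: "Methods: from imaged Rhizaria to global carbon and silica budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from imaged Rhizaria to global carbon and silica budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizcensus)
```

## The estimation problem

Large planktonic Rhizaria (0.6–20 mm) are too fragile for nets and too
sparse for bottle sampling; in situ imaging by the UVP5 — roughly one
litre imaged every few centimetres of a vertical cast — is the only
quantitative window on them. The census problem is to go from such
object tables (one row per imaged organism) to global element budgets:
how much organic carbon and biogenic silica do these protists hold, how
much carbon must mesopelagic flux-feeding Phaeodaria ingest, and what
share of the sinking POC flux does that demand represent?

The chain implemented here is: morphometry → allometric elemental
content → temperature-scaled physiological rates → per-profile and
per-cell concentrations → boosted-regression-tree habitat models →
integrated budgets. Each link is an exported function; the staged
pipeline (`run_stage()`) and the synthetic world tie them together.

## Morphometry and the volume-convention choice

`esd_from_area()` inverts the circle: ESD = √(4A/π). Biovolume is where
a genuine ambiguity lives: the census literature's printed sphere
equation reads V = 4/3·π·ESD³, which is exactly 8 times the geometric
sphere volume 4/3·π·(ESD/2)³. Both are first-class in
`sphere_volume()`; the package default is `"as_printed"`, for
consistency with the published equation chain, and every downstream
default is documented against that choice. Because the allometries are
power laws, the convention shifts contents by a constant factor
(8^0.455 ≈ 2.6 for carbon), not by shape; sensitivity runs need only
flip one argument. The size window 0.6–20 mm is applied inclusively at
both bounds (`size_filter()`), since the source range is quoted without
bracket convention.

## Allometric contents and the volume-unit question

Carbon: Q_C = 10^0.958 · V^0.455 µg C cell⁻¹; silica (Phaeodaria only,
since all Phaeodaria silicify while silicified Collodaria cannot be
recognized on UVP5 images): Q_bSi = 10^−4.05 · V^0.52 µg Si cell⁻¹.
The literature states V in µm³ for the carbon relation but mm³ for the
silica one. Taken literally, µm³ in the carbon relation gives ~0.2 g C
for a 1-mm cell — five orders of magnitude above any measured content
— whereas mm³ gives ~17 µg C, consistent with the low cellular carbon
density these organisms are known for. The package therefore evaluates
both allometries with V in mm³ by default; the unit is a declared field
of `allometric_params()`, mismatches between data and parameters are
errors rather than silent conversions, and the exact factor 10^(9b)
between unit declarations is asserted in the tests.

## Physiological rates

Turnover time is scaled to local temperature with a Q₁₀ of 2 around a
10 °C reference: τ_T = τ·2^((10−T)/10), with the reference τ = 10.9 d
and quartiles 8.4 / 17.4 d spanning the observed range; carbon demand
is CD = Q_C/(GGE·τ_T) with GGE = 0.4 (an energy-sparing value
appropriate for food-depleted mesopelagic flux-feeders; 0.2 doubles
every demand-derived number, a sensitivity carried through to the
attenuation envelope). Silica production scales the reference rates
{0.17, 0.54, 1.78} nmol Si cell⁻¹ d⁻¹ by the same Q₁₀ law. The source
labels that triple "minimum, maximum, and median", which is not a
consistent ordering; the package deliberately stores it as
low/mid/high without guessing which is the median, and budget reports
carry all three. Demand is restricted to mesopelagic Phaeodaria by
default — epipelagic Phaeodaria also feed, so the default is
conservative; `include_epipelagic_demand = TRUE` lifts the restriction.

Temperature lookup (`clim_lookup()`) uses the nearest grid node in
latitude, longitude and month, linear interpolation in depth, and holds
the deepest level constant below it (nutrient climatologies stop at
800 m while objects reach 1000 m).

## Gridding decisions

Profiles are binned to cells by the floor convention; casts falling on
a masked cell move to the nearest ocean cell by great-circle distance
(ties to the lowest cell index, deterministically), mirroring the
coastline mismatch of real climatologies. Depth layers are half-open —
an object at exactly 200 m is mesopelagic. Per-profile concentration is
Σq/Σv within the layer, so a sampled-but-empty layer is a structural
zero and stays in the training data. Two open choices are exposed
rather than hidden:

- **Averaging weights.** Whether cell averaging weights profiles
  equally or by imaged volume is not settled usage; the default is the
  unweighted per-profile mean (the commoner choice in the UVP
  literature), while `weighting = "volume"` makes the cell value the
  pooled Σq/Σv, under which total mass is conserved exactly — the
  identity the conservation tests assert to machine precision.
- **Partial casts.** Profiles contribute to a layer only if their
  volume bins span ≥90% of its depth range (`coverage`, configurable):
  a cast to 500 m should not stand in for a 200–1000 m mean.
- **Chlorophyll predictor.** WOA-style predictors are averaged over the
  layer's depth range and the climatology's months; surface
  chlorophyll-a is likewise used as its climatological month-set mean.
  Using each cell's sampled months instead would add sampling-season
  noise without changing the expectation; the month-mean convention
  also makes the synthetic world's true response an exact function of
  the table's predictors, which is what the recovery tests need.

## Distribution models

`xgboost` gradient boosting with the fixed hyperparameter set: learning
rate 0.08, maximum depth 2, minimum 1 element per leaf, exactly 500
trees, no early stopping, fit on untransformed concentrations (a
`log1p` transform of responses is trivially applied upstream if
desired). Ensembles of 20 repeats differ in seed and in per-tree row
subsampling (`subsample = 0.75`); with full-sample deterministic
boosting all repeats would be identical and the prediction SD maps
degenerate, so the subsample fraction is the explicit source of
ensemble spread. Cross-validation re-draws folds each repeat (seeded):
`random` assigns observations to 5 folds uniformly; `spatial` groups
cells into 15° blocks (size configurable; block centroids assigned
greedily, largest block to the smallest fold, after a seeded shuffle)
so that test cells are geographically separated from training cells.
Skill is the squared Pearson correlation between observed values and
the per-observation mean of held-out predictions; models above R² =
0.05 under random CV carry a display flag. A constant response yields
`NA` skill with a message, never a silent 0. Negative ensemble-mean
predictions are floored at zero before integration — concentrations
are nonnegative and depth-2 boosting can slightly overshoot near zero.

Spatial CV is expected to score at or below random CV on spatially
autocorrelated data, because held-out blocks remove the short-range
interpolation advantage; the tests assert this as a tendency over ten
simulated worlds with spatially correlated disturbances, not per run —
on any single world either scheme can win by a small margin.

## Budgets

Integration is the exact product concentration × thickness (200 m
epipelagic, 800 m mesopelagic; the top-500 m stock uses
epi×200 + meso×300). Cell areas use the spherical band formula with
R = 6371 km; the band sum closes to 4πR² to 1e-6 relative, which is
tested. Global sums apply per-cell mean ± SD bounds (floored at zero)
before summation; regional sums over any partition add up to the
global sum to machine precision. Attenuation is
100·demand/export against the median of a literature export set, with
the range from its extremes; export values are configuration inputs
with source labels, never constants in code. One worked identity
deserves a note: with a printed demand of 0.46 Pg C y⁻¹ (itself
rounded) the τ-quartile envelope evaluates to 11.94% at the upper end,
which print conventions show as 12.0%.

## The synthetic world: what it does and does not emulate

`generate_climatology()` builds smooth latitude/depth/season fields —
temperature strictly decreasing down every column toward a deep value,
chlorophyll with equatorial and subpolar bands, nutrient fields
increasing with depth and latitude — plus a seeded random land mask
(20% of cells). `sample_profiles()` places casts uniformly on ocean
cells and draws object counts per 25-m bin as Poisson with rate = true
response × imaged volume (0.01 m³ per metre of descent), ESDs from
taxon-specific lognormal spectra truncated to 0.6–20 mm, and pixel
areas back-computed so `esd_from_area()` inverts the drawn ESD exactly
(pixel size 0.088 mm px⁻¹). The true response is log-linear in
temperature and log₁₀ chlorophyll with one interaction and a per-layer
offset; its coefficients live in the spec object, and
`true_budget()` gives the implied global stocks in closed form via the
truncated-lognormal moment identity — the analytic target of the
recovery tests.

Deliberately not emulated: seasonal succession, patchiness beyond
Poisson counting noise, taxon misclassification, vignetting or any
image-level effect, and spatially correlated sampling effort (real
cruises cluster; synthetic casts are uniform). Passing recovery tests
therefore demonstrate that the pipeline's transformations are
correct and that the models can recover a known smooth
environment→biomass mapping from realistically sparse, noisy counts —
not that the boosted trees would attain any particular skill on real
ocean data, where the response is rougher and the sampling biased.

## Problem sizes and numerical choices

The default synthetic world runs on a 2° grid (80×180 cells, 9 depth
levels to 800 m, 12 months, two taxa); validation runs use 300–500
casts, and the skill/recovery checks use 500-row tables with 5–20
ensemble repeats — sizes chosen so the full suite exercises every
stage, including 200-fit cross-validation loops, in well under an
hour on a single core while leaving Monte-Carlo noise far below the
tolerances asserted. Seeds are explicit everywhere: the same spec and
seed reproduce climatologies, object tables, fold draws, model fits
and maps bit-identically on one platform. Tolerances in the tests are
1e-9 relative for closed-form equations, machine precision for the
algebraic identities (conservation, regional additivity), and
statistical (3 SE, or 5–20%) only where sampling noise is the object
of the test. Climatologies serialize to long-format CSV
(`write_climatology_csv()`), object tables to the tab-separated
EcoTaxa dialect, and configurations to YAML, keeping every artifact
plain text and diffable.

## Known limitations

- Silicified and naked Collodaria cannot be distinguished, so
  Collodaria silica is (conservatively) not estimated.
- The carbon-demand budget excludes epipelagic Phaeodaria by default
  and stops at 1000 m; both choices bias demand low.
- Predictions extrapolate wherever the environmental grid leaves the
  sampled predictor range; spatial-CV skill is the honest (and
  pessimistic) gauge of that extrapolation.
- The Q₁₀ scaling assumes a single temperature sensitivity across all
  phaeodarian taxa and the same reference turnover for all of them.
- The attenuation ratio compares a demand to an export flux; it is an
  upper bound on interception, not a particle-tracking estimate.
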