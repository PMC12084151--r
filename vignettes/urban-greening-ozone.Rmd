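---
title: "From urban greening to ozone mortality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From urban greening to ozone mortality: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenozone)
library(dplyr)
```

## The problem

Urban green space emits biogenic volatile organic compounds (BVOCs),
dominated by isoprene. Dense city cores are typically VOC-limited
photochemical regimes, so adding reactive carbon there increases ozone
production even though urban vegetation is a small share of a
metropolitan region's total biogenic emissions. greenozone implements the
full desk-scale chain needed to study this effect: land-cover fusion at
street-tree resolution, MEGAN-form isoprene emissions, MDA8 ozone
exposure metrics on a paired scenario difference, and an
attributable-mortality calculation that isolates the urban-greening
share of the ozone health burden.

Regional chemistry transport is deliberately out of scope. The package
replaces that step with a synthetic scenario-field generator whose
injected structure is known exactly, which is what makes every
downstream statistic testable: the pipeline must recover what the
generator put in.

## Land cover, PFTs and LAI

Two land-cover streams are fused on the analysis grid. Outside the urban
mask, per-cell fractions $\chi_j$ of 16 plant functional types (PFTs)
are used as supplied (in real applications these come from coarse
satellite PFT products; the mapping from an 8-class product ships as an
editable CSV). Inside the urban mask, where coarse products miss street
trees and parks entirely, a fine (10 m by default) raster of four
vegetation classes is aggregated: $\chi_j$ is the exact areal fraction
of fine cells of each class within the coarse cell. Urban tree cover is
assumed broadleaf; whether it is evergreen or deciduous follows
latitude, with a configurable cutoff defaulting to 30° (the
subtropical/temperate divide: a ~23°N city gets evergreen, a ~40°N city
deciduous). The rule is stated by the underlying methodology; the
numeric cutoff is our documented choice, not an assertion about any
particular dataset.

Leaf area index is assigned per cell as $\mathrm{LAI} = \sum_j \chi_j\,
\mathrm{LAI}_{\mathrm{ref}}(j)$ from an editable per-PFT reference
table; it is linear in $\chi$ and zero where nothing grows. Area
bookkeeping is conserved exactly: summed urban $\chi$ equals the fine
raster's vegetated fraction.

## Emissions

The emission flux of species $i$ is

$$F_i = \gamma_i \sum_j \varepsilon_{i,j}\,\chi_j,\qquad
\gamma_i = C_{CE}\,\mathrm{LAI}\,
\gamma_L\,\gamma_T\,\gamma_{LA}\,\gamma_{SM}\,\gamma_{CI}.$$

The light and temperature activities use the standard MEGAN closed
forms:

$$\gamma_T = \frac{E_{opt}\,C_{T2}\,e^{C_{T1}x}}
{C_{T2}-C_{T1}\left(1-e^{C_{T2}x}\right)},\quad
x=\frac{1/T_{opt}-1/T}{0.00831},\qquad
\gamma_L = \frac{C_p\,\alpha P}{\sqrt{1+\alpha^2P^2}}$$

with defaults $C_{T1}=95$, $C_{T2}=230$, $T_{opt}=313\,$K,
$E_{opt}=2.037$, $\alpha=0.004$, $C_p=1.21$ — transcribed into an
editable parameter list and verified in the tests against an independent
transcription. $\gamma_{LA}$, $\gamma_{SM}$ and $\gamma_{CI}$ default to
1 because the synthetic pipeline carries no leaf-age, soil-moisture or
CO$_2$ driving data; each is overridable. $C_{CE}$ defaults to the value
that makes $\gamma = 1$ at standard conditions (LAI 5, 30 °C, PAR
1000 µmol m$^{-2}$ s$^{-1}$), computed at call time rather than
hard-coded. Leaf temperature is approximated by 2 m air temperature (no
canopy model). Only isoprene is computed by default; other species enter
through additional emission-factor columns.

Seasonal budgets integrate flux × cell area × 1 h to Gg and split
exactly into urban + non-urban parts.

## MDA8 and the scenario difference

MDA8 is the daily maximum of 8-hour running means. The recipe is the
common regulatory convention, stated here because conventions differ: 24
windows per day starting 00:00–23:00 local, a window belongs to its
start day and may draw hours from the next day, hours past the end of
the series are missing, a window needs ≥ 6 of 8 valid hours, a day needs
≥ 18 valid windows. The implementation is a rolling-sum matrix engine;
the tests hold it to *exact* agreement with an exhaustive per-window
scan, including missing-data handling.

The scenario pair ("Base" without urban BVOC emissions, "UG" with them)
is differenced per cell after dropping the first 4 days as spin-up.
Relative changes use the Base seasonal-mean MDA8 as denominator.
Correlation with temperature uses daily urban-mean values by default
(all-cell means behind a flag), Pearson $r$ with a two-sided t-test.

## Health burden

Exposure at concentration $C_g$ carries relative risk
$RR(C_g) = rr^{(C_g - C_0)/10}$ above the theoretical minimum-risk
concentration $C_0 = 32.4$ ppb and exactly 1 at or below it. With
population $P_{g,j}$ and reported annual incidence $I_{i,j}$, the
underlying incidence is $\hat I_{i,j} = I_{i,j}/\overline{RR}$ where
$\overline{RR}$ is the population-weighted mean RR, and attributable
deaths are

$$M_{i,j} = \sum_g P_{g,j}\,\hat I_{i,j}\,(RR(C_g)-1).$$

Defaults: $rr = 1.06$ per 10 ppb for COPD (editable, never baked into
results), exposure metric = seasonal mean of daily MDA8, seasonal
scaling = annual incidence × season_days/365. Whether a summer burden
should scale incidence seasonally or apply full-year incidence to summer
exposure is genuinely ambiguous; both are available through
`season_days` (92-day summer vs 365) and the default pipeline uses the
retained-day count. Urban-greening attribution computes the burden
independently for both scenario exposures and reports
$(M_{UG}-M_{Base})/M_{UG}$, which lies in $[0,1]$ whenever the UG
exposure dominates cellwise.

## What the synthetic generator emulates

The generator reproduces the statistical structure the analysis relies
on, not the physics that produces it in reality:

* **Land cover**: vegetation inside the urban mask appears as clustered
  circular patches (Poisson-placed centers, one class per patch, 200 m
  default radius). The patch count is chosen in closed form,
  $n = -A/a \cdot \log(1-p)$, so expected coverage equals the target
  fraction; coverage 0 and 1 are exact. The default urban mix is
  tree-dominant (70% tree), reflecting street-tree-led greening; the
  default periphery is crop/grass-dominated with forest thickening
  toward the rural fringe, which places the urban share of domain
  isoprene emissions near 15% — the ballpark reported for Chinese
  megacities.
* **Meteorology**: daily-mean temperature 27 ± 2.5 °C (so a 92-day
  summer contains hot days above 30 °C), a 5 °C cosine diurnal cycle
  peaking at 14:00 whose daily mean is exactly the drawn value, PAR as a
  clear-sky half-sine scaled by a daily cloud factor, and a separable
  1 °C urban-heat-island offset. The recipes and their seed streams are
  documented so tests can re-simulate them independently.
* **Ozone**: Base is a mid-afternoon-peaking diurnal cycle with a
  temperature-driven day effect and additive Gaussian noise (2 ppb,
  clipped at zero). The UG enhancement is
  `amp × kernel × (1 + temp_coupling (T_d − T̄)) × lognormal noise`,
  with the kernel an urban Gaussian stretched downwind of a constant
  wind vector. The enhancement is applied as a *day-constant* increment
  per cell: a constant added to every hour of a day shifts that day's
  MDA8 by exactly itself (the maximizing window cannot change among
  same-day windows), so the amplitude can be calibrated in closed form
  to make the noise-free urban-mean ΔMDA8 equal the injected target.
  A diurnally shaped enhancement would be more realistic but would make
  the injection target approximate; exactness was judged more valuable
  for a generator whose purpose is recovery testing.
* **Population**: Gaussian-decaying density (σ = 0.6 × urban radius)
  over a uniform rural floor carrying ~10% of the mass, normalized
  exactly to the configured total; well over half the population falls
  inside the urban mask, which is what makes population-weighted
  exposure exceed the simple spatial mean, as in real megacities.

What passing tests therefore show: the *pipeline machinery* — fusion
arithmetic, emission algebra, MDA8, health equations, attribution — is
correct and recovers known structure through realistic noise. What they
do not show: anything about real chemistry (the ΔO₃–temperature link is
injected, not photochemical), real meteorology, or real land cover.
Headline numbers from cluster-scale chemistry-transport studies are not
reproducible at desk scale and are not targets here.

## Numerical choices and degenerate inputs

* Fixed seed ⇒ bit-identical outputs; every stochastic recipe draws
  from its own derived seed stream (`seed + fixed offset`).
* Wind climatology per city is unknown; a single constant wind vector
  per run is exposed instead of a guessed rose.
* Zero injected enhancement short-circuits to *identical* Base/UG
  fields, so downstream zeros are exact, not approximate.
* Degenerate correlation inputs (constant Δ or constant temperature)
  return `NA` rather than a spurious coefficient; fewer than 3 days is
  an error.
* Cells with zero Base MDA8 are excluded from relative-change
  statistics; zero total population is an error everywhere it would
  divide.
* Grid convention: regular lattice, cell-center coordinates in km,
  row 1 southernmost; latitude is assigned per row at ~111.32 km/degree.

## Problem sizes

The shipped study conditions are a 50 × 50 km domain at 1 km analysis
resolution with a 10 m urban land-cover layer and a 92-day summer (4
spin-up days dropped). The recovery checks in the test suite run the
same domain over 30 days; both sizes run in well under a minute per
pipeline pass on a single CPU.

## A short worked run

```{r, eval = FALSE}
res <- run_pipeline(seed = 1)
glance(res)            # one-row summary of every headline quantity
stratify(res$exposure) # urban vs suburban boxplot statistics
autoplot(res$exposure) # map of the seasonal MDA8 enhancement
plot_temperature_relationship(res$temperature)
```

## Known limitations

No chemistry: the generator injects a positive, temperature-coupled,
downwind-advected enhancement by construction, so regime questions
(VOC- vs NOx-limited) are outside what this package can answer. No
uncertainty propagation on incidence or relative risk. Single-epoch
LAI (no phenology within a season). Age structure is supported in the
health equations but the default synthetic data uses one aggregate
group.
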