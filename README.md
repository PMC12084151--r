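# greenozone

Urban green space emits biogenic volatile organic compounds (BVOCs) —
mostly isoprene — and city cores are typically VOC-limited, so street
trees and parks can *raise* summer ozone and its health burden even
though they are a small share of a region's biogenic emissions.
greenozone is a tidyverse-style R package for quantifying that chain at
desk scale, for air-quality and environmental-health researchers:

1. **Land cover** — fuse a fine (10 m) urban vegetation raster with
   coarse plant-functional-type (PFT) fractions; assign leaf area index
   (LAI) from editable per-PFT tables.
2. **Emissions** — MEGAN-form isoprene flux
   `F_i = γ_i Σ_j ε_ij χ_j`, with
   `γ_i = C_CE · LAI · γ_L · γ_T · γ_LA · γ_SM · γ_CI`, and seasonal
   Gg budgets split into urban/non-urban parts.
3. **Ozone exposure** — MDA8 (daily maximum 8-hour mean) on a paired
   scenario difference (Base = no urban BVOC emissions, UG = with
   them), with urban/suburban strata, a temperature relationship
   (Pearson r), and population-weighted exposure.
4. **Health burden** — attributable mortality
   `M = Σ_g P_g · Î · (RR(C_g) − 1)` with log-linear
   `RR(C) = rr^((C−C0)/10)` above the minimum-risk concentration
   `C0 = 32.4` ppb, underlying incidence `Î = I / RR̄`, and the
   urban-greening share `(M_UG − M_Base)/M_UG`.
5. **Synthetic data** — a generator producing all inputs (clustered
   urban vegetation, meteorology, scenario pair with a known injected
   enhancement, population, incidence), so the whole pipeline runs and
   is testable offline and parameter recovery can be verified.

All user-facing functions take data frames first and return tibbles;
results have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
ggplot2 graphics.

## Worked example

```r
library(greenozone)

res <- run_pipeline(seed = 1)   # default 50x50 km, 92-day summer domain
glance(res)
```

```
 urban_delta_ppb suburban_delta_ppb urban_rel_pct pearson_r     pearson_p
        3.610701           1.018622      4.739903 0.9986771 1.235235e-112
 pop_weighted_delta_ppb mean_delta_ppb emission_urban_fraction
               3.241849       1.760994               0.1539512
 emission_total_gg deaths_base deaths_ug deaths_attributed attribution_fraction
          2.448263    173.3366  184.5581          11.22152            0.0608021
```

Reading this: the generator injected a 3.6 ppb urban-mean MDA8
enhancement and the analysis recovered 3.61 ppb (a 4.7% relative
increase over the Base seasonal mean), stronger in urban than suburban
cells (1.02 ppb). The daily enhancement tracks daily-mean temperature
(r ≈ 1.00 here because the synthetic coupling is strong and clean).
Population-weighted exposure (3.24 ppb) exceeds the simple spatial mean
(1.76 ppb) because people and the enhancement are co-located in the
core. Urban areas contribute 15.4% of the domain's 2.45 Gg summer
isoprene. Of 184.6 ozone-attributable COPD deaths in the UG scenario,
11.2 (6.1%) are attributable to urban-greening BVOCs.

Individual stages are ordinary functions — e.g.
`mda8()`, `delta_mda8()`, `stratify()`, `population_weighted_mean()`,
`attributable_mortality()`, `attribute_to_urban_greening()` — and can
be applied to your own tibbles with the documented column contracts.
See `vignette("urban-greening-ozone")` for the models, assumptions and
design choices.

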