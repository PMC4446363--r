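---
title: "Simulating grassland management and carrying capacity with grassim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating grassland management and carrying capacity with grassim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassim)
```

## The problem

Grassland feeds ruminant livestock through two channels: grazing during the
vegetation period and conserved (mown) forage outside it. How many animals
a hectare of grassland can support — its carrying capacity — therefore
depends jointly on how productive the sward is, how the year splits into
grazing and indoor-feeding seasons, and how land is divided between mowing
and pasture. `grassim` implements this management layer as a set of small,
separately testable components on top of a deliberately minimal daily
grass-growth substrate, so that the management logic (harvest rules,
stocking optimization, adaptive herd dynamics, driver attribution) can be
studied, and unit-tested, without a full land-surface model.

## The growth substrate and its assumptions

The substrate tracks four pools per cell — shoot biomass, root biomass
(kg DM ha⁻¹), litter carbon (g C m⁻²) and a soil water store (mm) — at a
daily step on a 365-day calendar (no leap days, so annual feed bookkeeping
uses exactly `T_year` = 365).

Gross primary production is the minimum of an electron-transport-limited
rate (proportional to `Jmax`, saturating in shortwave radiation) and a
Rubisco-limited rate (proportional to `Vcmax`), attenuated by

* canopy closure `1 − exp(−k·LAI)` with LAI derived from shoot biomass via
  the specific leaf area and a 0.45 g C / g DM carbon fraction;
* a quadratic thermal optimum peaking near 18 °C and reaching zero around
  −5 °C — a temperate C3 grass response;
* bucket-soil water stress (linear below 40 % of a 150 mm capacity);
* a Michaelis-type CO2 response normalized to 1 at 380 ppm; and
* the nitrogen capacity enhancement described next.

NPP subtracts a fixed growth-respiration fraction of GPP and a
temperature-dependent maintenance term; positive NPP is allocated 60:40 to
shoot and root, negative NPP drains root reserves first. First-order
senescence (faster outside the thermal optimum) feeds the litter pool,
whose temperature-dependent decomposition is the heterotrophic respiration
of the NEE proxy used by the spin-up. A small crown/stubble floor
(30 kg DM ha⁻¹) is exempt from senescence and carbon drain so swards regrow
after winter dieback — without it a cold-winter cell would lose its canopy
irreversibly. Evapotranspiration scales with radiation, temperature and
vapour-pressure-like humidity deficit; a daily drainage/soil-evaporation
fraction empties the bucket under persistent drought, which is what lets a
rain-free year collapse production (the suite asserts annual NPP below 20 %
of the well-watered value on the same forcing).

The substrate is a *contract*, not a contribution: any model producing
daily NPP and shoot biomass that responds positively to light, CO2 and
nitrogen and negatively to water stress can replace it, and every
management-layer result in this package is defined against that contract.
Its constants were calibrated once so that a temperate cell yields annual
NPP of roughly 400–650 g C m⁻² yr⁻¹, 2–4 mowing events and cut yields of
2–7 t DM ha⁻¹ yr⁻¹, with mediterranean cells strongly water-limited and
cold cells season-limited.

## Nitrogen response

Annual nitrogen addition `N_amount` — organic plus mineral fertilization
plus atmospheric deposition, recomputed each year — raises both
photosynthetic capacities by the saturating fraction

$$N_{add} = N_{addmax}\,(1 - a^{N_{amount}/30}), \qquad a = 0.75,\;
N_{addmax} = 0.6,$$

so `Vcmax = (1+N_add)·Vcmax*` and `Jmax = (1+N_add)·Jmax*`. The asymptote
is a ~60 % capacity increase under very high nitrogen supply; half the
asymptote is reached near 70 kg N ha⁻¹ yr⁻¹. Only photosynthetic capacity
responds to nitrogen — SLA and allocation do not.

## Management rules

**Mowing.** Whenever shoot biomass exceeds the trigger (default
2000 kg DM ha⁻¹) it is cut back to the residual stubble (500 kg DM ha⁻¹).
A salvage cut recovers standing biomass above residual + 100 kg DM ha⁻¹
once growth has ceased for five consecutive days, with a year-end backstop.
The trigger/residual defaults were chosen to give ~2–4 cuts per year under
favorable forcing; both are configurable.

**Grazing.** Daily ingestion is `min(IC·S, e·(shoot − 300))` per grazed
hectare, where `IC = 13` kg DM LSU⁻¹ d⁻¹ and `e = 0.7` is the grazing use
efficiency: the gross removal is ingestion divided by `e`, the remainder
representing trampling and fouling losses. This single factor stands in
for the qualitative defoliation/trampling feedbacks of more detailed
models and reproduces the direction of the lower herbage-use efficiency of
grazing relative to cutting. Grazing stops when shoot biomass falls below
300 kg DM ha⁻¹ (applied to total shoot biomass) and resumes only after 15
consecutive days above it; the recovery wait applies to grazing-driven
stops, not to the first spring turn-out.

**Seasons.** The vegetation period is the longest run of days with
positive net shoot growth after 5-day *median* smoothing. A median is used
deliberately: it bridges gaps of up to two days and removes isolated
spikes without extending the run's support, so the period's length equals
the raw run length in the unambiguous case (a mean-filter would lengthen
it at both edges). The grazing season opens at turn-out — the first
vegetation-period day with biomass above the grazing threshold — and every
day an animal is not on pasture counts toward `T_farm`, the indoor feeding
period that the winter-feed balance charges against mown forage.

## The farm optimum

With `Y_graze(S)` the simulated annual ingestion per grazed hectare and
`Y_cut` the annual mown yield per cut hectare (computed once per cell —
cut land carries no animals), the optimizer finds the largest `S` whose
grazing-season demand `IC·(365 − T_farm)·S` is still met by `Y_graze(S)`
within tolerance (`(1 − T_farm)` in the season balance is read as
`365 − T_farm` days, the only dimensionally consistent reading), then sets
the grazed fraction from the winter-feed balance

$$F_{opt} = \frac{Y_{cut}}{IC \cdot T_{farm} \cdot S_{opt} + Y_{cut}},
\qquad D_{opt} = S_{opt} F_{opt}.$$

Because ingestion equals demand exactly while the sward can always feed
the herd, and falls short once availability limits intake, the demand
residual is zero up to a capacity boundary and grows beyond it; the solver
sweeps S geometrically (×1.25 on the scalar path) and bisects that
boundary. At a plateau the smallest S achieving the maximal density is
returned. Degenerate cells (no yield, or no grazing season) return zeros
rather than errors. Multi-year calls average yields over the supplied
window. An exhaustive (S, F) lattice search maximizing `D = S·F` under
both balances is shipped as an independent oracle; the test suite checks
the iterative solver against it on 50 random cells with S-independent
yields, where the optimum also has a closed form.

## Adaptive density dynamics

At the end of each year the realized density change is
`ΔD = α·(X′ − X)/IC/365` with `X′ = Y_cut·(1 − F)` the cut-forage
production and `X = IC·T_farm·S·F` the indoor demand, both per farm
hectare. α = 0.2 is the moderate-risk fraction of the maximal correction —
equivalent to tracking a roughly five-year mean productivity rather than
chasing single-year anomalies; the update itself is the literal
single-year balance scaled by α. The change is applied to `F_opt` at
fixed `S_opt`; if `F` would exceed 1 the stocking rate is raised instead
so the density stays continuous, and the density is floored at zero.
Under stationary forcing the map is a contraction (factor
`1 − α·(Y_cut + IC·T_farm·S)/(S·IC·365)` ≈ 0.8 for typical farms), so a
±20 % perturbation decays below 1 % of the optimum within 25 years — the
suite verifies this against an independent re-optimization.

## Experiment protocol

A full experiment runs: (1) a spin-up recycling an early forcing window at
fixed CO2 until the per-cell mean annual NEE proxy is below
1 g C m⁻² yr⁻¹ (a litter-rescaling acceleration exploits the pool's
linearity; tolerance 0 is detectably unreachable and errors); (2) a
reference optimization on the same window; (3) a historical adaptive
transient; then (4) the analysis transient plus three variants branching
from the historical end state with one driver frozen at the first analysis
year — CO2 fixed, climate recycled over the five leading analysis years,
or nitrogen fixed. Productivity is the area-weighted cut yield in
t DM ha⁻¹ yr⁻¹; trends are OLS slopes with the usual t-test (the p-value
convention for a constant series is slope 0, p 1). Differencing the
full-run trend against each fixed-driver run attributes the trend; the
drivers are not independent, so contributions can exceed 100 % jointly.

Nitrogen forcing follows the historical reconstruction: organic rates
constant; mineral rates zero before 1951, ramping linearly from one tenth
of the reference level in 1951 to the full level by 1961 and scaled
afterwards by a consumption index; deposition interpolated linearly
between decadal anchors. Anchor placement within a decade is not
well-defined a priori; midpoints were chosen and extrapolation is flat.

The parameter-uncertainty ensemble perturbs four factors at two levels —
`a` ±20 %, `N_addmax` ±0.20 absolute, `Vcmax/Jmax` jointly ±20 %,
`SLA_max` ±20 % — into 2⁴ = 16 member configurations; the 1-σ spread of
any scalar output across members is its uncertainty estimate and is
invariant to member order.

## What the synthetic forcing does and does not emulate

The weather generator produces a sinusoidal seasonal temperature cycle
with AR(1) daily noise and an annual anomaly tied to the same noise scale,
Bernoulli–gamma precipitation, day-of-year radiation damped on wet days,
and wet-day-elevated humidity; zone parameters (cold / temperate /
mediterranean, assigned by latitude band as a stand-in for a climate
classification) give realistic annual means (~730 mm precipitation in the
temperate band, ~370 mm in the mediterranean). It does **not** emulate
spatial correlation of weather between cells, drought persistence across
years, heat-wave/precipitation coupling, real coastlines or orography.
Passing tests therefore demonstrate the management logic and driver
responses under controlled statistical forcing — not predictive skill for
any real region. Absolute European trend magnitudes from reanalysis-driven
studies are likewise out of reach at desk scale and are not targeted.

## Numerical choices and problem sizes

Tolerances: feed-balance 0.5 kg DM ha⁻¹ (simulated cells), 10⁻⁶ for
closed-form toys; bisection to a relative S-bracket of 10⁻¹⁰ (vectorized
path: 25 bisection rounds after a ×1.6 sweep); spin-up NEE tolerance
1 g C m⁻² yr⁻¹ with a loop cap of 30. Ties at an optimizer plateau resolve
to the smallest S. Degenerate inputs (zero-productivity cells, empty
grazing season, zero-weight regions, constant trend series) return defined
values or informative errors, never NaN. The suite's problem sizes — a
three-cell zone strip for most properties, a 10×10 grid for 50 years for
the attribution experiment — keep a full run of tests plus experiments in
the minutes range on a single core while exercising every code path; the
attribution experiment's CO2-only design uses exactly tiled (bit-identical)
climate years so the climate and nitrogen contributions are structurally
zero and any deviation is a genuine defect.

## Known limitations

* A parcel is either cut or grazed within a year; mixed use is not
  represented.
* No legume N fixation, no soil nutrient pools beyond the nitrogen
  response, no pH/phosphorus/slope/palatability constraints — the computed
  density is a biological *potential*, generally above actual stocking.
* The growth substrate has no energy balance or prognostic soil carbon
  beyond the single litter pool; its constants are calibrated to plausible
  magnitudes, not fitted to observations.
* Livestock do not move between cells; each cell is a closed farm.
* Gridded outputs are written as tidy CSV tables (with unit headers), not
  as netCDF.
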