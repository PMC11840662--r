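---
title: "Methods: diet scenarios, land allocation and LUC emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet scenarios, land allocation and LUC emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

oilscape asks a land-system question: if the world's 2050 population eats
vegetable oils either at today's per-capita rates or at the EAT-Lancet
reference intakes, how much land do the four main oil crops (oil palm,
soybean, sunflower, rapeseed) need, where does that land come from, and what
land-use-change (LUC) CO2 emissions follow — and how do all three change if
palm oil in food is progressively replaced by the other oils? This vignette
documents the model as implemented, its assumptions, the tunable parameters,
and what the synthetic-world tests do and do not demonstrate.

## 1. Demand model

Per-oil food demand in 2050 is `rate (kg/capita/yr) x population / 1000` Mt,
with the SSP2 population of 9187 million. Two rate sets are built in:

* **current**: 2018–2020 global average food consumption per capita
  (palm 2.4, palm-kernel 0.19, rapeseed 1.24, soybean 3.14, sunflower 1.55,
  other 2.79 kg/capita/yr);
* **eat_lancet**: the reference intakes of 6.8 g/day palm oil and 40 g/day
  unsaturated oils, annualized (x365/1000) and split across individual oils
  proportionally to their current rates.

The palm intake is carried internally as the exact annualized value
2.482 kg/capita/yr, not the displayed 2.5: only the exact value reproduces
the 22.8 Mt palm demand that the rounded rate misses. Replacement scenarios
scale palm + palm-kernel demand by `1 - f` for `f` in {0, 0.25, 0.5, 1} and
hand the removed mass to rapeseed, soybean and sunflower in proportion to
their current *food* production (production x food-use share, normalized:
soybean 0.523, sunflower 0.268, rapeseed 0.209). Total palm + main
unsaturated demand is conserved exactly across fractions.

Presentation rounding (0.1 Mt cells, summary rows summed over rounded
components) lives only in `format_demand_table()`; every computation uses
unrounded values. The printed per-capita rates are themselves rounded, so a
few derived cells differ from a published-style table in the last digit;
the package never adjusts rates to force agreement.

## 2. Land allocation

The allocator works on a harmonized 5-arcmin-style grid where each pixel
carries fractions of eleven land-cover classes, a peat fraction, a country,
a climate zone, an existing-oil-palm share, and per-crop suitability
(ordinal 1–8) and attainable yield (seed t/ha; oil t/ha for palm). Four
criteria sets:

* **Inclusion/exclusion**: usable area is the pixel's fraction under bare
  land, grassland, shrubland, annual or perennial cropland, or forest;
  urban, water and wetland are never used. Suitability class 6 ("marginal")
  or worse excludes the pixel for that crop regardless of cover.
* **Attribution**: each included pixel belongs to exactly one crop — best
  suitability class, ties broken by highest attainable food-oil yield, then
  a fixed crop order. Crops never compete afterwards.
* **Priority**: within a crop, pixels are ranked by suitability class, then
  attainable yield, with pixel index as the final tie-break. For oil palm a
  second mode ranks existing-palm share ahead of yield (still behind
  suitability; `proximity_first = TRUE` flips that, since the source
  description is ambiguous about the dominance order).
* **Accumulation**: food-oil production per pixel is
  `usable area x attainable yield x conversion`, where the conversion is the
  oil/seed ratio (0.35 rapeseed/sunflower; 0.20 soybean, times the 84% of
  soybean seed that is crushed) times the food-use share (palm 25%, rapeseed
  38%, soybean 41%, sunflower 61%). Pixels are consumed whole in priority
  order until cumulative production meets demand; the overshoot is reported,
  and demand beyond total capacity yields an `infeasible` flag with the
  shortfall rather than an error. Palm + palm-kernel demand is one oil-palm
  demand; "other" oils are never allocated land.

The sunflower oil/seed ratio shares rapeseed's 0.35; both are registry
entries and can be overridden. Likewise the soybean chain multiplies the
crush share (0.84) and the food-use share (0.41) as two independent factors;
if a user considers that double counting, either entry can be set to 1.

**Within-pixel cover consumption.** Because pixels are consumed whole, every
cover in a selected pixel is consumed and the within-pixel order is
irrelevant — the three `cover_order` modes (proportional, forest-first,
forest-last) therefore coincide under the defaults. They become meaningful
with `trim_overshoot = TRUE`, which charges the marginal pixel only the area
needed to meet demand exactly and draws it from the covers in the chosen
order; this bounds how much of the reported deforestation is an artifact of
the whole-pixel rule. The existing-palm share of a selected palm pixel is a
zero-LUC slice carved proportionally out of the includable covers: it counts
toward production but toward no conversion.

## 3. LUC emissions

Emissions are booked per crop x prior cover x mechanism, always as
`CO2 = C x 44/12`:

* **forest_biomass**: the country's above- plus below-ground forest biomass
  carbon density is lost at conversion and amortized over the 25-year crop
  tenure (flux = area x density / 25).
* **perennial_biomass**: orchards lose their at-maturity above-ground stock
  (temperate 63, tropical moist 21, tropical dry and boreal 9 Mg C/ha),
  amortized the same way. The 30-year orchard maturity cycle is recorded in
  the registry but unused: the full at-maturity stock is the lost amount.
* **palm_sink_credit**: conversion *to* oil palm regrows biomass to
  40 Mg C/ha at 25 years; the credit is booked as negative rows against the
  biomass mechanisms only, bounded so the net per land unit is never
  negative (`net_floor = FALSE` books the full credit for sensitivity).
  The credit never offsets peat flux.
* **peat_soil**: drained peat under newly converted area emits a perpetual
  annual flux — not amortized, since drainage emissions persist for decades
  to centuries and the factors are already per-year — of 0.2 (boreal), 1.1
  (temperate) or 2.0 (tropical, both moist and dry) Mg C/ha/yr. The
  existing-palm slice is excluded: its peat was drained before 2050.

Bare land, grassland, shrubland and annual cropland carry zero biomass
stock; mineral-soil carbon, dead wood and litter are never counted in any
cover. Both absences are asserted by tests.

## 4. Synthetic worlds

No real rasters ship with the package; `generate_world()` builds landscapes
with the statistical structure the downstream stages assume, not with
real-world marginals:

* spatially autocorrelated fields (bilinear interpolation of coarse Gaussian
  noise, correlation length 8 pixels by default) thresholded into the 8
  suitability classes by configurable prevalences;
* attainable yield positively rank-correlated with suitability (class sets
  the mean, a x0.7–1.0 noise factor keeps the relation stochastic);
* default yield ranges chosen to reproduce the field's yield contrast: oil
  palm up to 4 t oil/ha against roughly 0.6–0.8 t oil/ha for the annual
  crops once seed is converted to oil;
* climate zones by latitude band (boreal beyond 55°, temperate 30–55°,
  tropics below 30° split moist/dry by a wetness field); the grid spans
  70°N–70°S so even small worlds cross all bands;
* countries as Voronoi cells of random seeds, with country forest carbon
  densities drawn from 40–180 Mg C/ha;
* cover mixtures from spatially modulated Dirichlet draws (fractions sum to
  1 per pixel), clustered peat hotspots, and staple harvested areas nested
  inside the annual-crop fraction;
* existing oil palm as clusters confined to palm-eligible tropical pixels
  and biased toward already-converted (low-forest) land — one cluster per
  ~800 pixels by default; where a cluster sits, forest cover is shifted into
  perennial cropland in proportion to the palm share, because a standing
  plantation is by definition converted land. This construction is what
  gives the proximity mode its real-world meaning: expansion next to
  existing plantations touches less forest.

Global Mt demands cannot be met by a toy landscape, so `run_pipeline()`
scales all demands by one factor; `"auto"` sizes it so the largest per-crop
demand across the scenario set uses 60% of that crop's attributed capacity.
This keeps every scenario feasible while preserving all demand ratios, which
is what the directional conclusions depend on.

**What the tests show** — exact reproduction of the demand-table arithmetic;
exact agreement of the allocator with a brute-force reference on fixtures
and random worlds; hand-checkable emission closed forms; and, on a standard
200 x 200 world, the qualitative mechanisms: land and emissions grow with
the replacement fraction, EAT-Lancet rates demand more land and emissions
than current rates, and proximity-mode palm emits less than yield-mode palm
at near-equal area. **What they do not show** — any global magnitude (Mha or
Mt CO2/yr at world scale), which depends entirely on the real suitability,
yield, cover, peat and carbon rasters.

## 5. Numerical choices and limitations

* All ties are broken deterministically (final tie-break: pixel index), so
  results are bit-reproducible across platforms given a seed; one seed in
  `world_config()` drives every random draw of a run.
* Pixel areas use a spherical Earth (authalic radius, 6371007.2 m); the
  sub-0.3% error against an ellipsoid is negligible next to input
  uncertainty. Cover-fraction validation allows 1e-6 slack on the sum.
* Harmonization of finer layers is area-weighted (mean for continuous and
  fraction layers — conserving per-class area — and mode for categorical
  layers); only affine lat-lon grids at integer refinement factors are
  supported, and gridded I/O uses plain-text matrix CSVs described by a YAML
  layer spec plus a CSV country carbon table.
* Problem sizes in the shipped tests (200 x 200 for the directional checks,
  5–20 pixel sides for oracle comparisons, 25–50 random worlds per property)
  were chosen to make the full suite a coffee-break run on a laptop.
* Out of scope by design: economic or cost modelling, endogenous yield
  trends, indirect land-use-change reallocation, N2O/CH4 and fire
  emissions, foregone sequestration, and any statistical matching of real
  GAEZ/ESA-CCI/SPAM distributions.
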