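---
title: "Accounting methods for a natural-climate-solutions portfolio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting methods for a natural-climate-solutions portfolio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncsaccount)
```

## The accounting model

Natural climate solutions (NCS) are conservation, restoration and improved
land-management interventions on forests, grasslands, agricultural lands and
wetlands that either increase carbon storage or avoid greenhouse-gas
emissions. `ncsaccount` implements a portfolio accounting framework over 21
such pathways: each pathway estimator maps biophysical inputs to a mean
annual mitigation with a 95% confidence interval, and the portfolio layer
sums means, propagates intervals, prices the opportunities, and reports.

Nearly every pathway reduces to the same primitive,

$$ M \;=\; A \times r, $$

with $A$ an eligible extent (Mha) and $r$ a per-area annual flux
(Mg CO$_2$e ha$^{-1}$ yr$^{-1}$), so that $M$ lands in Tg CO$_2$e yr$^{-1}$
without unit factors (1 Mha $\times$ 1 Mg ha$^{-1}$ = 1 Tg). The unit canon
is fixed throughout: extents in Mha, fluxes in Mg CO$_2$e ha$^{-1}$
yr$^{-1}$, totals in Tg CO$_2$e yr$^{-1}$; Pg appears only in formatted
output at 2 significant figures. Carbon masses convert to CO$_2$ with the
inventory factor 44/12.

Non-CO$_2$ gases are converted with an explicit, overridable metric
(`gwp_set()`). The default is the AR5 100-year GWP (CH$_4$ 28, N$_2$O 265).
The tidal-wetland pathway defaults to the 100-year sustained-flux metric
(SGWP, CH$_4$ 45) because the avoided methane flux is sustained rather than
pulsed; every report states the basis used. The choice is configuration, not
hard-coding, because no single metric is canonical for mixed pulse/flux
portfolios.

## Pathway estimators

A few pathways need structure beyond $A \times r$:

* **Reforestation** first derives the eligible extent from gridded layers:
  cells below 25% tree cover whose native cover is forest, excluding
  intensive development (urban, impervious, major roads) and Histosols (to
  avoid double counting with peatland restoration). Cropland and pasture are
  retained for food production unless the caller releases a stated area.
  A conifer-albedo discount $(1 - f_{conifer} \cdot d)$ can reduce the
  benefit of dark canopies on otherwise snow-bright land; its magnitude is
  not part of the reference conditions, so the default is $d = 0$ with the
  factor recorded whenever it is used. The same discount applies to avoided
  forest conversion.
* **Avoided forest conversion** multiplies the persistently converted share
  of annual clearing by committed biomass emissions. The soil pool is
  excluded by construction — evidence on soil carbon after forest conversion
  is conflicting — so its estimates are all-biomass.
* **Avoided grassland conversion** books a 28% loss of the soil stock to
  1 m plus root and shrub biomass, all times 44/12. With the default stock
  of $125 \cdot 12/(0.28 \cdot 44) \approx 121.75$ Mg C ha$^{-1}$ the soil
  term is 125 Mg CO$_2$e ha$^{-1}$, 81% of the per-hectare emission; the
  root-plus-shrub carbon (8.0 Mg C ha$^{-1}$) is back-solved from that
  share. Root biomass can alternatively be modelled from climate normals
  via a configured linear two-predictor regression clamped at zero — the
  functional form is the contract; coefficients are caller-supplied because
  no canonical set ships with the package.
* **Fire management** runs a year-by-year expected-value simulation: 5% of
  the treatable area is newly treated each year, treatment emits a
  prescribed-fire cost on the treated hectares and eliminates wildfire risk
  there for 20 years (only on directly treated land), untreated land burns
  with an annual probability, and the reported value is the mean annual
  (avoided minus prescribed) emission over a 20-year horizon. Wildfire is
  deterministic probability-times-emission rather than sampled ignition
  because the quantity of interest is an expected average; a seedable
  stochastic mode exists and is used as a simulation cross-check in the
  tests.
* **Cropland nutrient management** grows the baseline by 4.6% (business-as-
  usual fertilizer growth to the target year), cuts nitrogen rates by 22%,
  and maps that cut to emissions: field N$_2$O falls along an exponential
  response $E \propto N^k$ whose exponent is calibrated once by a
  deterministic root solve (tolerance $10^{-10}$, $k \approx 1.612$) so the
  22% rate cut yields a 33% field cut; upstream manufacture emissions fall
  proportionally (22%); and the combined 29% follows from the 7:4
  field:upstream emission weighting, itself recovered by a one-unknown
  linear solve from the 22/33/29 triple. A linear response is provided to
  show why the nonlinearity matters: it would reproduce only 22%.
* **Biochar** is a chain product — residue mass, char yield, char carbon
  fraction, and the 79.6% permanence fraction — with no N$_2$O or CH$_4$
  side terms.
* **Improved plantations** finds the biological rotation age by exhaustive
  argmax of mean annual increment over a tabulated stand-carbon curve and
  annualises the gain over the economic rotation, floored at zero.
* **Tidal wetland restoration** converts the avoided CH$_4$ flux from the
  27% of salt marshes that are freshened; **seagrass** pathways apply the
  1.5% yr$^{-1}$ loss rate with 50% release, and the 29–52% restorable
  interval whose endpoints directly supply the restoration CI.

Every estimator is homogeneous of degree 1 in its extent argument; the test
suite asserts this property across the library.

## Uncertainty propagation

Reported 95% intervals are represented by distribution families fitted from
`(mean, low, high)`: symmetric intervals become normal with
$\sigma = (high - low)/(2 \times 1.96)$, asymmetric ones two-piece normal
with per-side sigmas, degenerate ones point masses; lognormal and uniform
families are available for callers who know more.

Two combiners are provided. *Quadrature* (inventory Approach-1 style) sums
means and combines each side's half-widths in root-sum-of-squares,
preserving asymmetry. *Monte Carlo* (Approach-2 style) draws each quantity
from its fitted family, sums draws, and reports empirical 2.5/97.5
percentiles; it is seed-deterministic, leaves the caller's RNG state
untouched, and truncates negative draws at zero for quantities whose
reported interval is nonnegative (mitigation potentials are nonnegative by
construction; truncation counts are recorded on the result).

The reporting default is quadrature. This is a deliberate design choice:
the two-piece normal's mean lies $\sqrt{2/\pi}\,(\sigma_{high} -
\sigma_{low})$ above its mode, so summing many upward-skewed pathway
intervals shifts the Monte Carlo percentile interval upward relative to the
quadrature interval anchored at the reported means. Quadrature is
deterministic, reproduces asymmetry, and keeps the headline interval
anchored to the stated per-pathway bounds; Monte Carlo remains available
(`ci_method = "mc"`) and the two agree closely for symmetric inputs, which
the tests verify at $10^5$ draws within 2%. Inter-pathway correlation is
assumed zero in both combiners; no correlation structure is estimated.

## Cost structure

Costs enter only as tranche ceilings: each pathway carries the cumulative
mitigation achievable below USD 10, 50 and 100 per Mg CO$_2$e
(nondecreasing, bounded by the pathway maximum). The portfolio
marginal-abatement-cost curve is the pointwise sum of these three-step
functions, evaluated as a right-continuous step function that is zero below
the first price. Three steps — not a continuous curve — match the
granularity of the reference analysis; finer tranches would be a
configuration extension, and no discounting or leakage adjustment is
applied.

## The synthetic data and what it does (not) show

The package ships no external data. `generate_landscape()` emulates the
statistical structure of national land-cover/soil/climate stacks at toy
scale: the default is a 100$\times$100 grid of 100-ha cells (a 1 Mha
domain), categorical land cover from configurable class probabilities,
class-conditional tree cover (forest cells span intact and degraded stands
so eligibility masking has work to do), lognormal soil carbon with mean
122 Mg C ha$^{-1}$ and CV 0.3 — the mean at which the default
grassland-conversion soil term is reproduced — smooth temperature and
precipitation gradients with noise, and class-conditional exclusion masks.
One seed fixes every layer bit-for-bit.

`generate_parameter_table()` is the reference fixture: the ten leading
pathway maxima as reported (307, 267, 107, 103, 95, 82, 52, 38, 18, 12 Tg
CO$_2$e yr$^{-1}$) plus an eleven-pathway remainder summing to 122 Tg.
Because those ten must also be the ten *largest* for the 90%/10%
concentration split to hold, the remainder values are necessarily clustered
just below 12 Tg (mean 122/11 $\approx$ 11.1); they, the per-pathway CIs,
the unreported cost tranches and the pool splits are synthetic fixture
values, constructed once so that the portfolio-level quantities — the
asymmetric 0.9–1.6 Pg interval under quadrature, the 299/913/1095 Tg price
points, the 63/29/7 pool decomposition — are reproduced. The `random` mode
perturbs the fixture under a seed for property tests.

Passing tests on these inputs demonstrate that the accounting arithmetic,
masking logic, interval propagation and pricing are correct and internally
consistent. They do not validate the biophysical rates themselves, the
spatial realism of any landscape (no parcel geometry, ownership, road
networks, or regional structure), or national-scale spatial processing,
all of which are outside this package's scope.

## Numerical conventions and edge cases

* 1.96 (not `qnorm(0.975)`) maps CI half-widths to sigmas, so stated bounds
  round-trip exactly.
* Report rounding matches printed precision: nearest integer for Tg and
  percent, 2 significant figures for Pg; unrounded values are always
  carried alongside. Rounded pool percentages may sum to 99 — the report
  prints both forms rather than forcing a false 100.
* Pool decompositions must close on the mean within $10^{-6}$ Tg; pathway
  tables validate CI bracketing, tranche monotonicity, pool-fraction
  closure and co-benefit tags, and refuse duplicate ids (the double-counting
  guard).
* CSV writers serialize numerics at 17 significant digits, so written
  tables re-read bit-identically and file-recomputed totals match in-memory
  totals exactly.
* Degenerate inputs: zero extents, zero rates, empty eligibility and
  zero-width intervals all propagate to exact zeros rather than errors;
  an empty portfolio is an error.
* The fire simulation treats a cohort treated in year $s$ as protected for
  years $s, \ldots, s + 19$ (protection includes the treatment year), and
  never treats more than the currently unprotected area.

Problem sizes used by the test-suite: grids up to 200$\times$200 cells,
Monte Carlo at $10^4$–$10^5$ draws, 200-replicate coverage simulations —
sizes chosen so each statistical check has comfortable resolution (e.g.
binomial 3$\sigma$ bounds on class frequencies) at desk scale.

## Known limitations

Saturation durations are carried as metadata, not modelled dynamics; the
accounting is a single-year snapshot at stated rates. Leakage, monetary
co-benefit valuation and net-present-value discounting are out of scope by
design. The manure pathway enters as an exogenous total (its process model
lives in external analyses), and the natural-forest-management rate is a
back-solved scalar pending a process-based harvest-scheduling treatment.
Co-benefit tags are qualitative pass-through flags with no scoring.
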