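# ncsaccount

Portfolio accounting for **natural climate solutions (NCS)** — the
conservation, restoration and improved land-management interventions on
forests, grasslands, agricultural lands and wetlands that increase carbon
storage or avoid greenhouse-gas emissions. The package is aimed at
land-sector carbon analysts who need the full accounting chain to be
explicit, testable and reproducible: 21 pathway-specific estimators,
CO₂-equivalent conversion of CH₄/N₂O under configurable warming-potential
metrics, 95% confidence-interval propagation to the portfolio level,
marginal-abatement-cost (MAC) curves with price-constrained queries, and
Fig.-1-style tabular reporting. A synthetic-data module generates toy
gridded landscapes (ESRI ASCII layers + YAML manifest) and pathway
parameter tables, so the entire pipeline runs with no external data.

## The model in brief

Most pathways reduce to extent × rate,

```
M [Tg CO2e/yr] = A [Mha] × r [Mg CO2e/ha/yr]        (1 Mha × 1 Mg/ha = 1 Tg)
```

with pathway-specific structure where needed: land-cover eligibility
masking with exclusion layers for reforestation; a year-by-year
expected-value simulation of prescribed-fire treatment vs avoided wildfire;
stock-change accounting (28% soil-carbon loss to 1 m, plus root/shrub
biomass × 44/12) for avoided grassland conversion; a calibrated nonlinear
N-rate → N₂O response for nutrient management (22% rate cut → 33% field
cut → 29% combined); mean-annual-increment argmax for plantation rotation
extension; and sustained-flux GWP conversion of avoided tidal-marsh CH₄.
Per-pathway 95% CIs are combined to the portfolio interval by error
quadrature (default) or Monte Carlo, both preserving asymmetry via
two-piece normal representations. Cost enters as cumulative tranches below
USD 10/50/100 per Mg CO₂e, summed pointwise into a portfolio step function.

## Worked example

```r
library(ncsaccount)

tab   <- generate_parameter_table()     # 21-pathway reference table
pf    <- aggregate_portfolio(tab)       # totals + quadrature 95% CI
curve <- build_mac(tab)                 # MAC step function
cat(portfolio_summary(pf, curve), sep = "\n")
```

```
NCS portfolio: 21 pathways
GWP basis: GWP-100 (CH4 x28, N2O x265)
Maximum mitigation: 1203.0 Tg CO2e/yr (1.2 Pg CO2e/yr)
95% CI: 912.5 to 1604.7 Tg (0.91 to 1.6 Pg) [quadrature]
Share of reference net emissions (5794.5 Tg): 20.8% (~21%)
Pools: biomass 63.2%, soil 29.5%, avoided CH4/N2O 7.3% (rounded 63/29/7)
At USD 10/Mg: 299 Tg CO2e/yr (24.9%, ~25%)
At USD 50/Mg: 913 Tg CO2e/yr (75.9%, ~76%)
At USD 100/Mg: 1095 Tg CO2e/yr (91.0%, ~91%)
```

Reading: the 21 pathways could deliver up to 1203 Tg CO₂e yr⁻¹ (1.2 Pg),
about 21% of the 5794.5 Tg reference net national emissions; 299 Tg (25% of
the maximum) is available below USD 10 per Mg CO₂e and 1095 Tg (91%, i.e.
1.1 Pg) below USD 100; 63% of the potential is plant-biomass sequestration,
29% soil, 7% avoided CH₄/N₂O. The ten largest pathways hold 90% of the
total (`top_k_share(pf, 10)`).

Single pathways work standalone, e.g. cover crops on 88 Mha at
0.32 Mg C ha⁻¹ yr⁻¹:

```r
area_times_rate(88, 0.32 * 44/12)
#> [1] 103.2533
```

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `05_report.R`) that generates the synthetic inputs, runs
every estimator from first-principles inputs, propagates uncertainty,
builds the MAC curve and writes the results tables under `results/`.

## Package layout

- `R/` — core types and arithmetic (`gwp.R`, `core.R`), parameter tables
  (`params.R`), raster layers and ESRI ASCII I/O (`landscape.R`), the 21
  estimators (`pathways.R`, `inputs.R`), CI propagation (`uncertainty.R`),
  MAC curves (`abatement.R`), portfolio reporting (`portfolio.R`), and the
  synthetic-data generators (`synthetic.R`).
- `vignettes/ncs-accounting.Rmd` — the methods vignette: model assumptions,
  parameter defaults, uncertainty design, what the synthetic data does and
  does not demonstrate.
- `tests/testthat/` — unit, property and acceptance suites, including
  independent brute-force oracles (parcel-level fire enumeration,
  exhaustive eligibility counting, closed-form quadrature).
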