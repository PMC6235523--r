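#!/usr/bin/env Rscript
# Step 4 -- build the portfolio marginal-abatement-cost curve from the
# per-pathway cost tranches and evaluate the price-constrained mitigation
# at the three reference carbon prices.

suppressPackageStartupMessages(library(ncsaccount))

tab <- read_pathway_table("results/pathway_params.csv")
pf <- aggregate_portfolio(tab)
curve <- build_mac(tab)

rows <- lapply(c(10, 50, 100), function(p) {
  fr <- mac_fraction(curve, p, pf$total_mean)
  data.frame(price_usd = p,
             cumulative_tg = mitigation_at_price(curve, p),
             fraction_of_max = fr$fraction,
             percent_rounded = fr$percent_rounded)
})
mac_tab <- do.call(rbind, rows)
write_results_csv(mac_tab, "results/mac_curve.csv")

for (i in seq_len(nrow(mac_tab)))
  cat(sprintf("<= USD %3d/Mg CO2e: %6.0f Tg CO2e/yr (%d%% of maximum)\n",
              mac_tab$price_usd[i], mac_tab$cumulative_tg[i],
              mac_tab$percent_rounded[i]))
cat(sprintf("At USD 100 that is %.2g Pg CO2e/yr of the %.2g Pg maximum.\n",
            tg_to_pg(mitigation_at_price(curve, 100)),
            tg_to_pg(pf$total_mean)))
cat("Wrote results/mac_curve.csv\n")
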