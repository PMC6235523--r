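#!/usr/bin/env Rscript
# Step 1 -- generate every input the pipeline needs: a toy gridded
# landscape (written as ESRI ASCII layers + YAML manifest) and the pathway
# parameter tables (reference fixture and a perturbed variant).

suppressPackageStartupMessages(library(ncsaccount))

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
grid <- generate_landscape(cfg)
write_landscape(grid, "results/landscape")
cat(sprintf("Landscape: %d x %d cells of %g ha (%.2f Mha domain), seed %d\n",
            cfg$shape[1], cfg$shape[2], cfg$cell_area_ha,
            prod(cfg$shape) * cfg$cell_area_ha / 1e6, seed))
cat(sprintf("  mean soil C to 1 m: %.1f Mg C/ha (target 122)\n",
            mean(grid$soil_c_1m)))

tab <- generate_parameter_table()
write_pathway_table(tab, "results/pathway_params.csv")
cat(sprintf("Reference table: 21 pathways, %.0f Tg CO2e/yr maximum\n",
            sum(tab$mitigation_tg)))

rnd <- generate_parameter_table(synthetic_config(seed = seed,
                                                 table_noise = 0.15),
                                mode = "random")
write_pathway_table(rnd, "results/pathway_params_random.csv")
cat(sprintf("Perturbed table (15%% noise): %.0f Tg CO2e/yr maximum\n",
            sum(rnd$mitigation_tg)))

conv <- generate_conversion_events(grid, cfg$conversion_rates, seed = seed)
cat("Sampled annual conversion (Mha):",
    paste(sprintf("%s %.4f", names(conv), conv), collapse = ", "), "\n")
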