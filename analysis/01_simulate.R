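#!/usr/bin/env Rscript
# Step 1 -- simulate the study system.
#
# Generates a desk-scale synthetic landscape under the default study
# conditions (4000 plots, 6/18/54 nested habitats, 19 climate variables on 4
# latent gradients, narrow-level slope heterogeneity on PC1) plus the
# species-level community tables, and writes the five input schemas under
# results/data/ together with a JSON truth sidecar.

suppressMessages(library(habclim))
seed <- 20260901L
out <- "results/data"

cfg <- synthetic_config(tau1_sq = c(0.2, 0, 0, 0),
                        seed = derive_seed(seed, "simulate"))
d <- generate_dataset(cfg)
com <- generate_communities(d, list(missing_species_frac = 0.10,
                                    none_frac = 0.02),
                            seed = derive_seed(seed, "communities"))

message(sprintf("simulated %d plots, %d narrow habitats, %d species records",
                nrow(d$meta), length(unique(d$habitat$level3)),
                nrow(com$vegetation)))
message(sprintf("%d plot(s) flagged (target outside the pool's trait hull)",
                length(com$flagged)))

write_table(d$meta, file.path(out, "plot_metadata.csv"))
write_table(d$climate[, c("plot_id", paste0("bio", 1:19))],
            file.path(out, "climate.csv"))
write_table(d$habitat, file.path(out, "habitat.csv"))
write_table(com$vegetation, file.path(out, "vegetation.csv"))
write_table(com$traits, file.path(out, "traits.csv"))
write_table(d$responses, file.path(out, "direct_responses.csv"))

truth <- list(seed = seed, beta = cfg$beta, tau0_sq = cfg$tau0_sq,
              tau1_sq = cfg$tau1_sq, sigma_sq = cfg$sigma_sq,
              ranef_level = cfg$ranef_level,
              expected_r2_marginal = d$truth$expected$r2_marginal,
              expected_r2_conditional = d$truth$expected$r2_conditional,
              flagged_plots = com$flagged)
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote input tables and truth sidecar under ", out)
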