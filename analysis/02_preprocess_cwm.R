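#!/usr/bin/env Rscript
# Step 2 -- read the community tables, assign traits with genus fallback,
# compute community-weighted means and coverages, apply the six exclusion
# rules and the one-plot-per-cell stratification, and write the CWM table
# and the filter report.

suppressMessages(library(habclim))
seed <- 20260901L
dat <- "results/data"
out <- "results/preprocess"

veg <- read_table(file.path(dat, "vegetation.csv"), "vegetation")
traits <- read_table(file.path(dat, "traits.csv"), "traits")
meta <- read_table(file.path(dat, "plot_metadata.csv"), "plot_metadata")
climate <- read_table(file.path(dat, "climate.csv"), "climate")

assignment <- assign_traits(unique(veg[, c("species", "genus")]), traits)
message(sprintf("trait provenance: %s",
                paste(names(table(assignment$provenance)),
                      table(assignment$provenance), collapse = ", ")))

cwm <- compute_cwm(veg, assignment)
message(sprintf("CWMs for %d plots; median minimum coverage %.3f",
                nrow(cwm), median(cwm$coverage_min)))

flt <- apply_filters(veg, meta, climate, cwm_coverage(cwm))
print(flt$report)

meta_k <- meta[meta$plot_id %in% flt$plot_ids, ]
kept <- stratify_spatial(meta_k, cell_deg = 0.01,
                         seed = derive_seed(seed, "stratify"))
message(sprintf("filters kept %d of %d plots; stratification kept %d",
                length(flt$plot_ids), nrow(meta), length(kept)))

write_table(cwm[cwm$plot_id %in% kept, ], file.path(out, "cwm.csv"))
write_table(flt$report, file.path(out, "filter_report.csv"))
write_table(data.frame(plot_id = kept), file.path(out, "retained_plots.csv"))
message("wrote ", out)
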