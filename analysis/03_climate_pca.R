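#!/usr/bin/env Rscript
# Step 3 -- principal components of the 19 climate variables on the retained
# plots, and the plot scores on the first four components.

suppressMessages(library(habclim))
dat <- "results/data"
pre <- "results/preprocess"
out <- "results/pca"

climate <- read_table(file.path(dat, "climate.csv"), "climate")
kept <- read.csv(file.path(pre, "retained_plots.csv"))$plot_id
climate <- climate[climate$plot_id %in% kept & climate$climate_complete, ]

pca <- fit_climate_pca(climate, n_components = 4)
print(pca)
scores <- project_climate(climate, pca)

write_table(data.frame(variable = pca$variables, pca$loadings[, 1:4]),
            file.path(out, "loadings.csv"))
write_table(data.frame(component = seq_along(pca$explained_variance),
                       fraction = pca$explained_variance),
            file.path(out, "explained_variance.csv"))
write_table(scores, file.path(out, "scores.csv"))
message(sprintf("first four components explain %.1f%% of the climate variance",
                100 * sum(pca$explained_variance[1:4])))
message("wrote ", out)
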