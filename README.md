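# habclim

Habitat-specific climate–trait relationships from vegetation-plot data.

## The problem

A central question of trait-based community ecology is how much of the
functional composition of plant communities is governed by macroclimate. The
response variable is the community-weighted mean (CWM) of a trait in a
vegetation plot,

    CWM_t = sum_i c_i x_{i,t} / sum_i c_i

(cover-weighted arithmetic mean over the species *i* of the plot that carry a
value for trait *t*). Globally, climate predicts CWMs weakly: local factors —
soil, land use, disturbance, biotic interactions — differ between habitats
and mask the climatic signal. Classifying plots into a hierarchy of
increasingly narrow habitat types (broad level 1 → intermediate level 2 →
narrow level 3) holds those factors progressively more constant and lets the
climate effect, and its habitat-specificity, be estimated.

`habclim` implements that analysis end to end for four traits (plant height,
specific leaf area, seed mass, specific root length):

- **I/O and validation** for the five delimited-text schemas (comma or tab
  separated, UTF-8, `.` decimal separator); one example file per schema under
  `inst/extdata/`, plus `config_example.yaml` for the pipeline:

  | schema | required columns | notes |
  |---|---|---|
  | `vegetation` | `plot_id, species, cover` | optional `genus` (else first name token); duplicate `(plot, species)` covers summed, subspecies merged to the first two name tokens, capped at 100 |
  | `plot_metadata` | `plot_id, latitude, longitude` | optional `survey_year`, `abundance_type` in {`cover`, `presence_absence`} |
  | `traits` | `taxon, taxon_rank, plant_height, sla, seed_mass, srl` | `taxon_rank` in {`species`, `genus`}; values > 0 |
  | `habitat` | `plot_id, level1` | optional `level2`, `level3`, nested codes |
  | `climate` | `plot_id, bio1 ... bio19` | plots with missing values flagged, not dropped |
- **Preprocessing**: six exclusion rules in a fixed, audited order
  (presence/absence plots, missing coordinates, optional region box,
  latitude outside 34–82° N, trait coverage < 80%, missing climate),
  most-recent-census deduplication and one-plot-per-0.01°-grid-cell
  stratification.
- **CWMs** with species → genus trait fallback, per-trait coverage
  fractions and natural-log transformation.
- **Climate PCA**: correlation-matrix PCA of the 19 bioclimatic variables;
  plots projected on the first four components, which serve as the climate
  gradients.
- **Mixed models by REML** (`fit_mixed_reml()`): for one trait,

      log y_i = b0 + sum_j b_j x_ij + a_h(i) + sum_j u_h(i),j x_ij + s(lat,lon) + e_i

  with habitat random intercepts `a_h ~ N(0, tau0^2)`, habitat-specific
  random climate slopes `u_hj ~ N(0, tau1j^2)`, an optional low-rank
  spline-on-the-sphere smooth `s` and optional observation weights. Five
  models per trait: fixed effects only (on a balanced habitat subsample),
  plus broad-habitat intercepts, plus habitat-specific slopes at the broad,
  intermediate and narrow levels.
- **Inference**: habitat-specific marginal slopes `b_j + u_hj` with joint
  (Henderson) standard errors, ±1.96·SE confidence intervals, suppression of
  estimates from habitats with fewer than 100 plots, slope-sign tallies per
  broad-habitat parent, and marginal/conditional R² variance partitions with
  the climate-versus-habitat split.
- **A synthetic-data generator** (`generate_dataset()`,
  `generate_communities()`) with known mixed-model ground truth, used by the
  test suite for exact parameter recovery; see the methods vignette
  (`vignettes/habitat-climate-trait-models.Rmd`) for every modelling choice
  and default.

## Worked example

```r
library(habclim)

cfg <- list(
  mode = "synthetic", seed = 99,
  synthetic = list(n_plots = 800, n_habitats_per_level = c(4, 8, 16),
                   tau1_sq = c(0.2, 0, 0, 0)),
  traits = "sla", models = c(1, 3), min_n_slopes = 25
)
art <- run_pipeline(cfg)
#> [simulate] 0 -> 800
#> [cwm] 800 -> 800
#> [filters] 800 -> 800
#> [stratify] 800 -> 800
#> [pca] 800 -> 800
#> [fit] sla_model1: loglik -1072.86, 0 iterations
#> [fit] sla_model3: loglik -1326.12, 44 iterations

subset(art$decompositions, select = c(model_id, r2_marginal, r2_conditional, r2_climate, r2_habitat))
#>   model_id r2_marginal r2_conditional r2_climate r2_habitat
#> 1        1  0.03909802     0.03909802 0.03909802  0.0000000
#> 2        3  0.03329728     0.25617145 0.07187934  0.1842921

head(subset(art$slopes, pc == 1 & !is.na(habitat)), 4)
#>   trait model_id habitat level pc n_plots       slope         se      ci_low     ci_high significant suppressed se_formula
#> 5   sla        3      H1     1  1     156  0.03142201 0.04113740 -0.04920729  0.11205132       FALSE      FALSE      joint
#> 6   sla        3      H2     1  1     213  0.13936648 0.03148049  0.07766473  0.20106824        TRUE      FALSE      joint
#> 7   sla        3      H3     1  1     215  0.11909803 0.03289035  0.05463294  0.18356312        TRUE      FALSE      joint
#> 8   sla        3      H4     1  1     216 -0.08787275 0.03185374 -0.15030607 -0.02543942        TRUE      FALSE      joint
```

The decomposition rows read: in the fixed-effects model the four climate PCs
explain ~3.9% of the log-SLA variance; adding broad-habitat intercepts and
habitat-specific slopes (model 3) raises the *conditional* R² to ~26%, of
which ~18 points are habitat identity (red bars of the hierarchy figure) and
~7 points are general plus habitat-specific climate (blue bars). The slope
table gives each broad habitat's marginal slope of log SLA along PC1 with its
joint SE, CI and significance; estimates from habitats with fewer than
`min_n_slopes` plots would be reported but suppressed.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study on a synthetic
landscape whose ground truth is known (4000 plots, 6/18/54 habitats,
narrow-level slope heterogeneity on PC1):

```sh
Rscript analysis/01_simulate.R        # tables + truth sidecar -> results/data/
Rscript analysis/02_preprocess_cwm.R  # CWMs, filters, stratification
Rscript analysis/03_climate_pca.R     # climate PCs
Rscript analysis/04_fit_models.R      # 4 traits x 5 models by REML
Rscript analysis/05_report.R          # tallies, R2 trajectories
```

The final report prints, e.g. (climate share of explained variance by model;
3 = broad, 5 = narrow):

```
        trait r2_climate.3 r2_climate.4 r2_climate.5
 plant_height        0.074        0.080        0.117
          sla        0.060        0.076        0.137
    seed_mass        0.088        0.112        0.161
          srl        0.037        0.057        0.102
```

— the climate share grows toward narrower habitat definitions exactly where
the generator injected narrow-level slope heterogeneity.

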