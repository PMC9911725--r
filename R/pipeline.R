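# End-to-end orchestration: generate or read tables, filter, stratify,
# compute CWMs, fit the model hierarchy and derive slopes, tallies and
# variance partitions, with stage-level row-count bookkeeping and a manifest.

#' Default pipeline configuration
#'
#' @param mode `"synthetic"` (generate data) or `"tables"` (read the five
#'   delimited tables from `paths`).
#' @param seed master seed; per-stage seeds are derived by hashing stage
#'   names (see [derive_seed()]).
#' @return a nested configuration list; override entries via
#'   [run_pipeline()]'s `config` argument or a YAML file with the same
#'   structure.
#' @export
default_run_config <- function(mode = "synthetic", seed = 1L) {
  list(
    mode = mode,
    seed = as.integer(seed),
    synthetic = list(),          # overrides for synthetic_config()
    community = NULL,            # pool_config list to emit species tables
    paths = list(),              # vegetation, plot_metadata, traits, habitat, climate
    traits = trait_names(),
    models = 1:5,
    n_components = 4,
    filter_rules = default_filter_rules(),
    stratify = list(enabled = TRUE, cell_deg = 0.01),
    model_options = list(spatial = FALSE, k = 100, weights = FALSE),
    min_n_slopes = 100,
    out_dir = NULL
  )
}

#' Run the full analysis pipeline
#'
#' Stages: acquire (generate or read) -> trait assignment + CWM (community
#' tables) or direct responses -> exclusion filters -> most-recent-census +
#' grid stratification -> climate PCA -> model fits per trait and model ->
#' marginal slopes, tallies and R-squared partitions -> optional write-out.
#' Every stage logs its input/output row counts; identical config and seed
#' reproduce identical tables.
#'
#' @param config a (partial) configuration list merged over
#'   [default_run_config()], or the path of a YAML file holding one.
#' @param quiet suppress per-stage messages.
#' @return list of class `run_artifacts`: input tables, `cwm`, `scores`,
#'   `pca`, `fits` (per trait/model), `slopes`, `tallies`, `decompositions`,
#'   `filter_report`, `stage_counts`, `manifest`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_counts <- list()
  log_stage <- function(stage, n_in, n_out) {
    stage_counts[[length(stage_counts) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
    say("[%s] %d -> %d", stage, n_in, n_out)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      hc_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "habclim_stage_error",
              data = list(stage = stage,
                          stage_counts = do.call(rbind, stage_counts)))
    })
  }

  # --- acquire ---------------------------------------------------------------
  dataset <- NULL
  community <- NULL
  if (identical(cfg$mode, "synthetic")) {
    dataset <- run_stage("simulate", {
      sc <- do.call(synthetic_config,
                    utils::modifyList(cfg$synthetic,
                                      list(seed = derive_seed(cfg$seed, "simulate"))))
      generate_dataset(sc)
    })
    meta <- dataset$meta; climate <- dataset$climate; habitat <- dataset$habitat
    if (!is.null(cfg$community)) {
      community <- run_stage("communities",
        generate_communities(dataset, cfg$community,
                             seed = derive_seed(cfg$seed, "communities")))
    }
    log_stage("simulate", 0L, nrow(meta))
  } else if (identical(cfg$mode, "tables")) {
    need <- c("vegetation", "plot_metadata", "traits", "habitat", "climate")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss) > 0)
      hc_stop(sprintf("paths missing for: %s", paste(miss, collapse = ", ")),
              "habclim_validation_error")
    community <- run_stage("read", list(
      vegetation = read_table(cfg$paths$vegetation, "vegetation"),
      traits = read_table(cfg$paths$traits, "traits")))
    meta <- run_stage("read", read_table(cfg$paths$plot_metadata, "plot_metadata"))
    habitat <- run_stage("read", read_table(cfg$paths$habitat, "habitat"))
    climate <- run_stage("read", read_table(cfg$paths$climate, "climate"))
    log_stage("read", 0L, nrow(meta))
  } else hc_stop("mode must be 'synthetic' or 'tables'",
                 "habclim_validation_error")

  # --- CWM -------------------------------------------------------------------
  cwm <- run_stage("cwm", {
    if (!is.null(community)) {
      assignment <- assign_traits(
        unique(community$vegetation[, c("species", "genus")]),
        community$traits)
      compute_cwm(community$vegetation, assignment)
    } else {
      # direct mode: the generator's log-CWMs are the responses; coverage 1
      resp <- dataset$responses
      out <- data.frame(plot_id = resp$plot_id, stringsAsFactors = FALSE)
      for (tr in trait_names()) {
        lc <- resp[[paste0("log_cwm_", tr)]]
        out[[paste0("cwm_", tr)]] <- exp(lc)
        out[[paste0("log_cwm_", tr)]] <- lc
        out[[paste0("coverage_", tr)]] <- 1
      }
      out$coverage_min <- 1
      out
    }
  })
  log_stage("cwm", nrow(meta), nrow(cwm))

  # --- filters ---------------------------------------------------------------
  flt <- run_stage("filters", {
    meta_f <- meta[meta$plot_id %in% cwm$plot_id, , drop = FALSE]
    apply_filters(
      if (!is.null(community)) community$vegetation else
        data.frame(plot_id = cwm$plot_id, species = "direct", cover = 100),
      meta_f, climate[climate$plot_id %in% meta_f$plot_id, , drop = FALSE],
      cwm_coverage(cwm), cfg$filter_rules)
  })
  log_stage("filters", nrow(cwm), length(flt$plot_ids))
  kept <- flt$plot_ids

  # --- stratification --------------------------------------------------------
  if (isTRUE(cfg$stratify$enabled)) {
    kept2 <- run_stage("stratify", {
      meta_k <- meta[meta$plot_id %in% kept, , drop = FALSE]
      stratify_spatial(meta_k, cell_deg = cfg$stratify$cell_deg,
                       seed = derive_seed(cfg$seed, "stratify"))
    })
    log_stage("stratify", length(kept), length(kept2))
    kept <- kept2
  }
  meta <- meta[meta$plot_id %in% kept, , drop = FALSE]
  climate <- climate[climate$plot_id %in% kept, , drop = FALSE]
  habitat <- habitat[habitat$plot_id %in% kept, , drop = FALSE]
  cwm <- cwm[cwm$plot_id %in% kept, , drop = FALSE]

  # --- climate PCA -----------------------------------------------------------
  pca <- run_stage("pca", fit_climate_pca(climate, cfg$n_components))
  scores <- run_stage("pca", project_climate(climate, pca))
  log_stage("pca", nrow(climate), nrow(scores))

  # --- model fits ------------------------------------------------------------
  fits <- list()
  designs <- list()
  decomp_rows <- list()
  slope_tabs <- list()
  tally_tabs <- list()
  for (tr in cfg$traits) {
    for (m in cfg$models) {
      key <- sprintf("%s_model%d", tr, m)
      fit_obj <- run_stage(paste0("fit_", key), {
        cwm_m <- cwm
        if (m == 1) {
          ids <- balanced_subsample(habitat, level = 1,
                                    seed = derive_seed(cfg$seed, "balanced"))
          cwm_m <- cwm[cwm$plot_id %in% ids, , drop = FALSE]
        }
        des <- build_design(cwm_m, tr, scores, habitat, meta, model_id = m,
                            options = utils::modifyList(
                              cfg$model_options,
                              list(seed = derive_seed(cfg$seed, "knots"))))
        list(design = des, fit = fit_mixed_reml(des))
      })
      designs[[key]] <- fit_obj$design
      fits[[key]] <- fit_obj$fit
      vd <- r2_partition(fit_obj$fit, fit_obj$design)
      decomp_rows[[key]] <- decomposition_row(vd)
      if (m >= 3) {
        sl <- marginal_slopes(fit_obj$fit, fit_obj$design,
                              min_n = cfg$min_n_slopes)
        sl <- cbind(trait = tr, model_id = m, sl, stringsAsFactors = FALSE)
        slope_tabs[[key]] <- sl
        tl <- classify_and_tally(sl, habitat)
        tally_tabs[[key]] <- cbind(trait = tr, model_id = m, tl,
                                   stringsAsFactors = FALSE)
      }
      say("[fit] %s: loglik %.2f, %d iterations", key,
          fits[[key]]$loglik_reml, fits[[key]]$convergence$iterations)
    }
  }

  bind_or_empty <- function(lst, proto) {
    if (length(lst) > 0) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else proto
  }
  slopes <- bind_or_empty(slope_tabs, data.frame(
    trait = character(), model_id = integer(), habitat = character(),
    level = character(), pc = integer(), n_plots = integer(),
    slope = numeric(), se = numeric(), ci_low = numeric(), ci_high = numeric(),
    significant = logical(), suppressed = logical(),
    se_formula = character(), stringsAsFactors = FALSE))
  tallies <- bind_or_empty(tally_tabs, data.frame(
    trait = character(), model_id = integer(), pc = integer(),
    parent = character(), positive_significant = integer(),
    negative_significant = integer(), nonsignificant = integer(),
    suppressed = integer(), n_children = integer(), stringsAsFactors = FALSE))
  decompositions <- bind_or_empty(decomp_rows, data.frame(
    model_id = integer(), trait = character(), sigma2_fixed = numeric(),
    sigma2_intercept = numeric(), sigma2_slopes = numeric(),
    sigma2_spatial = numeric(), sigma2_residual = numeric(),
    r2_marginal = numeric(), r2_conditional = numeric(),
    r2_climate = numeric(), r2_habitat = numeric(), r2_spatial = numeric(),
    stringsAsFactors = FALSE))
  counts <- do.call(rbind, stage_counts)

  results <- list(filter_report = flt$report, stage_counts = counts,
                  slopes = slopes, tallies = tallies,
                  decompositions = decompositions, cwm = cwm,
                  explained_variance = data.frame(
                    component = seq_along(pca$explained_variance),
                    fraction = pca$explained_variance))
  manifest <- NULL
  if (!is.null(cfg$out_dir))
    manifest <- write_results(results, cfg$out_dir,
                              config = cfg[setdiff(names(cfg), "out_dir")],
                              seed = cfg$seed)

  structure(c(results, list(
    pca = pca, scores = scores, fits = fits, designs = designs,
    dataset = dataset, community = community, meta = meta, habitat = habitat,
    climate = climate, config = cfg, manifest = manifest
  )), class = "run_artifacts")
}
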