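# Synthetic landscapes with known mixed-model structure.
#
# The generator emulates the study conditions of a continental vegetation-plot
# analysis at desk scale: a 3-level nested habitat hierarchy, 19 correlated
# bioclimatic variables driven by a few latent gradients, and per-plot
# log-CWM responses that follow a linear mixed model with fixed climate-PC
# slopes, habitat random intercepts, habitat-specific random slopes, an
# optional spatial Gaussian-process field and Gaussian residuals.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the desk-scale study conditions: 4000 plots over a
#' 35-70 N / -10-30 E window, a 6 -> 18 -> 54 nested habitat hierarchy
#' (mirroring the 8 -> 40 -> 216 ratio of the full-scale classification at
#' quarter scale), 19 climate variables on 4 latent gradients, fixed slopes
#' beta = (0.3, -0.2, 0.1, 0) in log-trait units per unit PC score,
#' habitat random-intercept variance 0.5, no random-slope variance, residual
#' variance 1, spatial field off.
#'
#' @param n_plots number of plots.
#' @param n_habitats_per_level integer triple (level1, level2, level3);
#'   counts must be non-decreasing with divisible nesting (each child level a
#'   multiple of its parent).
#' @param lat_range,lon_range landscape extent in decimal degrees.
#' @param n_climate_vars number of climate variables (default 19).
#' @param n_latent_gradients number of latent climate gradients (<= 4 and
#'   <= `n_climate_vars`).
#' @param beta fixed slopes per climate PC (length 4).
#' @param tau0_sq habitat random-intercept variance (at `ranef_level`).
#' @param tau1_sq habitat random-slope variances per PC (length 4).
#' @param sigma_sq residual variance.
#' @param ranef_level habitat level (1, 2 or 3) carrying the random
#'   intercepts and slopes used for generation.
#' @param intercept_slope_cor correlation between a habitat's intercept and
#'   slope deviations (0 = independent, the default).
#' @param spatial_sd marginal standard deviation of the spatial field
#'   (0 disables).
#' @param spatial_range_km range of the exponential spatial covariance.
#' @param n_knots number of knots of the low-rank spatial process (<= 200).
#' @param trait_intercepts baseline log-CWM per trait (natural-log units of
#'   m, mm^2/mg, mg, m/g for height, SLA, seed mass, SRL).
#' @param seed master seed.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plots = 4000,
                             n_habitats_per_level = c(6L, 18L, 54L),
                             lat_range = c(35, 70),
                             lon_range = c(-10, 30),
                             n_climate_vars = 19,
                             n_latent_gradients = 4,
                             beta = c(0.3, -0.2, 0.1, 0),
                             tau0_sq = 0.5,
                             tau1_sq = c(0, 0, 0, 0),
                             sigma_sq = 1,
                             ranef_level = 3,
                             intercept_slope_cor = 0,
                             spatial_sd = 0,
                             spatial_range_km = 400,
                             n_knots = 100,
                             trait_intercepts = c(plant_height = -0.7, sla = 3,
                                                  seed_mass = 0.4, srl = 4.6),
                             seed = 1L) {
  cfg <- list(n_plots = as.integer(n_plots),
              n_habitats_per_level = as.integer(n_habitats_per_level),
              lat_range = lat_range, lon_range = lon_range,
              n_climate_vars = as.integer(n_climate_vars),
              n_latent_gradients = as.integer(n_latent_gradients),
              beta = beta, tau0_sq = tau0_sq, tau1_sq = tau1_sq,
              sigma_sq = sigma_sq, ranef_level = as.integer(ranef_level),
              intercept_slope_cor = intercept_slope_cor,
              spatial_sd = spatial_sd, spatial_range_km = spatial_range_km,
              n_knots = as.integer(n_knots),
              trait_intercepts = trait_intercepts, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  h <- cfg$n_habitats_per_level
  if (length(h) != 3 || any(h < 1) || any(diff(h) < 0) ||
      h[2] %% h[1] != 0 || h[3] %% h[2] != 0)
    hc_stop(paste("n_habitats_per_level must be three non-decreasing counts",
                  "with divisible nesting"), "habclim_config_error")
  if (cfg$tau0_sq < 0 || any(cfg$tau1_sq < 0) || cfg$sigma_sq < 0 ||
      cfg$spatial_sd < 0)
    hc_stop("all variances must be >= 0", "habclim_config_error")
  if (length(cfg$beta) != 4 || length(cfg$tau1_sq) != 4)
    hc_stop("beta and tau1_sq must have length 4", "habclim_config_error")
  if (cfg$n_latent_gradients > 4 || cfg$n_latent_gradients > cfg$n_climate_vars)
    hc_stop("n_latent_gradients must be <= 4 and <= n_climate_vars",
            "habclim_config_error")
  if (!cfg$ranef_level %in% 1:3)
    hc_stop("ranef_level must be 1, 2 or 3", "habclim_config_error")
  if (abs(cfg$intercept_slope_cor) > 1)
    hc_stop("intercept_slope_cor must lie in [-1, 1]", "habclim_config_error")
  invisible(cfg)
}

# nested habitat codes: level1 "H3", level2 "H3.2", level3 "H3.2.1"
habitat_codebook <- function(n_per_level) {
  l3 <- n_per_level[3]
  per2 <- n_per_level[3] / n_per_level[2]
  per1 <- n_per_level[2] / n_per_level[1]
  idx3 <- seq_len(l3)
  i2 <- ceiling(idx3 / per2)
  i1 <- ceiling(i2 / per1)
  j2 <- i2 - (i1 - 1) * per1
  j3 <- idx3 - (i2 - 1) * per2
  data.frame(level1 = paste0("H", i1),
             level2 = paste0("H", i1, ".", j2),
             level3 = paste0("H", i1, ".", j2, ".", j3),
             stringsAsFactors = FALSE)
}

# low-rank Gaussian-process field over plot coordinates:
# exponential covariance on great-circle distance, <= n_knots knots.
simulate_spatial_field <- function(lat, lon, sd, range_km, n_knots, seed) {
  n <- length(lat)
  if (sd <= 0) return(rep(0, n))
  with_seed(seed, {
    m <- min(n_knots, n)
    ki <- sample.int(n, m)
    K <- exp(-gc_dist_matrix(lat[ki], lon[ki], lat[ki], lon[ki]) / range_km)
    diag(K) <- diag(K) + 1e-8
    B <- exp(-gc_dist_matrix(lat, lon, lat[ki], lon[ki]) / range_km)
    L <- chol(K)                      # K = L'L
    u <- rnorm(m)
    # predictive-process draw: w = B K^{-1} L' u  has covariance B K^{-1} B'
    w <- drop(B %*% solve(K, t(L) %*% u))
    s <- sd(w)
    if (s > 0) w <- w * (sd / s)      # rescale to the nominal marginal sd
    w
  })
}

#' Generate a synthetic dataset with known mixed-model ground truth
#'
#' Plots are placed uniformly over the landscape and assigned uniformly to
#' the narrow habitats of the nested hierarchy. Climate variables are linear
#' mixtures of `n_latent_gradients` latent spatial gradients plus independent
#' noise, so a PCA recovers at most that many dominant axes. Direct-mode
#' log-CWM responses (one per trait) follow
#' `y = mu_t + X beta + a_h + sum_j b_hj x_j + s + e`, where `X` holds the
#' generator's own climate-PC scores standardized to unit variance, `a_h` and
#' `b_hj` are habitat deviations at `ranef_level`, `s` is the optional
#' spatial field and `e` is Gaussian residual noise. Fully reproducible from
#' the master seed via per-stage derived seeds.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset`: `meta`, `climate`, `habitat`
#'   tables (the [read_table()] schemas), `scores` (plot_id + unit-variance
#'   pc1..pc4 used for generation), `responses` (plot_id + `log_cwm_<trait>`),
#'   `pca` (the fitted [fit_climate_pca()] model), and `truth` (realized
#'   habitat deviations, spatial fields, stage seeds, expected variance
#'   components).
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_plots
  seed <- config$seed

  meta <- with_seed(derive_seed(seed, "plots"), {
    data.frame(
      plot_id = sprintf("P%05d", seq_len(n)),
      latitude = runif(n, config$lat_range[1], config$lat_range[2]),
      longitude = runif(n, config$lon_range[1], config$lon_range[2]),
      survey_year = sample(1960:2020, n, replace = TRUE),
      abundance_type = "cover",
      stringsAsFactors = FALSE
    )
  })

  cb <- habitat_codebook(config$n_habitats_per_level)
  hab_idx <- with_seed(derive_seed(seed, "habitats"),
                       sample.int(nrow(cb), n, replace = TRUE))
  habitat <- data.frame(plot_id = meta$plot_id, cb[hab_idx, ],
                        stringsAsFactors = FALSE)
  rownames(habitat) <- NULL

  climate <- with_seed(derive_seed(seed, "climate"), {
    L <- config$n_latent_gradients
    p <- config$n_climate_vars
    lat_s <- as.numeric(scale(meta$latitude))
    lon_s <- as.numeric(scale(meta$longitude))
    G <- matrix(0, n, L)
    shapes <- list(
      function() lat_s + 0.3 * rnorm(n),
      function() lon_s + 0.3 * rnorm(n),
      function() sin(meta$latitude / 6) + cos(meta$longitude / 9) + 0.3 * rnorm(n),
      function() lat_s * lon_s / 2 + 0.3 * rnorm(n)
    )
    for (l in seq_len(L)) G[, l] <- scale(shapes[[l]]())
    # orthogonalize the latent fields so the signal subspace has rank exactly L
    G <- scale(qr.Q(qr(G)))
    A <- qr.Q(qr(matrix(rnorm(p * L), p, L)))    # orthonormal mixing
    wts <- sqrt(c(8, 5, 3, 2))[seq_len(L)]
    X <- G %*% (t(A) * wts) + matrix(rnorm(n * p, sd = 0.4), n, p)
    out <- data.frame(plot_id = meta$plot_id, stringsAsFactors = FALSE)
    for (j in seq_len(p)) out[[paste0("bio", j)]] <- X[, j]
    out
  })
  climate <- validate_table(climate, "climate", source = "synthetic")

  pca <- fit_climate_pca(climate, n_components = 4)
  raw_scores <- project_climate(climate, pca)
  score_sd <- apply(as.matrix(raw_scores[, -1]), 2, sd)
  X <- sweep(as.matrix(raw_scores[, -1]), 2, score_sd, "/")
  scores <- data.frame(plot_id = meta$plot_id, X, stringsAsFactors = FALSE)
  names(scores) <- c("plot_id", paste0("pc", 1:4))

  lv_col <- paste0("level", config$ranef_level)
  groups <- sort(unique(habitat[[lv_col]]))
  g <- match(habitat[[lv_col]], groups)
  traits <- names(config$trait_intercepts)

  # habitat deviations: (intercept, slope1..4) per group, per trait;
  # intercept-slope correlation via an arrow-structured covariance
  sds <- sqrt(c(config$tau0_sq, config$tau1_sq))
  Sg <- diag(sds^2, 5)
  for (j in 2:5) {
    Sg[1, j] <- Sg[j, 1] <- config$intercept_slope_cor * sds[1] * sds[j]
  }
  eg <- eigen(Sg, symmetric = TRUE)
  if (min(eg$values) < -1e-10)
    hc_stop("intercept_slope_cor makes the random-effect covariance indefinite",
            "habclim_config_error")
  Sg_half <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 5) %*% t(eg$vectors)

  responses <- data.frame(plot_id = meta$plot_id, stringsAsFactors = FALSE)
  truth_effects <- list()
  spatial_fields <- list()
  stage_seeds <- list()
  for (tr in traits) {
    eff_seed <- derive_seed(seed, paste0("effects_", tr))
    dev <- with_seed(eff_seed,
                     matrix(rnorm(length(groups) * 5), length(groups), 5) %*%
                       t(Sg_half))
    colnames(dev) <- c("intercept", paste0("slope_pc", 1:4))
    rownames(dev) <- groups
    sp_seed <- derive_seed(seed, paste0("spatial_", tr))
    s <- simulate_spatial_field(meta$latitude, meta$longitude,
                                config$spatial_sd, config$spatial_range_km,
                                config$n_knots, sp_seed)
    res_seed <- derive_seed(seed, paste0("residual_", tr))
    e <- with_seed(res_seed, rnorm(n, sd = sqrt(config$sigma_sq)))
    y <- config$trait_intercepts[[tr]] + drop(X %*% config$beta) +
      dev[g, 1] + rowSums(X * dev[g, 2:5, drop = FALSE]) + s + e
    responses[[paste0("log_cwm_", tr)]] <- y
    truth_effects[[tr]] <- dev
    spatial_fields[[tr]] <- s
    stage_seeds[[tr]] <- list(effects = eff_seed, spatial = sp_seed,
                              residual = res_seed)
  }

  expected <- expected_variance_components(config, X)

  structure(list(
    config = config, meta = meta, climate = climate, habitat = habitat,
    scores = scores, responses = responses, pca = pca,
    truth = list(effects = truth_effects, spatial = spatial_fields,
                 stage_seeds = stage_seeds, score_sd = score_sd,
                 group_level = lv_col, groups = groups,
                 expected = expected, seed = seed)
  ), class = "synthetic_dataset")
}

#' Rebuild the direct-mode responses from the stored truth record
#'
#' Re-adds the residual noise from the stored stage seed to the deterministic
#' parts; byte-identical to `dataset$responses` by construction, which is the
#' reproducibility contract of the truth record.
#'
#' @param dataset a `synthetic_dataset`.
#' @return data.frame with the same shape as `dataset$responses`.
#' @export
reconstruct_responses <- function(dataset) {
  cfg <- dataset$config
  X <- as.matrix(dataset$scores[, paste0("pc", 1:4)])
  g <- match(dataset$habitat[[dataset$truth$group_level]],
             dataset$truth$groups)
  out <- data.frame(plot_id = dataset$meta$plot_id, stringsAsFactors = FALSE)
  for (tr in names(cfg$trait_intercepts)) {
    dev <- dataset$truth$effects[[tr]]
    e <- with_seed(dataset$truth$stage_seeds[[tr]]$residual,
                   rnorm(cfg$n_plots, sd = sqrt(cfg$sigma_sq)))
    out[[paste0("log_cwm_", tr)]] <- cfg$trait_intercepts[[tr]] +
      drop(X %*% cfg$beta) + dev[g, 1] +
      rowSums(X * dev[g, 2:5, drop = FALSE]) +
      dataset$truth$spatial[[tr]] + e
  }
  out
}

#' Expected variance components and R-squared of the generating model
#'
#' Plugs the generating variances into the variance-ratio formulas used by
#' the R-squared partition: the fixed component is the population variance of
#' `X beta` over plots; each random-slope component is the mean over plots of
#' `tau1_sq[j] * score_j^2`; marginal R-squared is fixed over total and
#' conditional R-squared adds the random and spatial components.
#'
#' @param config a [synthetic_config()].
#' @param climate_scores numeric matrix of the PC scores used for generation
#'   (plots x 4).
#' @return list of class `truth_summary`: `sigma2_fixed`,
#'   `sigma2_intercept`, `sigma2_slopes` (per PC), `sigma2_spatial`,
#'   `sigma2_residual`, `r2_marginal`, `r2_conditional`.
#' @export
expected_variance_components <- function(config, climate_scores) {
  climate_scores <- as.matrix(climate_scores)
  if (nrow(climate_scores) == 0 || ncol(climate_scores) != 4)
    hc_stop("climate_scores must be a non-empty plots x 4 matrix",
            "habclim_validation_error")
  fixed_part <- drop(climate_scores %*% config$beta)
  s2f <- pop_var(fixed_part)
  s2slopes <- vapply(1:4, function(j)
    config$tau1_sq[j] * mean(climate_scores[, j]^2), 0)
  s2sp <- config$spatial_sd^2
  total <- s2f + config$tau0_sq + sum(s2slopes) + s2sp + config$sigma_sq
  out <- list(sigma2_fixed = s2f,
              sigma2_intercept = config$tau0_sq,
              sigma2_slopes = setNames(s2slopes, paste0("pc", 1:4)),
              sigma2_spatial = s2sp,
              sigma2_residual = config$sigma_sq,
              r2_marginal = if (total > 0) s2f / total else 0,
              r2_conditional = if (total > 0)
                (s2f + config$tau0_sq + sum(s2slopes) + s2sp) / total else 0)
  class(out) <- "truth_summary"
  out
}

#' Emit species-level community tables consistent with the direct-mode targets
#'
#' For each plot, percent covers over the plot's habitat species pool are
#' chosen by exponential tilting (a softmax over species suitability, with
#' the tilting vector solved by Newton moment-matching) so that the
#' cover-weighted mean of the species' log traits matches the plot's
#' direct-mode log-CWM targets within `tolerance`. Plots whose 4-trait target
#' falls outside the convex hull of the pool's log-trait values are flagged,
#' not silently dropped. A configurable fraction of species can be emitted
#' without species-level trait rows (genus fallback) or without any trait
#' information at all, to exercise the coverage logic downstream.
#'
#' @param dataset a `synthetic_dataset` with direct-mode responses.
#' @param pool_config list: `species_per_habitat` (default 120), `pool_spread`
#'   (widening factor of the pool trait cloud relative to the habitat's
#'   target spread, default 2), `tolerance` (max abs deviation
#'   of realized from target log-CWM, default 0.05), `missing_species_frac`
#'   (fraction of species emitted with genus-level traits only, default 0),
#'   `none_frac` (fraction with no trait information, default 0),
#'   `min_share` (cover share below which a species is dropped, default 1e-3),
#'   `total_cover` (summed percent cover per plot, default 100).
#' @param seed integer seed.
#' @return list: `vegetation` and `traits` tables (the [read_table()]
#'   schemas), `flagged` (plot ids whose targets could not be matched),
#'   `pool` (the full species x trait pool, for reference).
#' @export
generate_communities <- function(dataset, pool_config = list(), seed = 1L) {
  pc <- utils::modifyList(
    list(species_per_habitat = 120, pool_spread = 2, tolerance = 0.05,
         missing_species_frac = 0, none_frac = 0, min_share = 1e-3,
         total_cover = 100),
    pool_config)
  traits <- names(dataset$config$trait_intercepts)
  y <- as.matrix(dataset$responses[, paste0("log_cwm_", traits)])
  hab1 <- dataset$habitat$level1
  habs <- sort(unique(hab1))

  # per-habitat species pools: log-traits drawn around the habitat's mean
  # target with the covariance of the habitat's own targets, widened by
  # pool_spread so the targets sit inside the pool's trait hull
  pool <- with_seed(derive_seed(seed, "species_pool"), {
    rows <- list()
    for (h in habs) {
      yh <- y[hab1 == h, , drop = FALSE]
      ctr <- colMeans(yh)
      Sig <- if (nrow(yh) > 4) stats::cov(yh) else diag(4)
      Sig <- Sig + diag(0.1, 4)
      L <- chol(Sig)
      S <- pc$species_per_habitat
      lt <- (matrix(rnorm(S * 4), S, 4) %*% L) * pc$pool_spread
      lt <- sweep(lt, 2, ctr, "+")
      dimnames(lt) <- NULL
      rows[[h]] <- data.frame(
        species = sprintf("Genus%s%02d sp%02d", gsub("[^0-9A-Za-z]", "", h),
                          ((seq_len(S) - 1) %% 12) + 1, seq_len(S)),
        habitat = h, lt, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    names(out)[3:6] <- paste0("log_", traits)
    out$genus <- vapply(strsplit(out$species, "\\s+"), `[`, "", 1L)
    rownames(out) <- NULL
    out
  })

  # exponential tilting: p_i(a) prop exp(a' f_i) over centred-and-scaled
  # natural-scale trait features f, so the cover-weighted arithmetic trait
  # means hit the natural-scale targets (the CWM is an arithmetic mean;
  # matching log-trait means would leave a Jensen gap). Solved by damped
  # Newton on the convex dual g(a) = log mean_i exp(a' f_i) - a' t, which is
  # bounded below exactly when the target lies in the pool's trait hull.
  tilt_weights <- function(F_nat, target_nat, max_iter = 300) {
    ctr <- colMeans(F_nat)
    scl <- apply(F_nat, 2, sd)
    scl[scl == 0] <- 1
    Fs <- sweep(sweep(F_nat, 2, ctr, "-"), 2, scl, "/")
    tg <- (target_nat - ctr) / scl
    gval <- function(a) {
      eta <- drop(Fs %*% a)
      mx <- max(eta)
      mx + log(mean(exp(eta - mx))) - sum(a * tg)
    }
    a <- rep(0, 4)
    g <- gval(a)
    for (it in seq_len(max_iter)) {
      eta <- drop(Fs %*% a)
      eta <- eta - max(eta)
      p <- exp(eta); p <- p / sum(p)
      mu <- drop(crossprod(Fs, p))
      grad <- mu - tg
      if (max(abs(grad)) < 1e-11) return(p)
      cen <- sweep(Fs, 2, mu, "-")
      V <- crossprod(cen * p, cen) + diag(1e-12, 4)
      step <- tryCatch(solve(V, -grad), error = function(e) -grad)
      alpha <- 1
      repeat {
        g_new <- gval(a + alpha * step)
        if (is.finite(g_new) && g_new <= g + 1e-4 * alpha * sum(grad * step))
          break
        alpha <- alpha / 2
        if (alpha < 1e-14) return(NULL)  # no descent: target outside the hull
      }
      a <- a + alpha * step
      g <- g_new
      if (max(abs(a)) > 1e4) return(NULL)
    }
    eta <- drop(Fs %*% a); eta <- eta - max(eta)
    p <- exp(eta); p <- p / sum(p)
    if (max(abs(drop(crossprod(Fs, p)) - tg)) < 1e-8) p else NULL
  }

  veg_rows <- vector("list", nrow(dataset$meta))
  flagged <- character(0)
  for (i in seq_len(nrow(dataset$meta))) {
    ph <- pool[pool$habitat == hab1[i], , drop = FALSE]
    Xp <- as.matrix(ph[, paste0("log_", traits)])
    F_nat <- exp(Xp)
    target_nat <- exp(y[i, ])
    if (nrow(ph) == 1) {
      # a one-species pool cannot bracket a target; the plot is flagged and
      # its CWM is that species' trait vector
      flagged <- c(flagged, dataset$meta$plot_id[i])
      veg_rows[[i]] <- data.frame(plot_id = dataset$meta$plot_id[i],
                                  species = ph$species, genus = ph$genus,
                                  cover = pc$total_cover,
                                  stringsAsFactors = FALSE)
      next
    }
    p <- tilt_weights(F_nat, target_nat)
    log_dev <- function(pr) {
      m <- drop(crossprod(F_nat, pr))
      if (any(m <= 0)) return(Inf)
      max(abs(log(m) - y[i, ]))
    }
    ok <- !is.null(p)
    if (ok) {
      keep <- p >= pc$min_share
      if (sum(keep) >= 2 && any(!keep)) {
        p2 <- rep(0, length(p))
        p2[keep] <- p[keep] / sum(p[keep])
        if (log_dev(p2) <= pc$tolerance) p <- p2
      }
      ok <- log_dev(p) <= pc$tolerance
    }
    if (!ok) {
      flagged <- c(flagged, dataset$meta$plot_id[i])
      # fall back to the two nearest pool species so the plot still has a community
      d2 <- rowSums(sweep(Xp, 2, y[i, ], "-")^2)
      p <- rep(0, nrow(ph))
      p[order(d2)[1:2]] <- c(0.6, 0.4)
    }
    nz <- which(p > 0)
    veg_rows[[i]] <- data.frame(plot_id = dataset$meta$plot_id[i],
                                species = ph$species[nz],
                                genus = ph$genus[nz],
                                cover = p[nz] * pc$total_cover,
                                stringsAsFactors = FALSE)
  }
  vegetation <- do.call(rbind, veg_rows)
  rownames(vegetation) <- NULL

  trait_tab <- with_seed(derive_seed(seed, "trait_table"), {
    S <- nrow(pool)
    status <- rep("species", S)
    n_none <- round(pc$none_frac * S)
    n_miss <- round(pc$missing_species_frac * S)
    reassign <- sample.int(S, min(S, n_none + n_miss))
    status[reassign[seq_len(min(n_none, length(reassign)))]] <- "none"
    if (length(reassign) > n_none)
      status[reassign[(n_none + 1):length(reassign)]] <- "genus_only"
    sp_rows <- data.frame(taxon = pool$species[status == "species"],
                          taxon_rank = "species",
                          exp(as.matrix(pool[status == "species",
                                             paste0("log_", traits)])),
                          stringsAsFactors = FALSE)
    names(sp_rows)[3:6] <- traits
    # genus rows: mean of member species on the natural scale; genera whose
    # every member is 'none' are withheld so provenance 'none' is reachable
    gvals <- exp(as.matrix(pool[, paste0("log_", traits)]))
    keep_g <- !pool$genus %in% pool$genus[status == "none"]
    gn <- unique(pool$genus[keep_g])
    gn_rows <- do.call(rbind, lapply(gn, function(g) {
      m <- colMeans(gvals[pool$genus == g, , drop = FALSE])
      cbind(data.frame(taxon = g, taxon_rank = "genus",
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(m, traits))))
    }))
    out <- rbind(sp_rows, gn_rows)
    rownames(out) <- NULL
    out
  })
  trait_tab <- validate_table(trait_tab, "traits", source = "synthetic")

  list(vegetation = validate_table(vegetation, "vegetation", "synthetic"),
       traits = trait_tab, flagged = flagged, pool = pool)
}
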