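# Simulation studies backing the validation claims: fixed-slope parameter
# recovery with CI coverage, the R-squared climate-share pattern across the
# habitat hierarchy, and a Monte-Carlo oracle for the induced random-slope
# variance formula. These are the workhorses of the analysis scripts, the
# test suite and the acceptance report.

#' Fixed-slope parameter recovery with confidence-interval coverage
#'
#' For each replicate, generates a direct-mode dataset, fits the generating
#' model (habitat random intercept plus the four habitat-specific climate-PC
#' slope blocks at the configured level) on the stored generating scores, and
#' records the fixed-slope estimates, their SEs and whether the 1.96-SE
#' interval covers the generating value.
#'
#' @param n_reps number of replicates.
#' @param config_args overrides for [synthetic_config()] (per-replicate seeds
#'   are derived from `seed`).
#' @param model_id model to fit (default 5, slopes at the narrow level).
#' @param trait trait whose response is analysed (default plant_height).
#' @param seed master seed.
#' @return list: `estimates` (data.frame rep x pc: estimate, se, covered),
#'   `summary` (per pc: bias, sd, coverage), `beta` (generating slopes).
#' @export
recovery_study <- function(n_reps = 200,
                           config_args = list(n_plots = 4000,
                                              beta = c(0.30, -0.20, 0.10, 0),
                                              tau0_sq = 0.50,
                                              tau1_sq = c(0.20, 0, 0, 0),
                                              sigma_sq = 1),
                           model_id = 5, trait = "plant_height", seed = 1L) {
  rows <- vector("list", n_reps)
  beta_true <- config_args$beta %||% synthetic_config()$beta
  for (r in seq_len(n_reps)) {
    cfg <- do.call(synthetic_config,
                   utils::modifyList(config_args,
                                     list(seed = derive_seed(seed, paste0("rep", r)))))
    d <- generate_dataset(cfg)
    des <- build_design(d$responses, trait, d$scores, d$habitat, d$meta,
                        model_id = model_id)
    fit <- fit_mixed_reml(des)
    est <- unname(fit$beta[2:5])
    se <- unname(fit$se_beta[2:5])
    rows[[r]] <- data.frame(rep = r, pc = 1:4, estimate = est, se = se,
                            covered = abs(est - beta_true) <= 1.96 * se)
  }
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(1:4, function(j) {
    e <- est[est$pc == j, ]
    data.frame(pc = j, beta = beta_true[j],
               bias = mean(e$estimate) - beta_true[j],
               sd = sd(e$estimate), coverage = mean(e$covered))
  }))
  list(estimates = est, summary = summ, beta = beta_true)
}

#' Climate-share R-squared pattern across the habitat hierarchy
#'
#' Generates direct-mode data with habitat-specific slope heterogeneity
#' injected at the narrow (level-3) habitats only -- or with none -- and fits
#' models 3, 4 and 5 to each replicate, recording the climate share of the
#' variance partition. With narrow-level heterogeneity the climate share
#' should be non-decreasing from the broad- to the narrow-level model; with
#' none the three shares should agree within Monte-Carlo noise.
#'
#' @param n_reps number of replicates.
#' @param tau1_sq slope-variance vector injected at the narrow level.
#' @param n_plots plots per replicate.
#' @param trait trait analysed.
#' @param seed master seed.
#' @return list: `r2` (data.frame rep x model: r2_climate, r2_marginal,
#'   r2_conditional), `monotone_fraction` (share of replicates with
#'   r2_climate non-decreasing across models 3 -> 4 -> 5), `mean_diff_53`
#'   (mean r2_climate difference model 5 minus model 3) and its `se`.
#' @export
r2_pattern_study <- function(n_reps = 50, tau1_sq = c(0.2, 0.2, 0.2, 0.2),
                             n_plots = 2000, trait = "sla", seed = 1L) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- synthetic_config(n_plots = n_plots, tau1_sq = tau1_sq,
                            ranef_level = 3,
                            seed = derive_seed(seed, paste0("pattern", r)))
    d <- generate_dataset(cfg)
    out <- lapply(3:5, function(m) {
      des <- build_design(d$responses, trait, d$scores, d$habitat, d$meta,
                          model_id = m)
      fit <- fit_mixed_reml(des)
      vd <- r2_partition(fit, des)
      data.frame(rep = r, model_id = m, r2_climate = vd$r2_climate,
                 r2_marginal = vd$r2_marginal,
                 r2_conditional = vd$r2_conditional)
    })
    rows[[r]] <- do.call(rbind, out)
  }
  r2 <- do.call(rbind, rows)
  wide <- stats::reshape(r2[, c("rep", "model_id", "r2_climate")],
                         idvar = "rep", timevar = "model_id",
                         direction = "wide")
  mono <- mean(wide$r2_climate.4 >= wide$r2_climate.3 - 1e-12 &
                 wide$r2_climate.5 >= wide$r2_climate.4 - 1e-12)
  d53 <- wide$r2_climate.5 - wide$r2_climate.3
  list(r2 = r2, monotone_fraction = mono, mean_diff_53 = mean(d53),
       se_diff_53 = sd(d53) / sqrt(length(d53)))
}

#' Monte-Carlo oracle for the induced random-slope variance formula
#'
#' Builds a one-block random-slope fixture with `n_groups` groups and a known
#' slope variance, computes the analytic component `tau^2 * mean(z^2)` used
#' by [r2_partition()], and compares it with the empirical variance of the
#' group-deviation contributions `Z b` pooled over many redraws of `b`.
#'
#' @param n_groups number of groups.
#' @param n_plots number of plots.
#' @param tau1_sq vector of slope variances (one per PC block checked).
#' @param n_draws Monte-Carlo redraws of the group deviations.
#' @param seed master seed.
#' @return data.frame per slope block: `analytic`, `mc`, `rel_err`.
#' @export
r2_slope_oracle <- function(n_groups = 50, n_plots = 2000,
                            tau1_sq = c(0.3, 0.15, 0.05, 0.2),
                            n_draws = 10000, seed = 1L) {
  with_seed(derive_seed(seed, "r2oracle"), {
    g <- sample.int(n_groups, n_plots, replace = TRUE)
    z_sd <- c(0.8, 1, 1.3, 1.1)
    out <- lapply(seq_along(tau1_sq), function(j) {
      z <- rnorm(n_plots, sd = z_sd[((j - 1) %% 4) + 1])
      analytic <- tau1_sq[j] * mean(z^2)
      # pooled variance of Z b over redraws, accumulated in chunks
      s1 <- 0; s2 <- 0
      done <- 0
      while (done < n_draws) {
        nd <- min(1000, n_draws - done)
        b <- matrix(rnorm(n_groups * nd, sd = sqrt(tau1_sq[j])), n_groups, nd)
        contrib <- z * b[g, , drop = FALSE]
        s1 <- s1 + sum(contrib)
        s2 <- s2 + sum(contrib^2)
        done <- done + nd
      }
      nn <- n_plots * n_draws
      mc <- s2 / nn - (s1 / nn)^2
      data.frame(pc = j, analytic = analytic, mc = mc,
                 rel_err = abs(analytic - mc) / analytic)
    })
    do.call(rbind, out)
  })
}

#' Balanced one-way random-intercept fixture: REML versus closed-form ANOVA
#'
#' On a balanced one-way layout the REML variance components coincide with
#' the ANOVA moment estimators (within mean square, and the between-group
#' mean square minus the within, over the group size). The fixture keeps the
#' between-group signal strong enough that the ANOVA estimator is interior.
#'
#' @param n_groups,group_size layout.
#' @param tau0_sq,sigma_sq generating variances.
#' @param seed seed.
#' @return list: `anova` and `reml` named vectors (tau0_sq, sigma_sq) and
#'   `max_rel_err`.
#' @export
anova_reml_check <- function(n_groups = 30, group_size = 10, tau0_sq = 1,
                             sigma_sq = 1, seed = 1L) {
  dat <- with_seed(derive_seed(seed, "anova"), {
    g <- factor(rep(seq_len(n_groups), each = group_size))
    y <- rnorm(n_groups, sd = sqrt(tau0_sq))[g] +
      rnorm(n_groups * group_size, sd = sqrt(sigma_sq))
    list(g = g, y = y)
  })
  n <- length(dat$y)
  msw <- sum(tapply(dat$y, dat$g, function(v) sum((v - mean(v))^2))) /
    (n_groups * (group_size - 1))
  msb <- group_size *
    sum((tapply(dat$y, dat$g, mean) - mean(dat$y))^2) / (n_groups - 1)
  anova_est <- c(tau0_sq = (msb - msw) / group_size, sigma_sq = msw)
  design <- list(y = dat$y, X = cbind(`(Intercept)` = rep(1, n)),
                 blocks = list(list(name = "group", type = "intercept",
                                    level = 1L, groups = dat$g,
                                    covariate = rep(1, n))),
                 spatial_basis = NULL, weights = NULL, model_id = 2,
                 trait = "fixture", n = n)
  fit <- fit_mixed_reml(design)
  reml_est <- c(tau0_sq = fit$variance_components$variance[1],
                sigma_sq = fit$variance_components$variance[2])
  list(anova = anova_est, reml = reml_est,
       max_rel_err = max(abs(reml_est - anova_est) / anova_est))
}
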