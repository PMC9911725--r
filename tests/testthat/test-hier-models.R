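test_that("designs follow the model hierarchy structure", {
  d <- small_dataset(seed = 31, n = 400)
  cwm <- d$responses
  des1 <- build_design(cwm, "sla", d$scores, d$habitat, d$meta, model_id = 1)
  expect_length(des1$blocks, 0)
  expect_equal(ncol(des1$X), 5L)

  des2 <- build_design(cwm, "sla", d$scores, d$habitat, d$meta, model_id = 2)
  expect_length(des2$blocks, 1)
  expect_equal(des2$blocks[[1]]$type, "intercept")
  expect_equal(nlevels(des2$blocks[[1]]$groups), 4L)

  des3 <- build_design(cwm, "sla", d$scores, d$habitat, d$meta, model_id = 3)
  expect_length(des3$blocks, 5)
  expect_equal(vapply(des3$blocks, `[[`, "", "type"),
               c("intercept", rep("slope", 4)))
  expect_true(all(vapply(des3$blocks, function(b) nlevels(b$groups), 0L) == 4L))

  des5 <- build_design(cwm, "sla", d$scores, d$habitat, d$meta, model_id = 5)
  expect_true(all(vapply(des5$blocks, function(b) nlevels(b$groups), 0L) == 16L))
  expect_equal(unique(vapply(des5$blocks, `[[`, 0L, "level")), 3L)

  expect_error(build_design(cwm, "sla", d$scores, d$habitat, d$meta, 6),
               "model_id")
  expect_error(build_design(cwm, "biomass", d$scores, d$habitat, d$meta, 1),
               "absent")
})

test_that("the spherical smooth basis has the stated geometry", {
  d <- small_dataset(seed = 32, n = 200)
  sb <- spherical_smooth_basis(d$meta, k = 12, seed = 1)
  expect_equal(ncol(sb$basis), 12L)
  expect_equal(dim(sb$penalty), c(12L, 12L))
  # penalty symmetric positive definite
  expect_equal(sb$penalty, t(sb$penalty))
  expect_true(min(eigen(sb$penalty, symmetric = TRUE,
                        only.values = TRUE)$values) > 0)
  # a plot coincident with a knot attains the kernel value at distance zero
  i <- which(d$meta$latitude == sb$knots$latitude[1] &
               d$meta$longitude == sb$knots$longitude[1])[1]
  expect_equal(sb$basis[i, 1], 1)
  # shifting all longitudes leaves distances, hence the basis, unchanged
  meta2 <- d$meta
  meta2$longitude <- meta2$longitude + 25
  sb2 <- spherical_smooth_basis(meta2, k = 12, seed = 1,
                                range_km = sb$range_km)
  expect_equal(sb2$basis, sb$basis, tolerance = 1e-9)
  expect_error(spherical_smooth_basis(d$meta, k = 2), "k must be")
  expect_error(spherical_smooth_basis(d$meta[1:5, ], k = 10),
               "distinct locations")
})

test_that("a noiseless linear response is recovered exactly", {
  d <- small_dataset(seed = 33, n = 300)
  X <- as.matrix(d$scores[, paste0("pc", 1:4)])
  beta <- c(2, 0.5, -0.25, 0.1, 0)
  cwm <- data.frame(plot_id = d$scores$plot_id,
                    log_cwm_sla = beta[1] + drop(X %*% beta[-1]))
  des <- build_design(cwm, "sla", d$scores, d$habitat, d$meta, model_id = 1)
  fit <- fit_mixed_reml(des)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-9)
  expect_lt(fit$sigma2, 1e-18)
})

test_that("balanced one-way REML equals the closed-form ANOVA estimators", {
  chk <- anova_reml_check(n_groups = 30, group_size = 10, seed = 5)
  expect_lt(chk$max_rel_err, 1e-6)
})

test_that("REML matches an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- small_dataset(seed = 34, n = 1000, tau1 = c(0.25, 0, 0.1, 0))
  des <- build_design(d$responses, "seed_mass", d$scores, d$habitat, d$meta,
                      model_id = 3)
  fit <- fit_mixed_reml(des)
  dat <- data.frame(y = des$y, des$X[, -1],
                    g = d$habitat$level1[match(des$plot_id, d$habitat$plot_id)])
  lf <- suppressMessages(lme4::lmer(
    y ~ pc1 + pc2 + pc3 + pc4 + (1 | g) + (0 + pc1 | g) + (0 + pc2 | g) +
      (0 + pc3 | g) + (0 + pc4 | g), data = dat, REML = TRUE))
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(unname(fit$se_beta),
               unname(sqrt(diag(as.matrix(vcov(lf))))), tolerance = 1e-3)
  expect_equal(fit$loglik_reml, as.numeric(logLik(lf)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$variance_components$variance[1], vc$vcov[1],
               tolerance = 1e-3)
  expect_equal(fit$sigma2, vc$vcov[6], tolerance = 1e-3)
  # BLUPs against lme4's conditional modes
  re <- lme4::ranef(lf)$g
  mine <- fit$blups[fit$blups$block == "intercept_level1", ]
  expect_equal(mine$estimate[match(rownames(re), mine$group)],
               re[["(Intercept)"]], tolerance = 1e-3)
})

test_that("forcing all variance ratios to zero reproduces weighted least squares", {
  d <- small_dataset(seed = 35, n = 500, tau1 = c(0.2, 0, 0, 0))
  w <- runif(500, 0.5, 1)
  cwm <- d$responses
  cwm$coverage_sla <- w
  des <- build_design(cwm, "sla", d$scores, d$habitat, d$meta, model_id = 3,
                      options = list(weights = TRUE))
  fit <- fit_mixed_reml(des, options = list(lambda_floor = 1e-12,
                                            lambda_cap = 1e-12))
  wls <- lm(des$y ~ des$X - 1, weights = des$weights)
  expect_equal(unname(fit$beta), unname(coef(wls)), tolerance = 1e-6)
})

test_that("observation weights scale the residual precision as in lme4", {
  skip_if_not_installed("lme4")
  d <- small_dataset(seed = 36, n = 600)
  w <- runif(600, 0.3, 1)
  cwm <- d$responses
  cwm$coverage_srl <- w
  des <- build_design(cwm, "srl", d$scores, d$habitat, d$meta, model_id = 2,
                      options = list(weights = TRUE))
  fit <- fit_mixed_reml(des)
  dat <- data.frame(y = des$y, des$X[, -1],
                    g = d$habitat$level1[match(des$plot_id, d$habitat$plot_id)],
                    w = des$weights)
  lf <- suppressMessages(lme4::lmer(y ~ pc1 + pc2 + pc3 + pc4 + (1 | g),
                                    data = dat, weights = w, REML = TRUE))
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$sigma2, sigma(lf)^2, tolerance = 1e-4)
})

test_that("the REML criterion trace is monotone over accepted steps", {
  d <- small_dataset(seed = 37, n = 800, tau1 = c(0.3, 0.1, 0, 0))
  des <- build_design(d$responses, "plant_height", d$scores, d$habitat, d$meta,
                      model_id = 5)
  fit <- fit_mixed_reml(des)
  expect_true(all(diff(fit$convergence$trace) <= 1e-10))
  expect_true(fit$convergence$converged)
  expect_true(all(fit$variance_components$variance >= 0))
  # BLUPs within a block of a balanced-ish design nearly centre on zero
  ints <- fit$blups[fit$blups$type == "intercept", "estimate"]
  expect_lt(abs(mean(ints)), 3 * sd(ints) / sqrt(length(ints)) + 0.05)
})

test_that("a superfluous spatial smooth does not move the fixed slopes", {
  d <- small_dataset(seed = 38, n = 700)  # spatial_sd = 0 in generation
  des0 <- build_design(d$responses, "sla", d$scores, d$habitat, d$meta,
                       model_id = 2)
  fit0 <- fit_mixed_reml(des0)
  des1 <- build_design(d$responses, "sla", d$scores, d$habitat, d$meta,
                       model_id = 2, options = list(spatial = TRUE, k = 40))
  fit1 <- fit_mixed_reml(des1)
  expect_true(all(abs(fit1$beta[-1] - fit0$beta[-1]) < fit0$se_beta[-1]))
})

test_that("a spatial field is absorbed by the smooth, not by the climate slopes", {
  cfg <- synthetic_config(n_plots = 900, n_habitats_per_level = c(4, 8, 16),
                          spatial_sd = 0.7, spatial_range_km = 600, seed = 39)
  d <- generate_dataset(cfg)
  des <- build_design(d$responses, "plant_height", d$scores, d$habitat, d$meta,
                      model_id = 2, options = list(spatial = TRUE, k = 60))
  fit <- fit_mixed_reml(des)
  sp_var <- fit$variance_components$variance[
    fit$variance_components$type == "spatial"]
  expect_gt(sp_var, 0.001)
  expect_true(all(abs(fit$beta[2:5] - c(0.3, -0.2, 0.1, 0)) < 0.15))
})

test_that("balanced subsampling draws the minimum group size from every habitat", {
  set.seed(40)
  sizes <- c(A = 5000, B = 3000, C = 2932)
  hab <- data.frame(
    plot_id = sprintf("b%05d", seq_len(sum(sizes))),
    level1 = rep(names(sizes), sizes),
    level2 = NA_character_, level3 = NA_character_,
    stringsAsFactors = FALSE)
  ids <- balanced_subsample(hab, level = 1, seed = 2)
  tab <- table(hab$level1[match(ids, hab$plot_id)])
  expect_true(all(tab == 2932))
  # equal group sizes: everything is retained
  hab_eq <- data.frame(plot_id = sprintf("e%03d", 1:60),
                       level1 = rep(c("B", "C"), each = 30),
                       stringsAsFactors = FALSE)
  expect_setequal(balanced_subsample(hab_eq, 1, seed = 3), hab_eq$plot_id)
  # determinism
  expect_identical(ids, balanced_subsample(hab, level = 1, seed = 2))
  expect_error(balanced_subsample(hab[0, ], 1, seed = 1), "empty habitat")
})

test_that("degenerate fits raise informative errors", {
  d <- small_dataset(seed = 41, n = 100)
  des <- build_design(d$responses, "sla", d$scores, d$habitat, d$meta, 1)
  des$X <- cbind(des$X, dup = des$X[, 2])
  expect_error(fit_mixed_reml(des), "singular")
  des2 <- build_design(d$responses, "sla", d$scores, d$habitat, d$meta, 1)
  des2$y <- des2$y[1:4]
  des2$X <- des2$X[1:4, ]
  expect_error(fit_mixed_reml(des2), "exceed")
})
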