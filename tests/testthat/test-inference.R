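fit_small <- function(seed = 51, n = 1500, tau1 = c(0.3, 0, 0, 0),
                      model_id = 3, trait = "plant_height", ...) {
  d <- small_dataset(seed = seed, n = n, tau1 = tau1, ...)
  des <- build_design(d$responses, trait, d$scores, d$habitat, d$meta,
                      model_id = model_id)
  list(d = d, des = des, fit = fit_mixed_reml(des))
}

test_that("marginal slopes combine fixed effects and BLUPs with joint SEs", {
  fs <- fit_small()
  sl <- marginal_slopes(fs$fit, fs$des, min_n = 100)
  # CI arithmetic: +/- 1.96 SE; significance iff 0 outside the interval
  expect_equal(sl$ci_low, sl$slope - 1.96 * sl$se)
  expect_equal(sl$ci_high, sl$slope + 1.96 * sl$se)
  unsup <- !sl$suppressed
  expect_equal(sl$significant[unsup],
               (sl$ci_low > 0 | sl$ci_high < 0)[unsup])
  # a slope of 0.5 with SE 0.2 has CI [0.108, 0.892] and is significant
  expect_equal(0.5 + c(-1.96, 1.96) * 0.2, c(0.108, 0.892))
  # across-habitat rows carry the fixed effect
  all_rows <- sl[is.na(sl$habitat), ]
  expect_equal(all_rows$slope, unname(fs$fit$beta[2:5]))
  expect_equal(all_rows$se, unname(fs$fit$se_beta[2:5]))
  # habitat slope = fixed + BLUP
  bl <- fs$fit$blups[fs$fit$blups$block == "slope_pc1_level1", ]
  hs <- sl[!is.na(sl$habitat) & sl$pc == 1, ]
  expect_equal(hs$slope[match(bl$group, hs$habitat)],
               unname(fs$fit$beta["pc1"]) + bl$estimate)
  # joint SE is at least the conditional BLUP SE contribution and recorded
  expect_true(all(hs$se_formula == "joint"))
  expect_error(marginal_slopes(fit_small(model_id = 2)$fit, NULL),
               "random slopes")
})

test_that("a zero BLUP deviation leaves the habitat slope at the fixed effect", {
  # data generated without slope heterogeneity: blocks whose variance is
  # estimated at the floor have (numerically) zero BLUPs, and their habitat
  # slopes must collapse onto the fixed slope
  fs <- fit_small(seed = 52, tau1 = c(0, 0, 0, 0))
  sl <- marginal_slopes(fs$fit, fs$des, min_n = 10)
  hs <- sl[!is.na(sl$habitat), ]
  floored <- which(fs$fit$lambda[paste0("slope_pc", 1:4, "_level1")] < 1e-7)
  expect_gt(length(floored), 0)
  for (j in floored) {
    dev <- abs(hs$slope[hs$pc == j] - fs$fit$beta[j + 1])
    expect_true(all(dev < 1e-4))
  }
  # and in general the slope is exactly fixed effect plus BLUP
  bl <- fs$fit$blups
  for (j in 1:4) {
    bj <- bl[bl$block == paste0("slope_pc", j, "_level1"), ]
    hj <- hs[hs$pc == j, ]
    expect_equal(hj$slope[match(bj$group, hj$habitat)],
                 unname(fs$fit$beta[j + 1]) + bj$estimate)
  }
})

test_that("slopes from habitats with fewer than min_n plots are suppressed", {
  fs <- fit_small(seed = 53, n = 900, model_id = 5)
  sl <- marginal_slopes(fs$fit, fs$des, min_n = 100)
  hs <- sl[!is.na(sl$habitat), ]
  expect_equal(hs$suppressed, hs$n_plots < 100)
  expect_true(any(hs$suppressed))  # 900 plots over 16 narrow habitats
  expect_true(all(is.na(hs$significant[hs$suppressed])))
  # an explicit 99-plot habitat is suppressed, a 100-plot one is not
  expect_true(all(hs$suppressed[hs$n_plots == 99]))
  expect_false(any(hs$suppressed[hs$n_plots >= 100]))
})

test_that("tallies count slope classes by level-1 parent and are order-invariant", {
  slopes <- data.frame(
    habitat = c("A1", "A2", "A3", "A4", "A5"), level = "2", pc = 1L,
    n_plots = c(500, 400, 300, 200, 50),
    slope = c(0.5, 0.3, -0.4, 0.05, 0.9),
    se = c(0.1, 0.1, 0.1, 0.1, 0.1), stringsAsFactors = FALSE)
  slopes$ci_low <- slopes$slope - 1.96 * slopes$se
  slopes$ci_high <- slopes$slope + 1.96 * slopes$se
  slopes$suppressed <- slopes$n_plots < 100
  slopes$significant <- ifelse(slopes$suppressed, NA,
                               slopes$ci_low > 0 | slopes$ci_high < 0)
  hab <- data.frame(plot_id = paste0("t", 1:5),
                    level1 = "A", level2 = c("A1", "A2", "A3", "A4", "A5"),
                    level3 = NA, stringsAsFactors = FALSE)
  tl <- classify_and_tally(slopes, hab)
  expect_equal(tl$positive_significant, 2L)
  expect_equal(tl$negative_significant, 1L)
  expect_equal(tl$nonsignificant, 1L)
  expect_equal(tl$suppressed, 1L)
  expect_equal(tl$n_children, 5L)
  # permutation invariance
  tl2 <- classify_and_tally(slopes[c(4, 2, 5, 1, 3), ], hab)
  expect_identical(tl, tl2)
  # a CI spanning zero is nonsignificant
  expect_false(slopes$significant[4])
  # missing parent mapping is an error
  hab2 <- hab[hab$level2 != "A3", ]
  expect_error(classify_and_tally(slopes, hab2), "parent")
})

test_that("R2 partition reduces to the fixed-effects identity without random terms", {
  d <- small_dataset(seed = 54, n = 500)
  des <- build_design(d$responses, "srl", d$scores, d$habitat, d$meta, 1)
  fit <- fit_mixed_reml(des)
  vd <- r2_partition(fit, des)
  s2f <- mean((drop(des$X %*% fit$beta) - mean(des$X %*% fit$beta))^2)
  expect_equal(vd$r2_marginal, s2f / (s2f + fit$sigma2))
  expect_equal(vd$r2_marginal, vd$r2_conditional)
  expect_equal(vd$r2_habitat, 0)
})

test_that("random-intercept models satisfy the conditional-minus-marginal identity", {
  fs <- fit_small(seed = 55, model_id = 2)
  vd <- r2_partition(fs$fit, fs$des)
  tau0 <- fs$fit$variance_components$variance[1]
  expect_equal(vd$r2_conditional - vd$r2_marginal, tau0 / vd$total,
               tolerance = 1e-12)
  expect_true(vd$r2_marginal <= vd$r2_conditional)
  expect_true(vd$r2_conditional <= 1)
})

test_that("slope components match the Monte-Carlo induced-variance oracle", {
  or <- r2_slope_oracle(n_groups = 50, n_plots = 2000, n_draws = 10000,
                        seed = 9)
  expect_true(all(or$rel_err < 0.02))
})

test_that("shares partition the total variance and spatial stays out of climate", {
  cfg <- synthetic_config(n_plots = 800, n_habitats_per_level = c(4, 8, 16),
                          tau1_sq = c(0.2, 0, 0, 0), spatial_sd = 0.5,
                          seed = 56)
  d <- generate_dataset(cfg)
  des <- build_design(d$responses, "sla", d$scores, d$habitat, d$meta, 3,
                      options = list(spatial = TRUE, k = 40))
  fit <- fit_mixed_reml(des)
  vd <- r2_partition(fit, des)
  resid_share <- vd$sigma2_residual / vd$total
  expect_equal(vd$r2_climate + vd$r2_habitat + vd$r2_spatial + resid_share, 1,
               tolerance = 1e-10)
  # conditional includes the spatial share, climate does not
  expect_equal(vd$r2_conditional - vd$r2_marginal,
               (sum(vd$components)) / vd$total, tolerance = 1e-12)
  vd2 <- r2_partition(fit, des, spatial_in_climate = TRUE)
  expect_equal(vd2$r2_climate - vd$r2_climate, vd$r2_spatial)
})

test_that("the fitted marginal R2 tracks the generating truth", {
  # averaged over seeds, the model-based marginal R2 matches the
  # generating-side expectation
  diffs <- vapply(1:8, function(s) {
    cfg <- synthetic_config(n_plots = 2500, n_habitats_per_level = c(4, 12, 36),
                            tau1_sq = c(0.2, 0, 0, 0), seed = 600 + s)
    d <- generate_dataset(cfg)
    des <- build_design(d$responses, "plant_height", d$scores, d$habitat,
                        d$meta, 5)
    fit <- fit_mixed_reml(des)
    vd <- r2_partition(fit, des)
    vd$r2_marginal - d$truth$expected$r2_marginal
  }, 0)
  expect_lt(abs(mean(diffs)), 0.02)
})
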