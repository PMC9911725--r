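# From fitted models to habitat-specific marginal slopes, slope-sign tallies
# and marginal/conditional R-squared variance partitions.

#' Habitat-specific marginal slopes with confidence intervals
#'
#' For each climate PC `j` and habitat `h`, the marginal slope is the fixed
#' effect plus the habitat's BLUP deviation, `beta_j + b_hj`. Its standard
#' error combines the fixed-effect variance, the BLUP's conditional variance
#' and twice their covariance, all taken from the joint Henderson covariance
#' of the fit (recorded as `se_formula = "joint"`; if a fit lacks the joint
#' covariance the cross term is 0 and `"independent"` is recorded). The
#' across-habitat slope is the fixed effect with its own SE. Confidence
#' limits are `slope +/- 1.96 * se`; an interval excluding zero is flagged
#' significant (approximately p < 0.05, two-sided). Estimates from habitats
#' with fewer than `min_n` plots are suppressed: reported but stripped of any
#' significance claim.
#'
#' @param fit a `fitted_model` from a model with random slopes (models 3-5).
#' @param design the matching `model_design`.
#' @param min_n suppression threshold on the habitat plot count (default 100).
#' @return data.frame of slope estimates: habitat (NA for the across-habitat
#'   row), level, pc, n_plots, slope, se, ci_low, ci_high, significant,
#'   suppressed, se_formula.
#' @export
marginal_slopes <- function(fit, design, min_n = 100) {
  blocks <- fit$design_info$blocks
  slope_blocks <- which(vapply(blocks, `[[`, "", "type") == "slope")
  if (length(slope_blocks) == 0)
    hc_stop("habitat-specific slopes require a model with random slopes (models 3-5)",
            "habclim_validation_error")
  p <- length(fit$beta)
  rows <- list()
  for (j in 1:4) {
    bj <- j + 1L  # fixed-effect index of pc j (after the intercept)
    rows[[length(rows) + 1]] <- data.frame(
      habitat = NA_character_, level = "all", pc = j,
      n_plots = fit$design_info$n, slope = unname(fit$beta[bj]),
      se = unname(fit$se_beta[bj]), stringsAsFactors = FALSE)
  }
  for (k in slope_blocks) {
    info <- blocks[[k]]
    j <- info$pc %||% as.integer(sub("slope_pc(\\d).*", "\\1", info$name))
    bj <- j + 1L
    ii <- fit$design_info$idx[[k]]
    bl <- fit$blups[fit$blups$block == info$name, , drop = FALSE]
    if (!is.null(fit$joint)) {
      Ci <- fit$joint$Cinv
      vv <- fit$sigma2 * (Ci[bj, bj] + diag(Ci)[p + ii] + 2 * Ci[bj, p + ii])
      formula_used <- "joint"
    } else {
      vv <- fit$se_beta[bj]^2 + bl$cond_se^2
      formula_used <- "independent"
    }
    rows[[length(rows) + 1]] <- data.frame(
      habitat = bl$group, level = as.character(info$level), pc = j,
      n_plots = bl$n_group, slope = unname(fit$beta[bj]) + bl$estimate,
      se = sqrt(pmax(vv, 0)), se_formula = formula_used,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    if (!"se_formula" %in% names(r)) r$se_formula <- "joint"
    r
  }))
  out$ci_low <- out$slope - 1.96 * out$se
  out$ci_high <- out$slope + 1.96 * out$se
  out$suppressed <- out$n_plots < min_n & !is.na(out$habitat)
  out$significant <- ifelse(out$suppressed, NA,
                            out$ci_low > 0 | out$ci_high < 0)
  rownames(out) <- NULL
  out[, c("habitat", "level", "pc", "n_plots", "slope", "se", "ci_low",
          "ci_high", "significant", "suppressed", "se_formula")]
}

#' Tally slope signs and significance by broad-habitat parent
#'
#' Classifies each unsuppressed habitat-specific slope as significantly
#' positive, significantly negative or nonsignificant and counts the classes
#' per (climate PC, level-1 parent habitat); suppressed estimates are counted
#' separately. Counts per row sum to the number of child habitats.
#'
#' @param slopes output of [marginal_slopes()] (one trait, one level).
#' @param habitats habitat assignment table providing the level-to-parent
#'   mapping.
#' @return data.frame: pc, parent, positive_significant,
#'   negative_significant, nonsignificant, suppressed, n_children.
#' @export
classify_and_tally <- function(slopes, habitats) {
  sl <- slopes[!is.na(slopes$habitat), , drop = FALSE]
  if (nrow(sl) == 0)
    hc_stop("no habitat-specific slopes to tally", "habclim_validation_error")
  lv <- unique(sl$level)
  if (length(lv) != 1)
    hc_stop("slopes must come from a single habitat level",
            "habclim_validation_error")
  col <- paste0("level", lv)
  map <- unique(habitats[!is.na(habitats[[col]]), c(col, "level1")])
  parent <- map$level1[match(sl$habitat, map[[col]])]
  if (anyNA(parent))
    hc_stop(sprintf("habitat(s) missing a level-1 parent mapping: %s",
                    paste(unique(sl$habitat[is.na(parent)]), collapse = ", ")),
            "habclim_validation_error")
  cls <- ifelse(sl$suppressed, "suppressed",
                ifelse(is.na(sl$significant) | !sl$significant, "nonsignificant",
                       ifelse(sl$slope > 0, "positive_significant",
                              "negative_significant")))
  key <- interaction(sl$pc, parent, drop = FALSE)
  agg <- table(data.frame(pc = sl$pc, parent = parent,
                          class = factor(cls, levels = c(
                            "positive_significant", "negative_significant",
                            "nonsignificant", "suppressed"))))
  out <- as.data.frame.table(agg, responseName = "count",
                             stringsAsFactors = FALSE)
  out <- stats::reshape(out, idvar = c("pc", "parent"), timevar = "class",
                        direction = "wide")
  names(out) <- sub("^count\\.", "", names(out))
  out <- out[out$positive_significant + out$negative_significant +
               out$nonsignificant + out$suppressed > 0, , drop = FALSE]
  out$n_children <- out$positive_significant + out$negative_significant +
    out$nonsignificant + out$suppressed
  out$pc <- as.integer(out$pc)
  out <- out[order(out$pc, out$parent), ]
  rownames(out) <- NULL
  out
}

#' Marginal/conditional R-squared partition from variance components
#'
#' The fixed component is the population variance of the fixed linear
#' predictor over the analysis rows (the spatial smooth is never part of it).
#' Each random-intercept component contributes its estimated variance; each
#' random-slope component contributes its variance times the mean squared
#' covariate (the mean diagonal of the induced covariance); the spatial
#' smooth contributes its variance times the mean squared row norm of its
#' reparameterised basis. Marginal R-squared is fixed over total; conditional
#' adds every random and spatial component; the climate share is fixed plus
#' the slope components and the habitat share is the intercept component. By
#' default the spatial share enters the conditional R-squared but not the
#' climate share, since the smooth models spatial dependence, not climate
#' (set `spatial_in_climate = TRUE` to change the convention).
#'
#' @param fit a converged `fitted_model`.
#' @param design the matching `model_design`.
#' @param spatial_in_climate include the spatial share in `r2_climate`
#'   (default FALSE).
#' @return list of class `variance_decomposition`: `model_id`, `trait`,
#'   `sigma2_fixed`, `components` (named, per random block), `sigma2_residual`,
#'   `total`, `r2_marginal`, `r2_conditional`, `r2_climate`, `r2_habitat`,
#'   `r2_spatial`.
#' @export
r2_partition <- function(fit, design, spatial_in_climate = FALSE) {
  if (!is.null(fit$convergence) && !isTRUE(fit$convergence$converged))
    hc_stop("r2_partition requires a converged fit", "habclim_validation_error")
  if (any(!is.finite(fit$variance_components$variance)))
    hc_stop("non-finite variance component", "habclim_numerical_error")
  beta <- fit$beta
  s2f <- pop_var(drop(design$X %*% beta))
  blocks <- fit$design_info$blocks
  comp <- numeric(0)
  types <- character(0)
  for (k in seq_along(blocks)) {
    info <- blocks[[k]]
    tau2 <- fit$variance_components$variance[
      fit$variance_components$component == info$name]
    mult <- switch(info$type,
                   intercept = 1,
                   slope = mean(info$covariate^2),
                   spatial = mean(rowSums(info$Zdense^2)))
    comp[info$name] <- tau2 * mult
    types[info$name] <- info$type
  }
  s2e <- fit$sigma2
  total <- s2f + sum(comp) + s2e
  slope_sum <- sum(comp[types == "slope"])
  int_sum <- sum(comp[types == "intercept"])
  sp_sum <- sum(comp[types == "spatial"])
  out <- list(
    model_id = fit$design_info$model_id,
    trait = fit$design_info$trait,
    sigma2_fixed = s2f,
    components = comp,
    component_types = types,
    sigma2_residual = s2e,
    total = total,
    r2_marginal = s2f / total,
    r2_conditional = (s2f + sum(comp)) / total,
    r2_climate = (s2f + slope_sum + if (spatial_in_climate) sp_sum else 0) / total,
    r2_habitat = int_sum / total,
    r2_spatial = sp_sum / total
  )
  class(out) <- "variance_decomposition"
  out
}

#' Flatten a variance decomposition into a one-row table
#'
#' @param vd a `variance_decomposition` from [r2_partition()].
#' @return one-row data.frame suitable for [write_results()].
#' @export
decomposition_row <- function(vd) {
  data.frame(model_id = vd$model_id %||% NA, trait = vd$trait %||% NA,
             sigma2_fixed = vd$sigma2_fixed,
             sigma2_intercept = sum(vd$components[vd$component_types == "intercept"]),
             sigma2_slopes = sum(vd$components[vd$component_types == "slope"]),
             sigma2_spatial = sum(vd$components[vd$component_types == "spatial"]),
             sigma2_residual = vd$sigma2_residual,
             r2_marginal = vd$r2_marginal, r2_conditional = vd$r2_conditional,
             r2_climate = vd$r2_climate, r2_habitat = vd$r2_habitat,
             r2_spatial = vd$r2_spatial, stringsAsFactors = FALSE)
}
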