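# Variance-component linear mixed models by profiled REML.
#
# The model hierarchy is y = X beta + sum_k Z_k b_k + e with independent
# Gaussian blocks b_k ~ N(0, tau_k^2 I) -- habitat random intercepts,
# habitat-specific random climate-PC slopes, and an optional low-rank
# spherical spatial smooth whose penalized coefficients form one more block
# after a Cholesky reparameterisation -- and e_i ~ N(0, sigma^2 / w_i) with
# optional observation weights w. REML is profiled over beta and sigma^2 and
# maximised over the log variance ratios log(tau_k^2 / sigma^2) with analytic
# gradients, a projected BFGS with a backtracking (Armijo) line search, and a
# final Newton polish.

#' Assemble the design for one trait and one model of the hierarchy
#'
#' Model 1: fixed climate-PC effects only (no random blocks; intended to be
#' fitted on a balanced subsample, see [balanced_subsample()]). Model 2: plus
#' a random intercept for the broad (level-1) habitats. Models 3/4/5: a
#' random intercept plus four random climate-PC slope blocks for the level-1,
#' level-2 or level-3 habitats respectively. All models can carry a low-rank
#' spline-on-the-sphere smooth and per-plot observation weights (the
#' trait-coverage sensitivity analysis). Only complete cases are kept; the
#' dropped-row count is recorded.
#'
#' @param cwm CWM table (needs `log_cwm_<trait>`; `coverage_<trait>` when
#'   `options$weights` is TRUE).
#' @param trait_name one of [trait_names()].
#' @param scores climate score table from [project_climate()] (or the
#'   generator's stored scores).
#' @param habitats habitat assignment table.
#' @param meta plot metadata (needed when `options$spatial` is TRUE).
#' @param model_id integer in 1..5.
#' @param options list: `spatial` (default FALSE), `k` (basis dimension,
#'   default 100), `spatial_range_km` (kernel range; default median knot
#'   spacing), `weights` (default FALSE), `seed` (knot selection, default 1).
#' @return an object of class `model_design`.
#' @export
build_design <- function(cwm, trait_name, scores, habitats, meta = NULL,
                         model_id = 1, options = list()) {
  opt <- utils::modifyList(list(spatial = FALSE, k = 100,
                                spatial_range_km = NULL, weights = FALSE,
                                seed = 1L), options)
  if (!model_id %in% 1:5)
    hc_stop("model_id must be in 1..5", "habclim_validation_error")
  ycol <- paste0("log_cwm_", trait_name)
  if (!ycol %in% names(cwm))
    hc_stop(sprintf("trait column '%s' absent from CWM table", ycol),
            "habclim_validation_error")

  level <- c(NA, 1L, 1L, 2L, 3L)[model_id]
  df <- merge(cwm[, c("plot_id", ycol,
                      intersect(paste0("coverage_", trait_name), names(cwm)))],
              scores, by = "plot_id")
  if (!is.na(level))
    df <- merge(df, habitats[, c("plot_id", paste0("level", level))],
                by = "plot_id")
  if (opt$spatial || !is.null(meta))
    df <- merge(df, meta[, c("plot_id", "latitude", "longitude")],
                by = "plot_id")
  n_in <- nrow(df)
  pc_cols <- paste0("pc", 1:4)
  need <- c(ycol, pc_cols)
  if (!is.na(level)) need <- c(need, paste0("level", level))
  if (opt$spatial) need <- c(need, "latitude", "longitude")
  if (opt$weights) {
    wcol <- paste0("coverage_", trait_name)
    if (!wcol %in% names(df))
      hc_stop("weights requested but coverage column absent",
              "habclim_validation_error")
    need <- c(need, wcol)
  }
  cc <- stats::complete.cases(df[, need])
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  if (n == 0) hc_stop("no complete cases", "habclim_validation_error")

  X <- cbind(`(Intercept)` = 1, as.matrix(df[, pc_cols]))
  blocks <- list()
  if (model_id >= 2) {
    gl <- factor(df[[paste0("level", level)]])
    blocks[[length(blocks) + 1]] <- list(
      name = sprintf("intercept_level%d", level), type = "intercept",
      level = level, groups = gl, covariate = rep(1, n))
    if (model_id >= 3) {
      for (j in 1:4) {
        blocks[[length(blocks) + 1]] <- list(
          name = sprintf("slope_pc%d_level%d", j, level), type = "slope",
          level = level, groups = gl, covariate = df[[pc_cols[j]]], pc = j)
      }
    }
  }
  spatial_basis <- NULL
  if (opt$spatial) {
    sub_meta <- data.frame(plot_id = df$plot_id, latitude = df$latitude,
                           longitude = df$longitude, stringsAsFactors = FALSE)
    spatial_basis <- spherical_smooth_basis(sub_meta, k = opt$k,
                                            seed = opt$seed,
                                            range_km = opt$spatial_range_km)
  }
  w <- if (opt$weights) df[[paste0("coverage_", trait_name)]] else NULL
  if (!is.null(w) && any(w <= 0))
    hc_stop("observation weights must be positive", "habclim_validation_error")

  structure(list(
    y = df[[ycol]], X = X, blocks = blocks, spatial_basis = spatial_basis,
    weights = w, model_id = model_id, trait = trait_name,
    plot_id = df$plot_id, level = level, n = n, n_dropped = n_in - n
  ), class = "model_design")
}

#' Low-rank spherical spatial smooth basis
#'
#' Knots are chosen by a seeded farthest-point (space-filling) design over
#' the distinct observed locations using great-circle distance; the basis is
#' the exponential kernel `exp(-d / range)` of great-circle distance to the
#' knots, and the penalty is the same kernel evaluated among the knots (plus
#' a small ridge), so the smooth enters REML as one penalized component with
#' a single variance parameter.
#'
#' @param meta plot metadata with `latitude` and `longitude`.
#' @param k basis dimension (>= 3, <= number of distinct locations).
#' @param seed seed for the knot-selection start.
#' @param range_km kernel range in km; default is the median pairwise knot
#'   distance.
#' @return object of class `spatial_basis`: `knots` (data.frame), `basis`
#'   (plots x k), `penalty` (k x k PSD), `k`, `range_km`.
#' @export
spherical_smooth_basis <- function(meta, k = 100, seed = 1L, range_km = NULL) {
  if (k < 3) hc_stop("k must be >= 3", "habclim_validation_error")
  k <- as.integer(k)
  loc <- unique(meta[, c("latitude", "longitude")])
  if (k > nrow(loc))
    hc_stop(sprintf("k = %d exceeds the %d distinct locations", k, nrow(loc)),
            "habclim_validation_error")
  start <- with_seed(derive_seed(seed, "knots"), sample.int(nrow(loc), 1L))
  sel <- integer(k)
  sel[1] <- start
  mind <- gc_dist_km(loc$latitude, loc$longitude,
                     loc$latitude[start], loc$longitude[start])
  if (k > 1) for (i in 2:k) {
    sel[i] <- which.max(mind)
    mind <- pmin(mind, gc_dist_km(loc$latitude, loc$longitude,
                                  loc$latitude[sel[i]], loc$longitude[sel[i]]))
  }
  knots <- loc[sel, , drop = FALSE]
  rownames(knots) <- NULL
  Dkk <- gc_dist_matrix(knots$latitude, knots$longitude,
                        knots$latitude, knots$longitude)
  if (is.null(range_km)) range_km <- stats::median(Dkk[upper.tri(Dkk)])
  K <- exp(-Dkk / range_km)
  diag(K) <- diag(K) + 1e-8
  B <- exp(-gc_dist_matrix(meta$latitude, meta$longitude,
                           knots$latitude, knots$longitude) / range_km)
  structure(list(knots = knots, basis = B, penalty = K, k = k,
                 range_km = range_km), class = "spatial_basis")
}

# Build the combined sparse random-effect matrix and the block index map.
# The spatial block is reparameterised with the Cholesky factor of its
# penalty so its coefficients are i.i.d. like every other block.
assemble_random <- function(design) {
  blocks <- design$blocks
  Zs <- list()
  info <- list()
  for (b in blocks) {
    gl <- droplevels(b$groups)
    qb <- nlevels(gl)
    Zs[[length(Zs) + 1]] <- Matrix::sparseMatrix(
      i = seq_along(gl), j = as.integer(gl), x = b$covariate,
      dims = c(design$n, qb))
    info[[length(info) + 1]] <- list(name = b$name, type = b$type,
                                     level = b$level, q = qb,
                                     labels = levels(gl),
                                     n_group = as.integer(table(gl)),
                                     covariate = b$covariate)
  }
  if (!is.null(design$spatial_basis)) {
    sb <- design$spatial_basis
    R <- chol(sb$penalty)
    Zsp <- t(backsolve(R, t(sb$basis), transpose = TRUE))  # B %*% R^{-1}
    Zs[[length(Zs) + 1]] <- Matrix::Matrix(Zsp, sparse = TRUE)
    info[[length(info) + 1]] <- list(name = "spatial", type = "spatial",
                                     level = NA_integer_, q = as.integer(sb$k),
                                     labels = paste0("knot", seq_len(sb$k)),
                                     n_group = rep(NA_integer_, sb$k),
                                     covariate = NULL, Zdense = Zsp)
  }
  if (length(Zs) == 0) return(NULL)
  Z <- do.call(cbind, Zs)
  qk <- vapply(info, function(b) as.integer(b$q), 0L)
  ends <- cumsum(qk)
  starts <- ends - qk + 1L
  idx <- lapply(seq_along(qk), function(i) starts[i]:ends[i])
  list(Z = Z, info = info, idx = idx, qk = qk)
}

#' Fit the variance-component mixed model by restricted maximum likelihood
#'
#' @param design a `model_design` from [build_design()], or any list with the
#'   same fields.
#' @param options list: `grad_tol` (projected-gradient tolerance on the
#'   profiled REML criterion, default 1e-6), `rel_tol` (relative
#'   log-likelihood change, default 1e-8), `max_iter` (default 200),
#'   `lambda_floor`/`lambda_cap` (box for the variance ratios, defaults
#'   1e-8 and 1e8).
#' @return object of class `fitted_model`: `beta` (with `se_beta` and
#'   `cov_beta`), `variance_components` (data.frame with one row per random
#'   block, the spatial smooth and the residual), `blups` (per block and
#'   group: deviation estimate, conditional SE, group size), `sigma2`,
#'   `loglik_reml`, and a `convergence` record (iterations, projected
#'   gradient norm, the monotone trace of accepted criterion values).
#' @export
fit_mixed_reml <- function(design, options = list()) {
  opt <- utils::modifyList(list(grad_tol = 1e-6, rel_tol = 1e-8,
                                max_iter = 200L, lambda_floor = 1e-8,
                                lambda_cap = 1e8), options)
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  if (n <= p) hc_stop("n must exceed the number of fixed effects",
                      "habclim_validation_error")
  w <- design$weights %||% rep(1, n)
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < p)
    hc_stop("singular fixed-effect design", "habclim_numerical_error")

  ra <- assemble_random(design)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  ytWy <- sum(w * y * y)
  vary <- pop_var(y)
  var_floor <- 1e-10 * vary

  if (is.null(ra)) {
    # weighted least squares: no random blocks
    beta <- drop(solve(XtWX, XtWy))
    r <- y - drop(X %*% beta)
    sigma2 <- sum(w * r^2) / (n - p)
    cov_beta <- sigma2 * solve(XtWX)
    loglik <- -0.5 * ((n - p) * log(2 * pi * sigma2) + sum(w * r^2) / sigma2 +
                        determinant(XtWX / sigma2, logarithm = TRUE)$modulus -
                        sum(log(w)))
    vc <- data.frame(component = "residual", type = "residual",
                     level = NA_integer_, variance = sigma2,
                     stringsAsFactors = FALSE)
    return(structure(list(
      beta = setNames(beta, colnames(X)),
      se_beta = setNames(sqrt(diag(cov_beta)), colnames(X)),
      cov_beta = cov_beta, variance_components = vc, blups = NULL,
      sigma2 = sigma2, loglik_reml = as.numeric(loglik),
      convergence = list(iterations = 0L, grad_norm = 0,
                         trace = numeric(0), converged = TRUE),
      design_info = list(n = n, p = p, blocks = list(), model_id = design$model_id,
                         trait = design$trait, weighted = !is.null(design$weights)),
      joint = NULL
    ), class = "fitted_model"))
  }

  Z <- ra$Z
  K <- length(ra$idx)
  q <- ncol(Z)
  S <- as.matrix(Matrix::crossprod(Z, w * Z))
  ZtWX <- as.matrix(Matrix::crossprod(Z, w * X))
  ZtWy <- as.numeric(Matrix::crossprod(Z, w * y))
  col_block <- rep(seq_len(K), ra$qk)

  # profiled REML criterion and analytic gradient in theta = log lambda
  eval_f <- function(theta, want_grad = TRUE) {
    lam <- exp(theta)
    lam_col <- lam[col_block]
    M <- S
    diag(M) <- diag(M) + 1 / lam_col
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(list(f = Inf))
    Minv <- function(A) backsolve(R, backsolve(R, A, transpose = TRUE))
    MiZtWX <- Minv(ZtWX)
    MiZtWy <- drop(Minv(ZtWy))
    XtHinvX <- XtWX - crossprod(ZtWX, MiZtWX)
    XtHinvy <- drop(XtWy - crossprod(ZtWX, MiZtWy))
    ytHinvy <- ytWy - sum(ZtWy * MiZtWy)
    Rx <- tryCatch(chol(XtHinvX), error = function(e) NULL)
    if (is.null(Rx)) return(list(f = Inf))
    beta <- drop(backsolve(Rx, backsolve(Rx, XtHinvy, transpose = TRUE)))
    rPr <- ytHinvy - sum(beta * XtHinvy)
    if (rPr <= 0) return(list(f = Inf))
    logdetH <- 2 * sum(log(diag(R))) + sum(theta[col_block]) - sum(log(w))
    logdetX <- 2 * sum(log(diag(Rx)))
    f <- (n - p) * log(rPr) + logdetH + logdetX
    out <- list(f = f, beta = beta, rPr = rPr, R = R, Rx = Rx,
                XtHinvX = XtHinvX)
    if (want_grad) {
      Fm <- Minv(S)
      dSF <- rowSums(S * t(Fm))            # diag(S %*% M^{-1} %*% S)
      trH <- as.numeric(tapply(diag(S) - dSF, col_block, sum))
      A <- t(ZtWX) - crossprod(MiZtWX, S)  # X' H^{-1} Z  (p x q)
      Gq <- backsolve(Rx, A, transpose = TRUE)
      qf <- as.numeric(tapply(colSums(Gq^2), col_block, sum))
      v <- ZtWy - ZtWX %*% beta
      u <- drop(v - S %*% Minv(v))         # Z' P y
      usq <- as.numeric(tapply(u^2, col_block, sum))
      dlam <- -(n - p) * usq / rPr + trH - qf
      out$grad <- dlam * lam
    }
    out
  }

  lb <- rep(log(opt$lambda_floor), K)
  ub <- rep(log(opt$lambda_cap), K)
  theta <- pmin(ub, pmax(lb, rep(log(0.1), K)))
  st <- eval_f(theta)
  if (!is.finite(st$f)) {
    theta <- pmin(ub, pmax(lb, rep(0, K)))
    st <- eval_f(theta)
  }
  if (!is.finite(st$f))
    hc_stop("REML criterion not finite at the starting values",
            "habclim_numerical_error")
  f <- st$f
  g <- st$grad
  Hinv <- diag(K)
  trace <- f
  converged <- FALSE
  iter <- 0L
  pg_norm <- function(theta, g) {
    pg <- g
    pg[theta <= lb + 1e-12 & g > 0] <- 0
    pg[theta >= ub - 1e-12 & g < 0] <- 0
    max(abs(pg))
  }

  while (iter < opt$max_iter) {
    iter <- iter + 1L
    if (pg_norm(theta, g) < opt$grad_tol) { converged <- TRUE; break }
    d <- -drop(Hinv %*% g)
    free <- !((theta <= lb + 1e-12 & g > 0) | (theta >= ub - 1e-12 & g < 0))
    d[!free] <- 0
    if (sum(d * g) > -1e-14) { d <- -g; d[!free] <- 0; Hinv <- diag(K) }
    alpha <- 1
    accepted <- FALSE
    repeat {
      theta_new <- pmin(ub, pmax(lb, theta + alpha * d))
      step <- theta_new - theta
      if (max(abs(step)) < 1e-14) break
      cand <- eval_f(theta_new)
      if (is.finite(cand$f) && cand$f <= f + 1e-4 * sum(g * step)) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
      if (alpha < 1e-13) break
    }
    if (!accepted) break  # line search exhausted; hand over to Newton polish
    s_vec <- theta_new - theta
    y_vec <- cand$grad - g
    sy <- sum(s_vec * y_vec)
    if (sy > 1e-12) {
      rho <- 1 / sy
      V <- diag(K) - rho * outer(s_vec, y_vec)
      Hinv <- V %*% Hinv %*% t(V) + rho * outer(s_vec, s_vec)
    }
    theta <- theta_new
    f <- cand$f
    g <- cand$grad
    st <- cand
    trace <- c(trace, f)
  }

  # Damped-Newton polish on the free coordinates with a finite-difference
  # Hessian of the analytic gradient; tightens the optimum past the BFGS
  # line-search resolution (Levenberg-Marquardt damping on non-descent steps)
  for (np in seq_len(25L)) {
    free <- which(!((theta <= lb + 1e-12 & g > 0) |
                      (theta >= ub - 1e-12 & g < 0)))
    if (length(free) == 0 || max(abs(g[free])) < 1e-9) break
    h <- 1e-5
    Hm <- matrix(0, length(free), length(free))
    for (jj in seq_along(free)) {
      tp <- theta; tp[free[jj]] <- tp[free[jj]] + h
      gp <- eval_f(tp)$grad
      Hm[, jj] <- (gp[free] - g[free]) / h
    }
    Hm <- (Hm + t(Hm)) / 2
    mu <- 0
    improved <- FALSE
    for (damp in seq_len(10L)) {
      step <- tryCatch(solve(Hm + diag(mu + 1e-12, nrow(Hm)), -g[free]),
                       error = function(e) NULL)
      if (!is.null(step)) {
        if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
        theta_new <- theta
        theta_new[free] <- theta[free] + step
        theta_new <- pmin(ub, pmax(lb, theta_new))
        cand <- eval_f(theta_new)
        if (is.finite(cand$f) && cand$f <= f + 1e-13) {
          theta <- theta_new; f <- cand$f; g <- cand$grad; st <- cand
          trace <- c(trace, f)
          improved <- TRUE
          break
        }
      }
      mu <- if (mu == 0) max(abs(diag(Hm))) * 1e-4 else mu * 10
    }
    if (!improved) break
  }
  converged <- converged || pg_norm(theta, g) < max(opt$grad_tol, 1e-4)

  if (!converged && pg_norm(theta, g) > 1e-2)
    hc_stop(sprintf(
      "REML did not converge in %d iterations (projected gradient %.2e)",
      iter, pg_norm(theta, g)), "habclim_numerical_error",
      data = list(trace = trace))

  lam <- exp(theta)
  sigma2 <- st$rPr / (n - p)
  beta <- st$beta
  cov_beta <- sigma2 * chol2inv(st$Rx)
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  tau2 <- pmax(lam * sigma2, var_floor)
  tau2[lam <= opt$lambda_floor * (1 + 1e-6)] <- var_floor

  # Henderson joint system for BLUPs, conditional SEs and the joint
  # fixed-effect/BLUP covariance
  lam_col <- lam[col_block]
  M <- S
  diag(M) <- diag(M) + 1 / lam_col
  C <- rbind(cbind(XtWX, t(ZtWX)), cbind(ZtWX, M))
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) solve(C))
  v <- ZtWy - drop(ZtWX %*% beta)
  bhat <- drop(backsolve(st$R, backsolve(st$R, v, transpose = TRUE)))
  cond_var <- sigma2 * diag(Cinv)[(p + 1):(p + q)]

  blups <- do.call(rbind, lapply(seq_len(K), function(k) {
    ii <- ra$idx[[k]]
    data.frame(block = ra$info[[k]]$name, type = ra$info[[k]]$type,
               level = ra$info[[k]]$level, group = ra$info[[k]]$labels,
               estimate = bhat[ii], cond_se = sqrt(pmax(cond_var[ii], 0)),
               n_group = ra$info[[k]]$n_group, stringsAsFactors = FALSE)
  }))
  rownames(blups) <- NULL

  vc <- data.frame(
    component = c(vapply(ra$info, `[[`, "", "name"), "residual"),
    type = c(vapply(ra$info, `[[`, "", "type"), "residual"),
    level = c(vapply(ra$info, function(b) as.integer(b$level %||% NA), 0L),
              NA_integer_),
    variance = c(tau2, sigma2),
    stringsAsFactors = FALSE)

  loglik <- -0.5 * (f - (n - p) * log(n - p) + (n - p) * (1 + log(2 * pi)))

  structure(list(
    beta = setNames(beta, colnames(X)),
    se_beta = setNames(sqrt(diag(cov_beta)), colnames(X)),
    cov_beta = cov_beta,
    variance_components = vc,
    blups = blups,
    sigma2 = sigma2,
    lambda = setNames(lam, vapply(ra$info, `[[`, "", "name")),
    loglik_reml = loglik,
    convergence = list(iterations = iter, grad_norm = pg_norm(theta, g),
                       trace = trace, converged = TRUE),
    design_info = list(n = n, p = p, model_id = design$model_id,
                       trait = design$trait,
                       weighted = !is.null(design$weights),
                       blocks = ra$info, idx = ra$idx),
    joint = list(Cinv = Cinv, p = p, q = q, col_block = col_block)
  ), class = "fitted_model")
}

#' @method print fitted_model
#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("REML mixed model (model %s, trait %s): n = %d\n",
              x$design_info$model_id %||% "?", x$design_info$trait %||% "?",
              x$design_info$n))
  cat("fixed effects:\n")
  print(round(cbind(estimate = x$beta, se = x$se_beta), 4))
  cat("variance components:\n")
  print(x$variance_components, row.names = FALSE)
  cat(sprintf("REML log-likelihood: %.3f (%d iterations)\n",
              x$loglik_reml, x$convergence$iterations))
  invisible(x)
}

#' Balanced subsample across the habitats of one level
#'
#' Draws the minimum group size from every habitat at the given level,
#' uniformly without replacement and seeded, so each broad habitat
#' contributes the same number of plots (the across-habitat fixed-effects
#' model is fitted on such a subsample).
#'
#' @param habitats habitat assignment table.
#' @param level habitat level (1, 2 or 3).
#' @param seed integer seed.
#' @return character vector of retained plot ids.
#' @export
balanced_subsample <- function(habitats, level = 1, seed = 1L) {
  col <- paste0("level", level)
  lab <- habitats[[col]]
  if (any(is.na(lab)))
    hc_stop("habitat labels missing at the requested level",
            "habclim_validation_error")
  counts <- table(lab)
  if (any(counts == 0) || length(counts) == 0)
    hc_stop("empty habitat group", "habclim_validation_error")
  n_min <- min(counts)
  with_seed(derive_seed(seed, "balanced_subsample"), {
    ids <- unlist(lapply(split(habitats$plot_id, lab), function(v) {
      if (length(v) == n_min) v else sample(v, n_min)
    }), use.names = FALSE)
    habitats$plot_id[habitats$plot_id %in% ids]
  })
}
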