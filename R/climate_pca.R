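# Principal component analysis of the 19 bioclimatic variables.
#
# Correlation-matrix PCA (z-scored variables), since the bioclim set mixes
# incommensurate units (degrees C, mm, dimensionless indices). Column signs
# are fixed so each loading column's largest-magnitude entry is positive,
# giving gradients a stable orientation across runs.

#' Fit a PCA model to a climate table
#'
#' @param climate validated climate table (complete cases only; plots flagged
#'   with missing climate must be filtered upstream).
#' @param n_components number of components to retain for scores (default 4).
#' @return an object of class `pca_model`: per-variable `center` and `scale`,
#'   full orthonormal `loadings` (variables x components),
#'   `explained_variance` fractions over all components, and `n_components`.
#' @export
fit_climate_pca <- function(climate, n_components = 4) {
  vars <- paste0("bio", 1:19)
  vars <- intersect(vars, names(climate))
  x <- as.matrix(climate[, vars])
  if (anyNA(x))
    hc_stop("climate table has missing values; filter flagged plots upstream",
            "habclim_validation_error")
  if (nrow(x) < n_components + 1)
    hc_stop("need at least n_components + 1 complete-case plots",
            "habclim_validation_error")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    hc_stop(sprintf("zero-variance climate variable(s): %s",
                    paste(vars[sds == 0], collapse = ", ")),
            "habclim_validation_error")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  # sign convention: largest-|.| entry of each column positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  ev <- pc$sdev^2
  structure(list(
    variables = vars,
    center = setNames(pc$center, vars),
    scale = setNames(pc$scale, vars),
    loadings = load,
    eigenvalues = ev,
    explained_variance = ev / sum(ev),
    n_components = n_components
  ), class = "pca_model")
}

#' @method print pca_model
#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d variables, %d retained components\n",
              length(x$variables), x$n_components))
  ev <- x$explained_variance[seq_len(x$n_components)]
  cat(sprintf("explained variance (retained): %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * ev), collapse = ", "),
              100 * sum(ev)))
  invisible(x)
}

#' Project plots onto the retained principal components
#'
#' Scores are z-scored values times the loadings; projecting the training set
#' reproduces a per-component score variance equal to the eigenvalue.
#'
#' @param climate climate table with the same variable set the model was
#'   fitted on.
#' @param model a `pca_model` from [fit_climate_pca()].
#' @return data.frame: `plot_id` and one `pc<k>` column per retained
#'   component.
#' @export
project_climate <- function(climate, model) {
  miss <- setdiff(model$variables, names(climate))
  if (length(miss) > 0)
    hc_stop(sprintf("climate table lacks variable(s) the PCA was fitted on: %s",
                    paste(miss, collapse = ", ")), "habclim_validation_error")
  x <- as.matrix(climate[, model$variables])
  if (anyNA(x))
    hc_stop("cannot project plots with missing climate values",
            "habclim_validation_error")
  z <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  k <- model$n_components
  scores <- z %*% model$loadings[, seq_len(k), drop = FALSE]
  out <- data.frame(plot_id = climate$plot_id, stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("pc", j)]] <- scores[, j]
  out
}
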