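#' @importFrom stats coef cor dist optim prcomp quantile rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' One master seed drives a whole run; per-stage seeds are derived
#' deterministically by hashing the stage name, so stages can be re-run in
#' isolation without seed bookkeeping by the user.
#'
#' @param seed master seed (single integer).
#' @param stage character stage name, e.g. `"climate"` or `"residual"`.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of mean radius 6371 km, vectorised
#' over pairs of coordinate sets.
#'
#' @param lat1,lon1 first set of coordinates, decimal degrees.
#' @param lat2,lon2 second set of coordinates, decimal degrees.
#' @return distances in km, recycled to common length.
#' @export
gc_dist_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * r * asin(sqrt(a))
}

# Dense matrix of great-circle distances between two coordinate tables (km).
gc_dist_matrix <- function(lat1, lon1, lat2, lon2) {
  n1 <- length(lat1)
  n2 <- length(lat2)
  out <- matrix(0, n1, n2)
  for (j in seq_len(n2)) {
    out[, j] <- gc_dist_km(lat1, lon1, lat2[j], lon2[j])
  }
  out
}

# Population variance (denominator n) of a numeric vector.
pop_var <- function(x) mean((x - mean(x))^2)

# with_seed: evaluate expr under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# consistent abort helper carrying a class for callers that distinguish
# validation from numerical failure.
hc_stop <- function(msg, class = "habclim_error", data = NULL) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}
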