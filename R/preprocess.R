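# Plot exclusion rules, most-recent-census deduplication and 0.01-degree
# spatial stratification, with an auditable filter report.

#' Default plot-exclusion rule configuration
#'
#' Six rules, applied sequentially in this order: plots with only
#' presence/absence abundances; plots without coordinates; plots inside an
#' excluded region (off by default; a bounding-box hook standing in for
#' region lists such as Greenland); plots south of 34 degrees N or north of
#' 82 degrees N (strict inequalities, so the boundary values are retained);
#' plots whose trait coverage is below 0.80 (coverage exactly 0.80 is
#' retained); plots with missing climate values.
#'
#' @param lat_min,lat_max latitude band limits in degrees.
#' @param min_coverage minimum trait-coverage fraction.
#' @param exclude_region `NULL` (off) or a list with `lat` and `lon`
#'   length-2 numeric ranges defining a closed bounding box to drop.
#' @return a named list consumed by [apply_filters()].
#' @export
default_filter_rules <- function(lat_min = 34, lat_max = 82, min_coverage = 0.80,
                                 exclude_region = NULL) {
  list(lat_min = lat_min, lat_max = lat_max, min_coverage = min_coverage,
       exclude_region = exclude_region)
}

.filter_rule_names <- c("presence_absence", "missing_coordinates",
                        "excluded_region", "latitude_band",
                        "trait_coverage", "missing_climate")

#' Apply the plot exclusion rules
#'
#' @param veg vegetation table (validated).
#' @param meta plot metadata (validated).
#' @param climate climate table (validated; carries a `climate_complete` flag).
#' @param cwm_coverage data.frame with `plot_id` and `coverage` (the per-plot
#'   trait-coverage fraction from the CWM stage, minimum across traits by
#'   default).
#' @param rules rule configuration from [default_filter_rules()]. Unknown
#'   entries are an error.
#' @return list with `plot_ids` (retained, in metadata order) and `report`
#'   (data.frame: rule, removed, remaining).
#' @export
apply_filters <- function(veg, meta, climate, cwm_coverage,
                          rules = default_filter_rules()) {
  known <- names(default_filter_rules())
  unknown <- setdiff(names(rules), known)
  if (length(unknown) > 0)
    hc_stop(sprintf("unknown filter rule option(s): %s",
                    paste(unknown, collapse = ", ")), "habclim_validation_error")
  rules <- utils::modifyList(default_filter_rules(), rules)

  veg_plots <- unique(veg$plot_id)
  orphan <- setdiff(veg_plots, meta$plot_id)
  if (length(orphan) > 0)
    hc_stop(sprintf("plot(s) present in vegetation but absent from metadata: %s",
                    paste(utils::head(orphan, 5), collapse = ", ")),
            "habclim_validation_error")

  keep <- meta
  cov_map <- setNames(cwm_coverage$coverage, cwm_coverage$plot_id)
  clim_ok <- setNames(climate$climate_complete, climate$plot_id)

  removed <- integer(0)
  remaining <- integer(0)
  applied <- character(0)

  drop_rule <- function(name, drop_idx) {
    applied <<- c(applied, name)
    removed <<- c(removed, sum(drop_idx))
    keep <<- keep[!drop_idx, , drop = FALSE]
    remaining <<- c(remaining, nrow(keep))
  }

  drop_rule("presence_absence", keep$abundance_type == "presence_absence")
  drop_rule("missing_coordinates", is.na(keep$latitude) | is.na(keep$longitude))

  if (is.null(rules$exclude_region)) {
    drop_rule("excluded_region", rep(FALSE, nrow(keep)))
  } else {
    box <- rules$exclude_region
    inside <- keep$latitude >= min(box$lat) & keep$latitude <= max(box$lat) &
      keep$longitude >= min(box$lon) & keep$longitude <= max(box$lon)
    drop_rule("excluded_region", inside)
  }

  drop_rule("latitude_band",
            keep$latitude < rules$lat_min | keep$latitude > rules$lat_max)

  cov <- cov_map[keep$plot_id]
  drop_rule("trait_coverage", is.na(cov) | cov < rules$min_coverage)

  ok <- clim_ok[keep$plot_id]
  drop_rule("missing_climate", is.na(ok) | !ok)

  report <- data.frame(rule = applied, removed = removed, remaining = remaining,
                       stringsAsFactors = FALSE)
  list(plot_ids = keep$plot_id, report = report)
}

#' Most-recent-census deduplication and one-plot-per-grid-cell stratification
#'
#' Among plots sharing identical coordinates, only the most recent survey
#' year survives (ties, and missing years, broken by a seeded uniform draw);
#' the survivors are then binned into a `floor(lat / cell)` by
#' `floor(lon / cell)` grid (half-open cells, lower-left inclusive) and one
#' plot per non-empty cell is retained by a seeded uniform draw.
#'
#' @param meta plot metadata (coordinates required for all rows).
#' @param cell_deg grid-cell size in degrees (default 0.01).
#' @param seed integer seed making the draws reproducible.
#' @return character vector of retained plot ids (in metadata order).
#' @export
stratify_spatial <- function(meta, cell_deg = 0.01, seed = 1L) {
  if (cell_deg <= 0)
    hc_stop("cell_deg must be > 0", "habclim_validation_error")
  if (any(is.na(meta$latitude) | is.na(meta$longitude)))
    hc_stop("stratify_spatial requires complete coordinates",
            "habclim_validation_error")
  n <- nrow(meta)
  if (n == 0) return(character(0))

  keep_flag <- with_seed(derive_seed(seed, "stratify"), {
    u <- runif(n)
    loc_key <- paste(meta$latitude, meta$longitude, sep = "\r")
    yr <- ifelse(is.na(meta$survey_year), -Inf, meta$survey_year)
    # rank within identical locations: max year wins, ties by u
    ord <- order(loc_key, -yr, u)
    first_of_loc <- !duplicated(loc_key[ord])
    recent <- logical(n)
    recent[ord] <- first_of_loc

    cell_key <- paste(floor(meta$latitude / cell_deg),
                      floor(meta$longitude / cell_deg), sep = "\r")
    u2 <- runif(n)
    cand <- which(recent)
    ord2 <- cand[order(cell_key[cand], u2[cand])]
    chosen <- ord2[!duplicated(cell_key[ord2])]
    out <- logical(n)
    out[chosen] <- TRUE
    out
  })
  meta$plot_id[keep_flag]
}

#' Metric size of a latitude/longitude grid cell
#'
#' Spherical-Earth arc lengths of a `cell_deg` step at a given latitude:
#' north-south extent `cell_deg * (pi/180) * R` and east-west extent
#' `ns * cos(latitude)`, with R = 6371 km (mean Earth radius). A 0.01-degree
#' cell at 51.5 degrees N is approximately 1.11 x 0.69 km.
#'
#' @param latitude latitude in decimal degrees, `abs(latitude) < 90`.
#' @param cell_deg cell size in degrees.
#' @return named numeric vector `c(north_south_km, east_west_km)`.
#' @export
grid_cell_km <- function(latitude, cell_deg = 0.01) {
  stopifnot(abs(latitude) < 90)
  r <- 6371
  ns <- cell_deg * (pi / 180) * r
  ew <- ns * cos(latitude * pi / 180)
  c(north_south_km = ns, east_west_km = ew)
}
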