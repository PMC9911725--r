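# Trait assignment with species -> genus fallback, community-weighted means,
# coverage fractions and log transformation.

#' Assign trait values to species with genus fallback
#'
#' Each species gets its species-level trait means when present in the trait
#' table; otherwise the genus-level means for its genus token; otherwise all
#' four traits are missing. Provenance records which route was used.
#'
#' @param species_list data.frame with columns `species` and `genus` (one row
#'   per distinct species), or a character vector of species names from which
#'   the genus is taken as the first whitespace-separated token.
#' @param trait_table validated trait table (see [read_table()]).
#' @return data.frame: species, genus, provenance
#'   (`"species"`/`"genus"`/`"none"`), and the four trait columns.
#' @export
assign_traits <- function(species_list, trait_table) {
  if (is.character(species_list)) {
    species_list <- data.frame(
      species = species_list,
      genus = vapply(strsplit(species_list, "\\s+"), `[`, "", 1L),
      stringsAsFactors = FALSE
    )
  }
  species_list <- unique(species_list[, c("species", "genus")])
  vals <- as.matrix(trait_table[, trait_names()])
  if (any(!is.na(vals) & vals <= 0))
    hc_stop("trait table contains non-positive trait values",
            "habclim_validation_error")

  sp_tab <- trait_table[trait_table$taxon_rank == "species", , drop = FALSE]
  gn_tab <- trait_table[trait_table$taxon_rank == "genus", , drop = FALSE]
  sp_idx <- match(species_list$species, sp_tab$taxon)
  gn_idx <- match(species_list$genus, gn_tab$taxon)

  out <- species_list
  out$provenance <- ifelse(!is.na(sp_idx), "species",
                           ifelse(!is.na(gn_idx), "genus", "none"))
  for (tr in trait_names()) {
    v <- rep(NA_real_, nrow(out))
    v[!is.na(sp_idx)] <- sp_tab[[tr]][sp_idx[!is.na(sp_idx)]]
    use_gn <- is.na(sp_idx) & !is.na(gn_idx)
    v[use_gn] <- gn_tab[[tr]][gn_idx[use_gn]]
    out[[tr]] <- v
  }
  # a species whose matched row has all traits missing is effectively 'none'
  all_missing <- rowSums(!is.na(as.matrix(out[, trait_names()]))) == 0
  out$provenance[all_missing] <- "none"
  rownames(out) <- NULL
  out
}

#' Community-weighted trait means per plot
#'
#' For each plot and trait, the cover-weighted arithmetic mean over the
#' species that carry a value for that trait (weights renormalised over
#' trait-bearing species), the coverage fraction (summed cover of
#' trait-bearing species over total plant cover), the natural-log CWM, and
#' the plot's total summed cover. Plots whose trait-bearing cover is zero
#' get a missing CWM for that trait and coverage 0.
#'
#' @param veg validated vegetation table.
#' @param assignment trait assignment from [assign_traits()].
#' @return data.frame with one row per plot: `plot_id`, `total_cover`, then
#'   per trait `cwm_<t>`, `log_cwm_<t>`, `coverage_<t>`, and `coverage_min`
#'   (the minimum across the four traits, used by the coverage filter).
#' @export
compute_cwm <- function(veg, assignment) {
  if (nrow(veg) == 0)
    hc_stop("empty vegetation table", "habclim_validation_error")
  idx <- match(veg$species, assignment$species)
  if (anyNA(idx))
    hc_stop("species in vegetation table missing from trait assignment",
            "habclim_validation_error")

  plot_ids <- unique(veg$plot_id)
  f <- factor(veg$plot_id, levels = plot_ids)
  total <- as.numeric(tapply(veg$cover, f, sum))
  out <- data.frame(plot_id = plot_ids, total_cover = total,
                    stringsAsFactors = FALSE)
  for (tr in trait_names()) {
    x <- assignment[[tr]][idx]
    has <- !is.na(x)
    wsum <- as.numeric(tapply(veg$cover * has, f, sum))
    xsum <- as.numeric(tapply(ifelse(has, veg$cover * x, 0), f, sum))
    cwm <- ifelse(wsum > 0, xsum / wsum, NA_real_)
    out[[paste0("cwm_", tr)]] <- cwm
    out[[paste0("log_cwm_", tr)]] <- ifelse(is.na(cwm), NA_real_, log(cwm))
    out[[paste0("coverage_", tr)]] <- wsum / total
  }
  out$coverage_min <- do.call(pmin, out[paste0("coverage_", trait_names())])
  out
}

#' Per-plot coverage table for the trait-coverage filter
#'
#' @param cwm a CWM table from [compute_cwm()].
#' @param mode `"min"` (default; the single per-plot criterion, minimum
#'   coverage across the four traits) or one trait name for per-trait mode.
#' @return data.frame `plot_id`, `coverage`.
#' @export
cwm_coverage <- function(cwm, mode = "min") {
  col <- if (identical(mode, "min")) "coverage_min" else {
    if (!mode %in% trait_names())
      hc_stop("coverage mode must be 'min' or a trait name",
              "habclim_validation_error")
    paste0("coverage_", mode)
  }
  data.frame(plot_id = cwm$plot_id, coverage = cwm[[col]],
             stringsAsFactors = FALSE)
}
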