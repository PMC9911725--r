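# Exclusion rules, stratification and grid-cell geometry.

# Seven plots: one violating each of the six rules plus one clean plot.
make_filter_fixture <- function() {
  meta <- data.frame(
    plot_id = paste0("f", 1:7),
    latitude = c(50, NA, 75, 20, 50, 50, 50),
    longitude = c(10, 10, -45, 10, 10, 10, 10),
    survey_year = 2000,
    abundance_type = c("presence_absence", rep("cover", 6)),
    stringsAsFactors = FALSE
  )
  veg <- data.frame(plot_id = meta$plot_id, species = "Alpha alta", cover = 90,
                    stringsAsFactors = FALSE)
  climate <- data.frame(plot_id = meta$plot_id, stringsAsFactors = FALSE)
  for (j in 1:19) climate[[paste0("bio", j)]] <- j
  climate$bio5[6] <- NA
  coverage <- data.frame(plot_id = meta$plot_id,
                         coverage = c(1, 1, 1, 1, 0.5, 1, 1),
                         stringsAsFactors = FALSE)
  list(meta = validate_table(meta, "plot_metadata"),
       veg = validate_table(veg, "vegetation"),
       climate = validate_table(climate, "climate"),
       coverage = coverage)
}

test_that("each exclusion rule removes exactly its violator; one clean plot survives", {
  fx <- make_filter_fixture()
  rules <- default_filter_rules(
    exclude_region = list(lat = c(59, 84), lon = c(-74, -10)))
  out <- apply_filters(fx$veg, fx$meta, fx$climate, fx$coverage, rules)
  expect_equal(out$plot_ids, "f7")
  expect_equal(out$report$removed, rep(1L, 6))
  expect_equal(out$report$rule,
               c("presence_absence", "missing_coordinates", "excluded_region",
                 "latitude_band", "trait_coverage", "missing_climate"))
  # removals sum to input minus output
  expect_equal(sum(out$report$removed), nrow(fx$meta) - length(out$plot_ids))
  # remaining counts non-increasing
  expect_true(all(diff(out$report$remaining) <= 0))
})

test_that("latitude and coverage boundaries use strict inequalities", {
  meta <- data.frame(plot_id = c("a", "b", "c", "d"),
                     latitude = c(33.99, 34.00, 82.00, 82.01),
                     longitude = 10, survey_year = 2000,
                     abundance_type = "cover", stringsAsFactors = FALSE)
  veg <- data.frame(plot_id = meta$plot_id, species = "X y", cover = 50,
                    stringsAsFactors = FALSE)
  climate <- data.frame(plot_id = meta$plot_id, stringsAsFactors = FALSE)
  for (j in 1:19) climate[[paste0("bio", j)]] <- 1
  cov <- data.frame(plot_id = meta$plot_id, coverage = c(1, 1, 0.80, 0.799))
  out <- apply_filters(validate_table(veg, "vegetation"),
                       validate_table(meta, "plot_metadata"),
                       validate_table(climate, "climate"), cov)
  # 33.99 out (lat), 82.01 would be out by lat but falls first to coverage? no:
  # order is latitude then coverage; d violates both, removed at latitude
  expect_setequal(out$plot_ids, c("b", "c"))
  lat_removed <- out$report$removed[out$report$rule == "latitude_band"]
  cov_removed <- out$report$removed[out$report$rule == "trait_coverage"]
  expect_equal(lat_removed, 2L)  # 33.99 and 82.01
  expect_equal(cov_removed, 0L)  # 0.80 retained; 0.799 plot already gone
})

test_that("coverage 0.80 is retained and 0.799 removed", {
  meta <- data.frame(plot_id = c("a", "b"), latitude = 50, longitude = 10,
                     survey_year = 2000, abundance_type = "cover",
                     stringsAsFactors = FALSE)
  veg <- data.frame(plot_id = meta$plot_id, species = "X y", cover = 50,
                    stringsAsFactors = FALSE)
  climate <- data.frame(plot_id = meta$plot_id, stringsAsFactors = FALSE)
  for (j in 1:19) climate[[paste0("bio", j)]] <- 1
  cov <- data.frame(plot_id = meta$plot_id, coverage = c(0.80, 0.799))
  out <- apply_filters(validate_table(veg, "vegetation"),
                       validate_table(meta, "plot_metadata"),
                       validate_table(climate, "climate"), cov)
  expect_equal(out$plot_ids, "a")
})

test_that("unknown rule names and orphan plots are validation errors", {
  fx <- make_filter_fixture()
  expect_error(apply_filters(fx$veg, fx$meta, fx$climate, fx$coverage,
                             list(bogus = 1)), "unknown filter rule")
  veg2 <- rbind(fx$veg, data.frame(plot_id = "ghost", species = "A b",
                                   cover = 10, genus = "A"))
  expect_error(apply_filters(veg2, fx$meta, fx$climate, fx$coverage),
               "absent from metadata")
})

test_that("filtering is idempotent", {
  fx <- make_filter_fixture()
  out1 <- apply_filters(fx$veg, fx$meta, fx$climate, fx$coverage)
  meta2 <- fx$meta[fx$meta$plot_id %in% out1$plot_ids, ]
  out2 <- apply_filters(fx$veg[fx$veg$plot_id %in% out1$plot_ids, ],
                        meta2, fx$climate, fx$coverage)
  expect_equal(out2$plot_ids, out1$plot_ids)
  expect_equal(sum(out2$report$removed), 0L)
})

test_that("stratification keeps one plot per cell and the most recent census per location", {
  meta <- data.frame(
    plot_id = paste0("s", 1:6),
    latitude = c(50.001, 50.002, 50.001, 51.5, 52.3, 50.001),
    longitude = c(10.001, 10.002, 10.001, 11.0, 12.0, 10.001),
    survey_year = c(1990, 2000, 2010, 2000, NA, 2010),
    abundance_type = "cover", stringsAsFactors = FALSE)
  meta <- validate_table(meta, "plot_metadata")
  kept <- stratify_spatial(meta, cell_deg = 0.01, seed = 5)
  # s1/s3/s6 share a location; s2 shares their cell: exactly one survives
  expect_equal(sum(kept %in% c("s1", "s2", "s3", "s6")), 1L)
  # the location survivor must have the max year (2010: s3 or s6), so s1 never wins
  expect_false("s1" %in% kept)
  expect_true(all(c("s4", "s5") %in% kept))
  # re-binning: at most one plot per cell
  sub <- meta[meta$plot_id %in% kept, ]
  cells <- paste(floor(sub$latitude / 0.01), floor(sub$longitude / 0.01))
  expect_false(anyDuplicated(cells) > 0)
  # determinism
  expect_identical(kept, stratify_spatial(meta, cell_deg = 0.01, seed = 5))
})

test_that("plots in distinct cells pass stratification unchanged", {
  meta <- data.frame(plot_id = letters[1:4], latitude = c(50, 51, 52, 53),
                     longitude = 10, survey_year = 2000,
                     abundance_type = "cover", stringsAsFactors = FALSE)
  meta <- validate_table(meta, "plot_metadata")
  expect_setequal(stratify_spatial(meta, seed = 1), meta$plot_id)
  expect_error(stratify_spatial(meta, cell_deg = 0), "cell_deg")
})

test_that("grid-cell geometry matches the spherical-Earth arc lengths", {
  # 0.01 degrees in Central Europe: approximately 1.11 x 0.69 km
  expect_equal(unname(round(grid_cell_km(51.5, 0.01), 2)), c(1.11, 0.69))
  eq <- grid_cell_km(0, 0.01)
  expect_equal(eq[["north_south_km"]], eq[["east_west_km"]])
  at60 <- grid_cell_km(60, 0.01)
  expect_equal(at60[["east_west_km"]], at60[["north_south_km"]] / 2,
               tolerance = 1e-12)
})
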