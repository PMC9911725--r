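# Tabular I/O for the five input schemas and all result tables.
#
# All files are delimited text (comma by default, tab accepted), UTF-8,
# "." as decimal separator -- the conventions of ecology data archives.

.schemas <- list(
  vegetation = list(
    required = c("plot_id", "species", "cover"),
    optional = c("genus"),
    numeric  = c("cover")
  ),
  plot_metadata = list(
    required = c("plot_id", "latitude", "longitude"),
    optional = c("survey_year", "abundance_type"),
    numeric  = c("latitude", "longitude", "survey_year")
  ),
  traits = list(
    required = c("taxon", "taxon_rank", "plant_height", "sla", "seed_mass", "srl"),
    optional = character(),
    numeric  = c("plant_height", "sla", "seed_mass", "srl")
  ),
  habitat = list(
    required = c("plot_id", "level1"),
    optional = c("level2", "level3"),
    numeric  = character()
  ),
  climate = list(
    required = c("plot_id", paste0("bio", 1:19)),
    optional = character(),
    numeric  = paste0("bio", 1:19)
  )
)

#' Names of the tabular schemas understood by [read_table()]
#' @return character vector of schema names.
#' @export
schema_names <- function() names(.schemas)

#' Trait column names used throughout the package
#' @return character vector of the four trait identifiers.
#' @export
trait_names <- function() c("plant_height", "sla", "seed_mass", "srl")

# Detect field separator from the header line: tab if present, else comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read and validate one of the five input tables
#'
#' Reads a delimited text file (comma default, tab auto-detected), checks the
#' header against the named schema (order-insensitive), coerces and validates
#' the numeric columns, and applies schema-specific normalisation:
#' vegetation records duplicated on (plot_id, species) are merged by summing
#' covers (capped at 100, the subspecies-merging convention); a missing
#' `genus` column is derived from the first whitespace-separated name token.
#' A validation report is attached as attribute `"report"`.
#'
#' @param path file path.
#' @param schema_name one of [schema_names()].
#' @return a validated `data.frame` with attribute `"report"`.
#' @export
read_table <- function(path, schema_name) {
  if (!schema_name %in% names(.schemas))
    hc_stop(sprintf("unknown schema '%s'", schema_name), "habclim_validation_error")
  if (!file.exists(path))
    hc_stop(sprintf("file not found: %s", path), "habclim_io_error")
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"", comment.char = "",
                          colClasses = NA)
  validate_table(df, schema_name, source = path)
}

#' Validate an in-memory table against a schema
#'
#' The same checks as [read_table()] applied to a `data.frame` already in
#' memory; used by the synthetic generator and the pipeline so every module
#' consumes only validated tables.
#'
#' @param df a data.frame.
#' @param schema_name one of [schema_names()].
#' @param source label used in error messages.
#' @return validated data.frame with attribute `"report"`.
#' @export
validate_table <- function(df, schema_name, source = "<memory>") {
  sch <- .schemas[[schema_name]]
  if (is.null(sch))
    hc_stop(sprintf("unknown schema '%s'", schema_name), "habclim_validation_error")
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols) > 0)
    hc_stop(sprintf("%s: schema '%s' is missing required column(s): %s",
                    source, schema_name, paste(missing_cols, collapse = ", ")),
            "habclim_validation_error")
  keep <- intersect(c(sch$required, sch$optional), names(df))
  df <- df[, keep, drop = FALSE]
  notes <- character()

  for (col in intersect(sch$numeric, names(df))) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(vals <- as.numeric(df[[col]]))
      bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "" &
                     toupper(df[[col]]) != "NA")
      if (length(bad) > 0)
        hc_stop(sprintf("%s: column '%s' has unparseable numeric value at data row(s) %s",
                        source, col, paste(utils::head(bad, 5), collapse = ", ")),
                "habclim_validation_error")
      df[[col]] <- vals
    }
  }

  if (schema_name == "vegetation") {
    if (any(is.na(df$cover) | df$cover <= 0))
      hc_stop(sprintf("%s: vegetation covers must be > 0", source),
              "habclim_validation_error")
    if (!"genus" %in% names(df)) {
      df$genus <- vapply(strsplit(df$species, "\\s+"), `[`, "", 1L)
      notes <- c(notes, "genus derived from first species-name token")
    }
    # subspecies/variety merging convention: species key is the first two
    # name tokens; duplicate (plot, species) covers are summed, capped at 100
    df$species <- vapply(strsplit(df$species, "\\s+"), function(tok)
      paste(tok[seq_len(min(2L, length(tok)))], collapse = " "), "")
    key <- paste(df$plot_id, df$species, sep = "\r")
    if (anyDuplicated(key)) {
      n_before <- nrow(df)
      agg <- tapply(df$cover, key, sum)
      first <- df[!duplicated(key), , drop = FALSE]
      first$cover <- pmin(100, as.numeric(agg[paste(first$plot_id, first$species,
                                                    sep = "\r")]))
      df <- first
      notes <- c(notes, sprintf("merged %d duplicate (plot, species) records",
                                n_before - nrow(df)))
    }
    df$cover <- pmin(100, df$cover)
  }

  if (schema_name == "plot_metadata") {
    if (anyDuplicated(df$plot_id))
      hc_stop(sprintf("%s: duplicate plot_id in plot metadata", source),
              "habclim_validation_error")
    ok_lon <- is.na(df$longitude) | (df$longitude >= -180 & df$longitude <= 180)
    ok_lat <- is.na(df$latitude) | (df$latitude >= -90 & df$latitude <= 90)
    if (!all(ok_lon) || !all(ok_lat))
      hc_stop(sprintf("%s: coordinates outside valid ranges", source),
              "habclim_validation_error")
    if (!"survey_year" %in% names(df)) df$survey_year <- NA_real_
    if (!"abundance_type" %in% names(df)) df$abundance_type <- "cover"
    bad_type <- !df$abundance_type %in% c("cover", "presence_absence")
    if (any(bad_type))
      hc_stop(sprintf("%s: abundance_type must be 'cover' or 'presence_absence'",
                      source), "habclim_validation_error")
  }

  if (schema_name == "traits") {
    vals <- as.matrix(df[, trait_names()])
    if (any(!is.na(vals) & vals <= 0))
      hc_stop(sprintf("%s: trait values must be positive", source),
              "habclim_validation_error")
    if (!all(df$taxon_rank %in% c("species", "genus")))
      hc_stop(sprintf("%s: taxon_rank must be 'species' or 'genus'", source),
              "habclim_validation_error")
    if (anyDuplicated(paste(df$taxon, df$taxon_rank)))
      hc_stop(sprintf("%s: duplicate (taxon, rank) rows", source),
              "habclim_validation_error")
  }

  if (schema_name == "habitat") {
    if (anyDuplicated(df$plot_id))
      hc_stop(sprintf("%s: duplicate plot_id in habitat assignment", source),
              "habclim_validation_error")
    if (!"level2" %in% names(df)) df$level2 <- NA_character_
    if (!"level3" %in% names(df)) df$level3 <- NA_character_
  }

  if (schema_name == "climate") {
    vars <- paste0("bio", 1:19)
    flagged <- rowSums(is.na(df[, vars])) > 0
    df$climate_complete <- !flagged
    if (any(flagged))
      notes <- c(notes, sprintf("%d plot(s) flagged with missing climate values",
                                sum(flagged)))
  }

  attr(df, "report") <- list(schema = schema_name, source = source,
                             n_rows = nrow(df), notes = notes)
  rownames(df) <- NULL
  df
}

#' Write a delimited result or input table
#'
#' @param df data.frame to write.
#' @param path output path; directories are created as needed.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, sep = ",") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a set of result tables plus a JSON run manifest
#'
#' Each element of `results` that is a data.frame is written as
#' `<name>.csv` under `out_dir`; a `manifest.json` records the
#' configuration, seed, package version, timestamp and per-table row counts.
#'
#' @param results named list of data.frames (may be empty data.frames).
#' @param out_dir output directory.
#' @param config optional configuration list echoed into the manifest.
#' @param seed optional master seed echoed into the manifest.
#' @return the manifest list, invisibly; files on disk as a side effect.
#' @export
write_results <- function(results, out_dir, config = NULL, seed = NULL) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    hc_stop(sprintf("cannot create output directory '%s'", out_dir),
            "habclim_io_error")
  tables <- Filter(is.data.frame, results)
  counts <- list()
  for (nm in names(tables)) {
    write_table(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    counts[[nm]] <- nrow(tables[[nm]])
  }
  manifest <- list(
    package = "habclim",
    version = as.character(utils::packageVersion("habclim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
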