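# Serialisation: tidy power-table CSV/JSON and the run manifest.
#
# CSV numeric fields are written with 17 significant digits ("%.17g"), the
# shortest format guaranteeing a lossless double round trip.

POWER_TABLE_COLS <- c("scenario_id", "sex_effect", "treatment_effect",
                      "interaction_effect", "pipeline", "term", "power",
                      "n_sig", "n_sim", "ci_low", "ci_high")

#' Write and read power tables
#'
#' `write_power_table()` serialises a [run_scenario_sweep()] result to a tidy
#' CSV or JSON file; `read_power_table()` restores it. The numeric columns
#' round-trip losslessly at full double precision.
#'
#' @param table A `power_table` data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the file
#'   extension.
#' @return `write_power_table()` returns `path` invisibly;
#'   `read_power_table()` returns a `power_table` data frame.
#' @export
write_power_table <- function(table, path, format = NULL) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(POWER_TABLE_COLS, names(table))
  if (length(missing_cols))
    stop_sabv("sabv_error_schema", "power table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  format <- format %||% guess_format(path)
  df <- as.data.frame(table)[, POWER_TABLE_COLS]
  if (format == "csv") {
    out <- df
    for (nm in names(out))
      if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    # digits = I(17): 17 significant digits, lossless for doubles
    jsonlite::write_json(df, path, dataframe = "rows", digits = I(17),
                         auto_unbox = TRUE)
  } else {
    stop_sabv("sabv_error_schema", "unknown format '%s' (use csv or json)", format)
  }
  invisible(path)
}

#' @rdname write_power_table
#' @export
read_power_table <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  if (!file.exists(path)) stop_sabv("sabv_error_parse", "file not found: %s", path)
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    stop_sabv("sabv_error_schema", "unknown format '%s' (use csv or json)", format)
  }
  missing_cols <- setdiff(POWER_TABLE_COLS, names(df))
  if (length(missing_cols))
    stop_sabv("sabv_error_parse", "power table file lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  for (nm in c("sex_effect", "treatment_effect", "interaction_effect",
               "power", "ci_low", "ci_high"))
    df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("n_sig", "n_sim")) df[[nm]] <- as.integer(df[[nm]])
  class(df) <- c("power_table", "data.frame")
  df
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("csv", "json")) ext
  else stop_sabv("sabv_error_schema",
                 "cannot guess format from extension '%s'; pass format=", ext)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest
#'
#' A manifest records everything needed to re-run a sweep bit-identically:
#' the full configuration, the scenario list, the master seed, the package
#' version, the output paths and a timestamp. `write_manifest()` stores it as
#' JSON; `read_manifest()` restores it; `rerun_manifest()` re-executes the
#' sweeps it describes.
#'
#' @param config A [simulation_config()].
#' @param scenario_ids Character vector of scenario identifiers.
#' @param outputs Named character vector/list of files the run wrote.
#' @return `run_manifest()` returns a `run_manifest` list.
#' @export
run_manifest <- function(config, scenario_ids, outputs = character(0)) {
  stopifnot(inherits(config, "simulation_config"))
  bad <- setdiff(scenario_ids, SCENARIO_IDS)
  if (length(bad))
    stop_sabv("sabv_error_scenario", "unknown scenario id(s): %s",
              paste(bad, collapse = ", "))
  structure(
    list(package = "sabvpower",
         version = as.character(utils::packageVersion("sabvpower")),
         created = format(Sys.time(), tz = "UTC", usetz = TRUE),
         config = unclass(config),
         scenario_ids = scenario_ids,
         seed = config$seed,
         outputs = as.list(outputs)),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path File path of the manifest JSON.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_sabv("sabv_error_parse", "file not found: %s", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$config <- do.call(simulation_config, m$config[c("n_per_cell", "baseline_mean",
                                                    "noise_variance", "alpha",
                                                    "n_sim", "seed")])
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @export
rerun_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  tables <- lapply(manifest$scenario_ids, run_scenario_sweep, config = manifest$config)
  names(tables) <- manifest$scenario_ids
  tables
}
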