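## CSV readers/writers for the canonical long-format schemas. Long format is
## canonical everywhere; the wide "report-shaped" tables are render-only and
## never read back, so no parser ever consumes a rounded number.

read_schema <- function(path, cols, validator, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  df <- readr::read_csv(path, col_types = cols, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p1 <- probs[1, ]
    abort(paste0("Malformed ", what, " in '", path, "' (row ", p1$row,
                 ", col ", p1$col, "): expected ", p1$expected,
                 ", got ", p1$actual))
  }
  validator(df, what = paste0(what, " ('", path, "')"))
  df
}

#' Read and write the pipeline's CSV schemas
#'
#' Each reader validates column names, types and value constraints and fails
#' with a message naming the file and offending cell; each writer emits plain
#' long-format CSV that its reader round-trips exactly.
#'
#' Schemas: census `region,category,count`; transitions
#' `from_category,to_category,probability,standard_error`; construction
#' `region,category,year,count`; population `region,year,population`;
#' norms `staff_type,category,headcount`; roster `staff_type,employed`;
#' panel `facility_id,year,category`.
#'
#' @param path File path.
#' @return The validated tibble.
#' @export
#' @rdname csv_io
read_census_csv <- function(path) {
  df <- read_schema(path, readr::cols(region = "c", category = "c",
                                      count = "d"),
                    validate_census, "facility census")
  mutate(df, category = as_category(.data$category))
}

#' @export
#' @rdname csv_io
read_transitions_csv <- function(path) {
  df <- read_schema(path, readr::cols(from_category = "c", to_category = "c",
                                      probability = "d",
                                      standard_error = "d"),
                    validate_transitions, "transition table")
  structure(df, class = c("hwf_transitions", class(df)))
}

#' @export
#' @rdname csv_io
read_construction_csv <- function(path) {
  df <- read_schema(path, readr::cols(region = "c", category = "c",
                                      year = "i", count = "d"),
                    validate_construction, "construction schedule")
  mutate(df, category = as_category(.data$category))
}

#' @export
#' @rdname csv_io
read_population_csv <- function(path) {
  read_schema(path, readr::cols(region = "c", year = "i", population = "d"),
              validate_population, "population series")
}

#' @export
#' @rdname csv_io
read_norms_csv <- function(path) {
  df <- read_schema(path, readr::cols(staff_type = "c", category = "c",
                                      headcount = "d"),
                    validate_norms, "staffing norms")
  mutate(df, category = as_category(.data$category))
}

#' @export
#' @rdname csv_io
read_roster_csv <- function(path) {
  read_schema(path, readr::cols(staff_type = "c", employed = "d"),
              validate_roster, "employment roster")
}

#' @export
#' @rdname csv_io
read_panel_csv <- function(path) {
  read_schema(path, readr::cols(facility_id = "c", year = "i",
                                category = "c"),
              validate_panel, "facility panel")
}

#' @param x Tibble conforming to the schema.
#' @export
#' @rdname csv_io
write_table_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Render a projection as a wide national census table
#'
#' National counts (summed over regions) per category and year, rounded half
#' up to whole facilities, with subtotal rows for primary (district) hospitals
#' (PHA-PHD) and for all facilities.
#'
#' @param projection A `hwf_projection` or census tibble with `region`,
#'   `category`, `year`, `count`.
#' @return Wide tibble: one row per category plus the two subtotal rows, one
#'   column per year.
#' @export
census_wide <- function(projection) {
  require_columns(projection, c("category", "year", "count"), "census")
  nat <- projection |>
    as_tibble() |>
    mutate(category = as.character(.data$category)) |>
    group_by(.data$category, .data$year) |>
    summarise(count = sum(.data$count), .groups = "drop")
  ph <- c("PHA", "PHB", "PHC", "PHD")
  subtot <- dplyr::bind_rows(
    nat |> filter(.data$category %in% ph) |>
      group_by(.data$year) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(category = "Primary hospitals (PHA-PHD)"),
    nat |> group_by(.data$year) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(category = "All facilities"))
  order_levels <- c(facility_categories(), "Primary hospitals (PHA-PHD)",
                    "All facilities")
  dplyr::bind_rows(nat, subtot) |>
    mutate(count = round_half_up(.data$count),
           category = factor(.data$category, levels = order_levels)) |>
    arrange(.data$category) |>
    tidyr::pivot_wider(names_from = "year", values_from = "count")
}

#' Render flows as a wide year-by-pair table
#'
#' Annual flows at one decimal place, one row per year plus a final `Total`
#' row with the per-pair horizon totals rounded to whole facilities.
#'
#' @param flows Output of [transition_flows()].
#' @return Wide tibble: column `year` (character; last row `"Total"`), one
#'   column per adjacent pair.
#' @export
flows_wide <- function(flows) {
  require_columns(flows, c("year", "from_category", "to_category", "flow"),
                  "flows")
  fl <- flows |>
    as_tibble() |>
    mutate(pair = paste(.data$from_category, "to", .data$to_category),
           pair = factor(.data$pair, levels = unique(.data$pair)))
  wide <- fl |>
    mutate(flow = round_half_up(.data$flow, 1)) |>
    select("year", "pair", "flow") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "flow") |>
    mutate(year = as.character(.data$year))
  totals <- fl |>
    group_by(.data$pair) |>
    summarise(flow = round_half_up(sum(.data$flow)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "flow") |>
    mutate(year = "Total")
  dplyr::bind_rows(wide, totals)
}

#' Render national requirements as a wide staff-type-by-year table
#'
#' @param requirements A `hwf_requirements` tibble (summed to national
#'   internally); `lower`/`upper` columns, if present, are dropped here — use
#'   the long bounds output for intervals.
#' @return Wide tibble: one row per staff type plus a `Total` row, one column
#'   per year, headcounts rounded half up to integers.
#' @export
requirements_wide <- function(requirements) {
  nat <- national_requirements(requirements) |>
    select("staff_type", "year", "required")
  total <- nat |>
    group_by(.data$year) |>
    summarise(required = sum(.data$required), .groups = "drop") |>
    mutate(staff_type = "Total")
  dplyr::bind_rows(nat, total) |>
    mutate(required = round_half_up(.data$required)) |>
    tidyr::pivot_wider(names_from = "year", values_from = "required")
}

#' Run the whole forecasting pipeline from a configuration
#'
#' Orchestrates the full pipeline — project the facility census, compute
#' flows, translate to workforce requirements, attach predictive bounds, and
#' (when a roster is supplied) compute staff-availability ratios — and writes
#' the report set to an output directory. Outputs are staged in a temporary
#' directory and moved into place only on success, so a failed run never
#' leaves partial outputs behind. A `manifest.json` records the configuration,
#' the seed, the package version and MD5 hashes of all file inputs; it
#' contains no timestamps, so re-running an identical configuration yields
#' byte-identical outputs.
#'
#' @param config Named list (or path to a YAML/JSON file holding one) with
#'   elements: `census`, `transitions` (paths or tibbles; required); optional
#'   `construction`, `population`, `norms`, `roster`, `workload`; `horizon`
#'   (default 10); `baseline_year` (default 2016); `chps_divisor` (default
#'   1500); `z` (default 1.96); `seed` (optional, recorded); `out_dir`
#'   (required).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_forecast <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or a file path")
  for (req in c("census", "transitions", "out_dir")) {
    if (is.null(config[[req]])) {
      abort(paste0("Configuration error: `", req, "` is required"))
    }
  }
  horizon <- config$horizon %||% 10
  if (!is.numeric(horizon) || horizon < 1 || horizon != floor(horizon)) {
    abort("Configuration error: `horizon` must be an integer >= 1")
  }
  baseline_year <- config$baseline_year %||% 2016
  chps_divisor <- config$chps_divisor %||% 1500
  z <- config$z %||% 1.96

  load_input <- function(x, reader) {
    if (is.null(x)) NULL
    else if (is.character(x) && length(x) == 1) reader(x)
    else as_tibble(x)
  }
  paths_used <- purrr::keep(
    config[c("census", "transitions", "construction", "population",
             "norms", "roster", "workload")],
    is.character)

  census <- load_input(config$census, read_census_csv)
  transitions <- load_input(config$transitions, read_transitions_csv)
  construction <- load_input(config$construction, read_construction_csv)
  population <- load_input(config$population, read_population_csv)
  norms <- load_input(config$norms, read_norms_csv)
  roster <- load_input(config$roster, read_roster_csv)
  workload <- if (is.null(config$workload)) NULL else {
    load_input(config$workload, function(p) {
      readr::read_csv(p, col_types = readr::cols(region = "c",
                                                 category = "c",
                                                 delta = "d"),
                      progress = FALSE)
    })
  }

  proj <- project(census, transitions, construction = construction,
                  population = population, horizon = horizon,
                  baseline_year = baseline_year, chps_divisor = chps_divisor)
  flows <- transition_flows(proj)

  stage <- file.path(tempfile("hwf_stage_"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  out <- list()
  emit <- function(x, name) {
    p <- file.path(stage, name)
    write_table_csv(x, p)
    out[[name]] <<- file.path(config$out_dir, name)
  }

  emit(as_tibble(proj), "census_long.csv")
  emit(census_wide(proj), "census_wide.csv")
  emit(as_tibble(flows), "flows_long.csv")
  emit(flows_wide(flows), "flows_wide.csv")

  if (!is.null(norms)) {
    req <- staff_requirements(proj, norms, workload = workload)
    emit(as_tibble(req), "requirements_long.csv")
    emit(requirements_wide(req), "requirements_wide.csv")
    bounds <- predictive_interval(
      census, transitions, norms, construction = construction,
      population = population, workload = workload, horizon = horizon,
      baseline_year = baseline_year, chps_divisor = chps_divisor, z = z)
    emit(national_requirements(bounds), "requirements_bounds.csv")
    if (!is.null(roster)) {
      emit(staff_availability_ratio(req, roster, baseline_year), "sar.csv")
    }
  }

  manifest <- list(
    package = "hwforecast",
    version = as.character(utils::packageVersion("hwforecast")),
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    input_md5 = as.list(purrr::map_chr(paths_used, ~ unname(tools::md5sum(.x)))))
  manifest_path <- file.path(stage, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  out[["manifest.json"]] <- file.path(config$out_dir, "manifest.json")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(out)) {
    file.copy(file.path(stage, name), out[[name]], overwrite = TRUE)
  }
  invisible(out)
}
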