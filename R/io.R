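# Bundle serialization: one delimited long table per component plus a JSON
# config echo, so a scenario can be regenerated, archived, or fed back into
# the pipeline without any binary formats.

config_to_list <- function(config) {
  out <- unclass(config)
  ab <- as.data.frame(out$age_bands)
  ab$upper[is.infinite(ab$upper)] <- NA_real_ # JSON cannot carry Inf
  out$age_bands <- ab
  out$cause_profile <- as.list(out$cause_profile)
  out
}

config_from_list <- function(lst) {
  ab <- as_tibble(as.data.frame(lst$age_bands))
  ab$upper[is.na(ab$upper)] <- Inf
  do.call(scenario_config, c(
    lst[setdiff(names(lst), c("age_bands", "cause_profile"))],
    list(age_bands = ab, cause_profile = unlist(lst$cause_profile))
  ))
}

#' Write a synthetic bundle to a directory of delimited text files
#'
#' Files written: `exposure.csv` (`cell_id`, `year`, `period` = `"annual"`
#' or the month number, `pollutant`, `value`), `population.csv`,
#' `mortality.csv` (cause-specific rates with the band's residual life
#' expectancy `le` repeated per row), `erf.csv` (see [write_erf_table()])
#' and `config.json` (config echo plus the generating `truth` record).
#'
#' @param bundle a [make_scenario()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- bundle$exposure$annual
  exposure_long <- bind_rows(
    tibble(cell_id = ann$cell_id, year = ann$year, period = "annual",
           pollutant = "pm25", value = ann$pm25_annual),
    tibble(cell_id = bundle$exposure$monthly$cell_id,
           year = bundle$exposure$monthly$year,
           period = as.character(bundle$exposure$monthly$month),
           pollutant = "o3", value = bundle$exposure$monthly$o3)
  )
  readr::write_csv(exposure_long, file.path(dir, "exposure.csv"))
  readr::write_csv(bundle$population, file.path(dir, "population.csv"))
  mort <- bundle$mortality$rates |>
    left_join(bundle$mortality$life_table, by = "age_band")
  readr::write_csv(mort, file.path(dir, "mortality.csv"))
  write_erf_table(bundle$erf_set, file.path(dir, "erf.csv"))
  jsonlite::write_json(
    list(config = config_to_list(bundle$config), truth = bundle$truth),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' Read and validate a bundle directory
#'
#' Reads the files written by [write_bundle()], recomputes derived fields
#' (the ozone peak-season metric), and runs full cross-file validation:
#' schema, non-negativity, complete subgroup cross-products, and cell-key
#' alignment between exposure and population. Validation failures name the
#' offending cell, year and subgroup.
#'
#' @param dir bundle directory.
#' @return a `synthetic_bundle`.
#' @export
read_bundle <- function(dir) {
  need <- c("exposure.csv", "population.csv", "mortality.csv", "erf.csv",
            "config.json")
  missing_f <- need[!file.exists(file.path(dir, need))]
  if (length(missing_f) > 0) {
    stop_validation("bundle directory %s is missing: %s", dir,
                    paste(missing_f, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  config <- config_from_list(meta$config)

  exp_long <- readr::read_csv(file.path(dir, "exposure.csv"),
                              show_col_types = FALSE, progress = FALSE)
  ann_pm <- exp_long |>
    filter(.data$pollutant == "pm25", .data$period == "annual")
  monthly <- exp_long |>
    filter(.data$pollutant == "o3", .data$period != "annual") |>
    mutate(month = as.integer(.data$period)) |>
    select("cell_id", "year", "month", o3 = "value") |>
    arrange(.data$year, .data$cell_id, .data$month)
  per_cy <- monthly |> dplyr::count(.data$cell_id, .data$year)
  bad <- per_cy |> filter(.data$n != 12L)
  if (nrow(bad) > 0) {
    stop_validation("cell %d year %d has %d ozone months (expected 12)",
                    bad$cell_id[1], bad$year[1], bad$n[1])
  }
  o3_mat <- matrix(monthly$o3, ncol = 12L, byrow = TRUE)
  peak <- tibble(cell_id = monthly$cell_id[seq(1, nrow(monthly), by = 12L)],
                 year = monthly$year[seq(1, nrow(monthly), by = 12L)],
                 o3_peak_season = peak_season_matrix(o3_mat))
  annual <- ann_pm |>
    select("cell_id", "year", pm25_annual = "value") |>
    inner_join(peak, by = c("cell_id", "year")) |>
    arrange(.data$year, .data$cell_id)
  exposure <- structure(list(annual = annual, monthly = monthly,
                             n_truncated = c(pm25 = 0L, o3 = 0L)),
                        class = "exposure_history")

  population <- readr::read_csv(file.path(dir, "population.csv"),
                                show_col_types = FALSE, progress = FALSE)
  class(population) <- c("population_grid", class(population))

  mort <- readr::read_csv(file.path(dir, "mortality.csv"),
                          show_col_types = FALSE, progress = FALSE)
  rates <- mort |> select("sex", "age_band", "residence", "cause", "rate")
  all_cause <- rates |>
    group_by(.data$sex, .data$age_band, .data$residence) |>
    summarise(rate = sum(.data$rate), .groups = "drop")
  life_table <- mort |> dplyr::distinct(.data$age_band, .data$le)
  mortality <- structure(list(rates = rates, all_cause = all_cause,
                              life_table = life_table, le0 = config$le0),
                         class = "mortality_schedule")

  erf_set <- load_erf_table(file.path(dir, "erf.csv"))

  bundle <- structure(list(config = config, exposure = exposure,
                           population = population, mortality = mortality,
                           erf_set = erf_set, truth = meta$truth),
                      class = "synthetic_bundle")
  validate_bundle(bundle)
}

#' Validate a bundle's cross-file consistency
#'
#' @param bundle a `synthetic_bundle`.
#' @return the bundle, invisibly rethrown on success; errors name the
#'   offending rows.
#' @export
validate_bundle <- function(bundle) {
  ann <- bundle$exposure$annual
  pop <- bundle$population
  if (any(ann$pm25_annual < 0) || any(ann$o3_peak_season < 0)) {
    stop_validation("negative concentrations in exposure table")
  }
  if (any(pop$count < 0)) {
    bad <- pop[pop$count < 0, ][1, ]
    stop_validation("negative population count at cell %d year %d (%s/%s/%s)",
                    bad$cell_id, bad$year, bad$sex, bad$age_band,
                    bad$residence)
  }
  exp_keys <- unique(paste(ann$cell_id, ann$year))
  pop_keys <- unique(paste(pop$cell_id, pop$year))
  if (!setequal(exp_keys, pop_keys)) {
    off <- c(setdiff(exp_keys, pop_keys), setdiff(pop_keys, exp_keys))
    stop_validation("exposure and population cell-year keys differ (e.g. %s)",
                    off[1])
  }
  expected <- tidyr::expand_grid(
    key = unique(paste(pop$cell_id, pop$year)),
    sex = unique(pop$sex),
    age_band = unique(pop$age_band),
    residence = unique(pop$residence))
  have <- paste(pop$cell_id, pop$year, pop$sex, pop$age_band, pop$residence)
  want <- paste(expected$key, expected$sex, expected$age_band,
                expected$residence)
  gap <- setdiff(want, have)
  if (length(gap) > 0) {
    stop_validation("population table is missing stratum (cell year sex band residence): %s",
                    gap[1])
  }
  if (any(bundle$mortality$rates$rate < 0)) {
    stop_validation("negative baseline mortality rate")
  }
  invisible(bundle)
}

#' Reshape a per-cell column into the grid matrix
#'
#' Helper for mapping or exporting gridded fields: returns the values of
#' one year as a matrix in the grid's row-major (north-west origin)
#' layout.
#'
#' @param values per-cell vector ordered by `cell_id`.
#' @param config the [scenario_config()] defining the grid.
#' @return `n_rows` x `n_cols` matrix.
#' @export
field_matrix <- function(values, config) {
  matrix(values, nrow = config$n_rows, ncol = config$n_cols, byrow = TRUE)
}
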