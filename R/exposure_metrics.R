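#' Peak-season concentration from twelve monthly means
#'
#' The long-term ozone exposure metric: the maximum 6-month moving average
#' of the monthly means of the daily 8-hour average concentration. Windows
#' do not wrap across calendar years, so a year has exactly seven candidate
#' windows (Jan-Jun through Jul-Dec); the cross-year alternative is
#' discussed in the methods vignette.
#'
#' @param monthly numeric vector of exactly 12 ordered monthly means.
#' @return the peak-season concentration (same units as the input).
#' @examples
#' peak_season_concentration(1:12) # mean of Jul-Dec = 9.5
#' @export
peak_season_concentration <- function(monthly) {
  if (length(monthly) != 12L) {
    stop_validation("`monthly` must have exactly 12 values (got %d)",
                    length(monthly))
  }
  if (anyNA(monthly) || any(!is.finite(monthly))) {
    stop_validation("`monthly` contains missing or non-finite values; no imputation is performed")
  }
  if (any(monthly < 0)) {
    stop_validation("`monthly` contains negative concentrations")
  }
  max(vapply(1:7, function(k) mean(monthly[k:(k + 5L)]), numeric(1)))
}

# vectorized form: rows of `m` are 12-month series
peak_season_matrix <- function(m) {
  stopifnot(ncol(m) == 12L)
  out <- rowMeans(m[, 1:6, drop = FALSE])
  for (k in 2:7) {
    out <- pmax(out, rowMeans(m[, k:(k + 5L), drop = FALSE]))
  }
  out
}

#' Population-weighted mean
#'
#' @param values per-cell values (e.g. concentrations).
#' @param population per-cell population weights, aligned with `values`.
#' @return `sum(values * population) / sum(population)`.
#' @export
population_weighted_mean <- function(values, population) {
  check_aligned(values, population, "values", "population")
  if (any(population < 0)) stop_validation("population weights must be non-negative")
  tot <- sum(population)
  if (tot <= 0) stop_validation("total population must be positive")
  sum(values * population) / tot
}

#' Population fraction exposed above a threshold
#'
#' Share of the population living in cells with a value strictly greater
#' than `threshold`; ties at the threshold count as compliant.
#'
#' @inheritParams population_weighted_mean
#' @param threshold exposure threshold (same units as `values`).
#' @return fraction in `[0, 1]`.
#' @export
fraction_above <- function(values, population, threshold) {
  check_aligned(values, population, "values", "population")
  tot <- sum(population)
  if (tot <= 0) stop_validation("total population must be positive")
  sum(population[values > threshold]) / tot
}

#' Least-squares trend of a cell's exposure across years
#'
#' Ordinary least-squares slope of value on calendar year, the per-grid
#' trend summarized in exposure trend maps.
#'
#' @param values exposure values.
#' @param years calendar years, aligned with `values`; at least two distinct.
#' @return slope in value units per year.
#' @export
cell_trend <- function(values, years) {
  check_aligned(values, years, "values", "years")
  if (length(unique(years)) < 2L) {
    stop_validation("need at least two distinct years for a trend")
  }
  yc <- years - mean(years)
  sum(yc * (values - mean(values))) / sum(yc^2)
}

#' Directly age/sex-standardized rate
#'
#' Weights stratum-specific rates by a fixed reference population structure
#' (e.g. the first study year), removing the effect of demographic change
#' from a rate comparison.
#'
#' @param rates named or plain numeric vector of stratum rates.
#' @param weights reference-structure weights summing to 1; if both vectors
#'   are named they are matched by name.
#' @return the standardized rate.
#' @export
age_standardized_rate <- function(rates, weights) {
  if (!is.null(names(rates)) && !is.null(names(weights))) {
    if (!setequal(names(rates), names(weights))) {
      stop_validation("strata of `rates` and `weights` do not match")
    }
    weights <- weights[names(rates)]
  } else {
    check_aligned(rates, weights, "rates", "weights")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_validation("`weights` must sum to 1 (got %.12g)", sum(weights))
  }
  sum(rates * weights)
}

#' Exposure summary table for a synthetic bundle
#'
#' Population-weighted mean exposure and population fraction above a
#' pollution threshold, per year and pollutant. PM2.5 uses the annual mean
#' against the national ambient standard (35 ug/m3 by default); ozone uses
#' the peak-season metric.
#'
#' @param bundle a [make_scenario()] bundle (or list with `exposure` and
#'   `population`).
#' @param pm25_threshold,o3_threshold pollution thresholds (ug/m3).
#' @return tibble with `year`, `pollutant`, `popwt_mean`, `threshold`,
#'   `frac_above`.
#' @export
exposure_summary <- function(bundle, pm25_threshold = 35, o3_threshold = 100) {
  pop_cell <- bundle$population |>
    group_by(.data$cell_id, .data$year) |>
    summarise(pop = sum(.data$count), .groups = "drop")
  ann <- bundle$exposure$annual |>
    inner_join(pop_cell, by = c("cell_id", "year"))
  th <- c(pm25 = pm25_threshold, o3 = o3_threshold)
  out <- lapply(sort(unique(ann$year)), function(y) {
    d <- ann[ann$year == y, ]
    tibble(
      year = y,
      pollutant = c("pm25", "o3"),
      popwt_mean = c(population_weighted_mean(d$pm25_annual, d$pop),
                     population_weighted_mean(d$o3_peak_season, d$pop)),
      threshold = unname(th),
      frac_above = c(fraction_above(d$pm25_annual, d$pop, th[["pm25"]]),
                     fraction_above(d$o3_peak_season, d$pop, th[["o3"]]))
    )
  })
  bind_rows(out)
}

#' Per-cell least-squares exposure trends
#'
#' @param bundle a [make_scenario()] bundle.
#' @return tibble with `cell_id`, `pollutant`, `slope` (ug/m3 per year).
#' @export
exposure_trends <- function(bundle) {
  ann <- bundle$exposure$annual |> arrange(.data$cell_id, .data$year)
  years <- sort(unique(ann$year))
  ncell <- length(unique(ann$cell_id))
  pm <- matrix(ann$pm25_annual[order(ann$cell_id, ann$year)], ncol = length(years),
               byrow = TRUE)
  o3 <- matrix(ann$o3_peak_season[order(ann$cell_id, ann$year)], ncol = length(years),
               byrow = TRUE)
  yc <- years - mean(years)
  bind_rows(
    tibble(cell_id = sort(unique(ann$cell_id)), pollutant = "pm25",
           slope = as.vector((pm - rowMeans(pm)) %*% yc) / sum(yc^2)),
    tibble(cell_id = sort(unique(ann$cell_id)), pollutant = "o3",
           slope = as.vector((o3 - rowMeans(o3)) %*% yc) / sum(yc^2))
  )
}
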