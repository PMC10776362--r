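#' Empirical percentile interval from draw values
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), pinned here so confidence intervals are
#' bit-reproducible.
#'
#' @param values numeric draw values.
#' @param ci_level interval level in (0, 1).
#' @return `c(lower, upper)`.
#' @export
percentile_interval <- function(values, ci_level = 0.95) {
  if (ci_level <= 0 || ci_level >= 1) {
    stop_config("`ci_level` must lie strictly inside (0, 1)")
  }
  a <- (1 - ci_level) / 2
  unname(quantile(values, probs = c(a, 1 - a), type = 7, names = FALSE))
}

#' Monte Carlo interval for a metric over exposure-response draws
#'
#' Recomputes `fun(draw)` for each draw index and returns the central value
#' with empirical percentile bounds. If any draw fails the error is
#' re-raised naming the draw.
#'
#' @param fun function of one argument (the draw index) returning a scalar.
#' @param n_draws number of draws (>= 2 for a non-degenerate interval).
#' @param ci_level interval level.
#' @param central central estimate; default `fun("central")`.
#' @return object of class `interval_estimate`: list with `central`,
#'   `lower`, `upper`, `n_draws`, `ci_level`, `values`.
#' @export
monte_carlo <- function(fun, n_draws, ci_level = 0.95, central = NULL) {
  if (n_draws < 1L) stop_config("`n_draws` must be at least 1")
  values <- vapply(seq_len(n_draws), function(d) {
    tryCatch(fun(d), error = function(e) {
      stop_computation("metric failed on draw %d: %s", d, conditionMessage(e))
    })
  }, numeric(1))
  if (is.null(central)) central <- fun("central")
  bounds <- percentile_interval(values, ci_level)
  interval_estimate(central, bounds[1], bounds[2], n_draws, ci_level, values)
}

interval_estimate <- function(central, lower, upper, n_draws, ci_level,
                              values = NULL) {
  if (lower > central || central > upper) {
    warn(sprintf(
      "central estimate %.6g lies outside the %g%% interval [%.6g, %.6g]; draws may not bracket the central curve",
      central, 100 * ci_level, lower, upper))
  }
  structure(list(central = central, lower = lower, upper = upper,
                 n_draws = n_draws, ci_level = ci_level, values = values),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.6g (%g%% CI: %.6g-%.6g; %d draws)\n", x$central,
              100 * x$ci_level, x$lower, x$upper, x$n_draws))
  invisible(x)
}

#' Interval estimates for the national burden
#'
#' Convenience wrapper combining [national_burden_draws()] with the central
#' estimate of [compute_burden()] into one tidy table of empirical
#' intervals.
#'
#' @param bundle a [make_scenario()] bundle.
#' @param n_draws draws to use (default: all in the ERF set).
#' @param ci_level interval level.
#' @param pollutants subset of `c("pm25", "o3")`.
#' @return tibble with `year`, `pollutant`, `metric` (deaths/yll/lle),
#'   `central`, `lower`, `upper`, `n_draws`.
#' @export
burden_intervals <- function(bundle, n_draws = NULL, ci_level = 0.95,
                             pollutants = c("pm25", "o3")) {
  n_draws <- n_draws %||% bundle$erf_set[[1]]$n_draws
  draws_tab <- national_burden_draws(bundle, seq_len(n_draws), pollutants)
  central <- compute_burden(bundle, draw = "central",
                            pollutants = pollutants,
                            subgroup_detail = FALSE)$national
  long_d <- draws_tab |>
    tidyr::pivot_longer(c("deaths", "yll", "lle"), names_to = "metric",
                        values_to = "value")
  long_c <- central |>
    tidyr::pivot_longer(c("deaths", "yll", "lle"), names_to = "metric",
                        values_to = "central")
  long_d |>
    group_by(.data$year, .data$pollutant, .data$metric) |>
    summarise(lower = percentile_interval(.data$value, ci_level)[1],
              upper = percentile_interval(.data$value, ci_level)[2],
              .groups = "drop") |>
    inner_join(long_c |> select("year", "pollutant", "metric", "central"),
               by = c("year", "pollutant", "metric")) |>
    mutate(n_draws = n_draws) |>
    select("year", "pollutant", "metric", "central", "lower", "upper",
           "n_draws")
}
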