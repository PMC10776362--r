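#' Observed national exposure levels anchoring the default scenario
#'
#' Population-weighted national exposure levels reported for Chinese adults
#' over the two-stage clean-air-action period (2013, 2017, 2020): annual-mean
#' PM2.5 and the fraction of adults above the 35 ug/m3 national ambient
#' standard, and peak-season ozone. The default [scenario_config()] is
#' parameterized so the synthetic scenario reproduces this national
#' trajectory; the table also feeds the package's worked-arithmetic
#' consistency checks (stage-wise concentration reductions and percentage
#' declines).
#'
#' @return tibble with `year`, `pm25_popwt`, `pm25_frac_above_pct`,
#'   `o3_popwt` (concentrations in ug/m3, fractions in percent).
#' @export
caa_reference_levels <- function() {
  tibble(
    year = c(2013L, 2017L, 2020L),
    pm25_popwt = c(68.98, 47.13, 35.77),
    pm25_frac_above_pct = c(95.86, 76.77, 46.83),
    o3_popwt = c(111.4, 121.1, 114.9)
  )
}

#' Observed national burden levels anchoring the default scenario
#'
#' National attributable-burden estimates for the same setting: PM2.5 and
#' ozone attributable deaths (millions), years of life lost (millions) and
#' the PM2.5 loss of life expectancy (years per capita) in 2013, 2017 and
#' 2020, plus the stage-wise gains of life expectancy in months (PM2.5-only
#' and PM2.5+O3 combined). Used to calibrate the default exposure-response
#' magnitudes and for arithmetic consistency checks; the package does not
#' re-estimate these numbers from real data.
#'
#' @return list with tibble `by_year` and tibble `stages`.
#' @export
caa_reference_burden <- function() {
  list(
    by_year = tibble(
      year = c(2013L, 2017L, 2020L),
      pm25_deaths_million = c(1.31, 1.23, 1.06),
      pm25_yll_million = c(28.87, 26.97, 22.62),
      pm25_lle_years = c(1.86, 1.69, 1.38),
      o3_deaths_million = c(0.102, 0.124, 0.116),
      o3_yll_million = c(1.76, 2.10, 1.93)
    ),
    stages = tibble(
      stage = c("2013-2017", "2017-2020"),
      gle_pm25_months = c(2.11, 3.68),
      gle_combined_months = c(1.87, 3.94),
      gini_combined = c(0.44, 0.18)
    )
  )
}
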