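#' Adult age bands (GBD-style five-year bands from 25 to 95+)
#'
#' Builds the age-band table used throughout the package: five-year bands
#' covering adults from `from` upwards, closed below and open above, with an
#' open-ended top band. The `mid` column is the band midpoint used for
#' Gompertz mortality scaling and residual life expectancy (the open top band
#' is assigned midpoint `top_mid`).
#'
#' @param from lower age of the youngest adult band (years).
#' @param top lower age of the open-ended oldest band.
#' @param width band width in years.
#' @param top_mid nominal midpoint assigned to the open top band.
#' @return tibble with columns `age_band` (label), `lower`, `upper`, `mid`.
#' @examples
#' default_age_bands()
#' @export
default_age_bands <- function(from = 25, top = 95, width = 5, top_mid = 100) {
  lower <- seq(from, top, by = width)
  upper <- c(lower[-1], Inf)
  label <- c(sprintf("%d-%d", lower[-length(lower)], lower[-1] - 1L),
             sprintf("%d+", top))
  mid <- ifelse(is.finite(upper), (lower + upper) / 2, top_mid)
  tibble(age_band = label, lower = lower, upper = upper, mid = mid)
}

#' Default cause-of-death profile
#'
#' Fractions of all-cause adult mortality assigned to each cause. The six
#' causes with a PM2.5 exposure-response relationship (ischemic heart
#' disease, stroke, lung cancer, COPD, lower-respiratory-tract infection,
#' type-2 diabetes) follow an approximate GBD cause mix for Chinese adults;
#' COPD is additionally the ozone-linked cause. The remainder is carried as
#' `other` so that cause-specific rates sum exactly to the all-cause rate.
#'
#' @return named numeric vector of fractions summing to 1.
#' @export
default_cause_profile <- function() {
  c(ihd = 0.17, stroke = 0.20, lung_cancer = 0.06, copd = 0.09,
    lri = 0.02, t2dm = 0.02, other = 0.44)
}

#' Scenario configuration for the synthetic two-stage clean-air scenario
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' national conditions of China's staged clean-air programme 2013-2020:
#' population-weighted PM2.5 of about 69 ug/m3 falling to about 47 and then
#' 36 ug/m3 over two stages, peak-season ozone rising from about 111 to 121
#' ug/m3 and then easing to 115, an adult population of 1.09 billion with a
#' crude mortality rate of 7.6 per 1000 that is aging rapidly.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param years ordered calendar years; consecutive pairs form the stages.
#' @param pm25_baseline_mean,pm25_baseline_sd mean and spatial sd of the
#'   first-year annual PM2.5 field (ug/m3).
#' @param pm25_stage_reductions mean fractional decline of PM2.5 per stage
#'   (length `length(years) - 1`).
#' @param pm25_reduction_sd spatial sd of the cell-level reduction fraction;
#'   scalar or one value per stage (the default makes the second stage's
#'   improvement more spatially even, emulating the synergic multi-region
#'   control of the later programme).
#' @param o3_baseline_mean,o3_baseline_sd mean and spatial sd of the
#'   first-year peak-season ozone field (ug/m3).
#' @param o3_stage_deltas additive change in peak-season ozone per stage
#'   (ug/m3, sign-free: positive entries emulate the rise, negative the fall).
#' @param o3_delta_sd spatial sd of the cell-level ozone change; scalar or
#'   one value per stage.
#' @param spatial_corr_length Gaussian smoothing bandwidth (cells) giving the
#'   fields their spatial autocorrelation.
#' @param age_bands tibble as returned by [default_age_bands()].
#' @param aging_rate per-year exponential tilt of pyramid mass toward older
#'   bands (0 = static pyramid).
#' @param urban_fraction_range interval in `[0,1]` from which each cell's
#'   urban population fraction is drawn (spatially smoothly).
#' @param total_population national adult population (persons), constant
#'   across years.
#' @param pop_log_sd log-scale sd of the per-cell population density field.
#' @param sex_male_share share of males in the adult population.
#' @param crude_mortality_rate all-cause adult deaths per person-year in the
#'   first year, used to calibrate the Gompertz age schedule.
#' @param le0 life expectancy at birth (years); the free scaling constant of
#'   the loss-of-life-expectancy metric.
#' @param cause_profile named fractions of all-cause mortality per cause,
#'   summing to 1 (see [default_cause_profile()]).
#' @param n_draws default number of exposure-response draws.
#' @param erf_noise_scale log-normal sd of the draw-level perturbation of the
#'   exposure-response parameters.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   bundle.
#' @return object of class `scenario_config` (a validated list).
#' @seealso [make_scenario()]
#' @export
scenario_config <- function(n_rows = 50L,
                            n_cols = 50L,
                            years = c(2013L, 2017L, 2020L),
                            pm25_baseline_mean = 68.98,
                            pm25_baseline_sd = 20,
                            pm25_stage_reductions = c(1 - 47.13 / 68.98,
                                                      1 - 35.77 / 47.13),
                            pm25_reduction_sd = c(0.10, 0.05),
                            o3_baseline_mean = 111.4,
                            o3_baseline_sd = 15,
                            o3_stage_deltas = c(9.7, -6.2),
                            o3_delta_sd = c(6, 3),
                            spatial_corr_length = 4,
                            age_bands = default_age_bands(),
                            aging_rate = 0.015,
                            urban_fraction_range = c(0.2, 0.9),
                            total_population = 1.09e9,
                            pop_log_sd = 1,
                            sex_male_share = 0.512,
                            crude_mortality_rate = 0.0076,
                            le0 = 77.6,
                            cause_profile = default_cause_profile(),
                            n_draws = 100L,
                            erf_noise_scale = 0.1,
                            seed = 1L) {
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    years = as.integer(years),
    pm25_baseline_mean = pm25_baseline_mean,
    pm25_baseline_sd = pm25_baseline_sd,
    pm25_stage_reductions = pm25_stage_reductions,
    pm25_reduction_sd = pm25_reduction_sd,
    o3_baseline_mean = o3_baseline_mean,
    o3_baseline_sd = o3_baseline_sd,
    o3_stage_deltas = o3_stage_deltas,
    o3_delta_sd = o3_delta_sd,
    spatial_corr_length = spatial_corr_length,
    age_bands = as_tibble(age_bands),
    aging_rate = aging_rate,
    urban_fraction_range = urban_fraction_range,
    total_population = total_population,
    pop_log_sd = pop_log_sd,
    sex_male_share = sex_male_share,
    crude_mortality_rate = crude_mortality_rate,
    le0 = le0,
    cause_profile = cause_profile,
    n_draws = as.integer(n_draws),
    erf_noise_scale = erf_noise_scale,
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  if (cfg$n_rows < 1L || cfg$n_cols < 1L) {
    stop_config("grid dimensions must be positive (got %d x %d)",
                cfg$n_rows, cfg$n_cols)
  }
  if (length(cfg$years) < 2L || any(diff(cfg$years) <= 0)) {
    stop_config("`years` must be strictly increasing with at least two entries")
  }
  n_stages <- length(cfg$years) - 1L
  if (length(cfg$pm25_stage_reductions) != n_stages ||
      length(cfg$o3_stage_deltas) != n_stages) {
    stop_config("stage parameters must have length %d (one per year pair)",
                n_stages)
  }
  # per-stage heterogeneity: recycled (or truncated) to one value per stage
  for (nm in c("pm25_reduction_sd", "o3_delta_sd")) {
    v <- cfg[[nm]]
    if (length(v) < 1L || any(!is.finite(v)) || any(v < 0)) {
      stop_config("`%s` must be non-negative", nm)
    }
    cfg[[nm]] <- rep_len(v, n_stages)
  }
  for (nm in c("pm25_baseline_mean", "o3_baseline_mean", "total_population",
               "crude_mortality_rate", "le0")) {
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop_config("`%s` must be a strictly positive number", nm)
    }
  }
  for (nm in c("pm25_baseline_sd", "o3_baseline_sd", "spatial_corr_length",
               "pop_log_sd", "aging_rate", "erf_noise_scale")) {
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop_config("`%s` must be a non-negative number", nm)
    }
  }
  ufr <- cfg$urban_fraction_range
  if (length(ufr) != 2L || any(ufr < 0) || any(ufr > 1) || ufr[1] > ufr[2]) {
    stop_config("`urban_fraction_range` must be an interval within [0, 1]")
  }
  if (nrow(cfg$age_bands) == 0L) {
    stop_config("`age_bands` must contain at least one band")
  }
  if (any(diff(cfg$age_bands$lower) <= 0)) {
    stop_config("`age_bands` must be ordered by increasing lower age")
  }
  if (abs(sum(cfg$cause_profile) - 1) > 1e-9 || any(cfg$cause_profile < 0)) {
    stop_config("`cause_profile` fractions must be non-negative and sum to 1")
  }
  if (cfg$sex_male_share <= 0 || cfg$sex_male_share >= 1) {
    stop_config("`sex_male_share` must lie strictly inside (0, 1)")
  }
  if (cfg$n_draws < 1L) stop_config("`n_draws` must be at least 1")
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  grid: %d x %d cells, years %s\n", x$n_rows, x$n_cols,
              paste(x$years, collapse = ", ")))
  cat(sprintf("  PM2.5: %.2f ug/m3 baseline, stage reductions %s\n",
              x$pm25_baseline_mean,
              paste(sprintf("%.1f%%", 100 * x$pm25_stage_reductions),
                    collapse = ", ")))
  cat(sprintf("  O3 peak season: %.1f ug/m3 baseline, stage deltas %s\n",
              x$o3_baseline_mean,
              paste(sprintf("%+.1f", x$o3_stage_deltas), collapse = ", ")))
  cat(sprintf("  population: %.3g adults, %d age bands, aging rate %.3f/yr\n",
              x$total_population, nrow(x$age_bands), x$aging_rate))
  cat(sprintf("  seed: %d, draws: %d\n", x$seed, x$n_draws))
  invisible(x)
}

#' Grid cell index table
#'
#' Cell ids are row-major from the north-west corner, the raster convention
#' recorded in run manifests.
#'
#' @param config a [scenario_config()].
#' @return tibble with `cell_id`, `row`, `col`.
#' @export
grid_cells <- function(config) {
  tibble(
    cell_id = seq_len(config$n_rows * config$n_cols),
    row = rep(seq_len(config$n_rows), each = config$n_cols),
    col = rep(seq_len(config$n_cols), times = config$n_rows)
  )
}
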