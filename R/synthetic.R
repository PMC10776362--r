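# Seed-reproducible synthetic inputs emulating a two-stage clean-air
# scenario. Each generator derives its RNG stream from config$seed with a
# fixed offset so the bundle is bit-identical for identical (config, seed)
# while individual generators remain usable on their own.

SEED_EXPOSURE <- 101L
SEED_POPULATION <- 202L
SEED_ERF <- 303L

#' Seasonal profile of monthly ozone
#'
#' Sinusoid peaking in July, normalized so that its maximum 6-month moving
#' average equals 1. Multiplying the profile by a cell's peak-season level
#' therefore yields a monthly series whose peak-season metric recovers that
#' level exactly, which keeps the peak-season operator non-trivial but
#' checkable.
#'
#' @param amplitude relative strength of the seasonal cycle.
#' @return numeric vector of 12 monthly factors.
#' @export
o3_seasonal_profile <- function(amplitude = 0.45) {
  raw <- 1 + amplitude * cos(2 * pi * ((1:12) - 7) / 12)
  raw / peak_season_concentration(raw)
}

#' Generate the per-year exposure fields of a scenario
#'
#' PM2.5 annual-mean fields start from a spatially autocorrelated baseline
#' and decline stage-wise by the configured mean fractions, with smooth
#' cell-level heterogeneity in the realized reduction. Peak-season ozone
#' starts from its own autocorrelated baseline and shifts additively per
#' stage (rise then fall under the defaults); monthly ozone series are the
#' peak-season level times a summer-peaking seasonal profile. Negative
#' concentrations produced by the additive noise are truncated at zero and
#' counted.
#'
#' @param config a [scenario_config()].
#' @return object of class `exposure_history`: list with `annual`
#'   (tibble `cell_id`, `year`, `pm25_annual`, `o3_peak_season`), `monthly`
#'   (tibble `cell_id`, `year`, `month`, `o3`) and `n_truncated` (named
#'   count of zero-truncations per pollutant).
#' @export
generate_exposure_history <- function(config) {
  config <- validate_scenario_config(config)
  set.seed(config$seed + SEED_EXPOSURE)
  years <- config$years
  n_years <- length(years)
  n_cells <- config$n_rows * config$n_cols

  pm <- matrix(NA_real_, n_cells, n_years)
  pm_raw <- config$pm25_baseline_mean +
    config$pm25_baseline_sd * smooth_field_vector(config)
  n_trunc_pm <- sum(pm_raw < 0)
  pm[, 1] <- pmax(pm_raw, 0)
  for (j in seq_len(n_years - 1L)) {
    r <- config$pm25_stage_reductions[j] +
      config$pm25_reduction_sd[j] * smooth_field_vector(config)
    r <- pmin(pmax(r, 0), 1)
    pm[, j + 1L] <- pm[, j] * (1 - r)
  }

  o3 <- matrix(NA_real_, n_cells, n_years)
  o3_raw <- config$o3_baseline_mean +
    config$o3_baseline_sd * smooth_field_vector(config)
  n_trunc_o3 <- sum(o3_raw < 0)
  o3[, 1] <- pmax(o3_raw, 0)
  for (j in seq_len(n_years - 1L)) {
    nxt <- o3[, j] + config$o3_stage_deltas[j] +
      config$o3_delta_sd[j] * smooth_field_vector(config)
    n_trunc_o3 <- n_trunc_o3 + sum(nxt < 0)
    o3[, j + 1L] <- pmax(nxt, 0)
  }

  season <- o3_seasonal_profile()
  monthly <- tibble(
    cell_id = rep(rep(seq_len(n_cells), times = n_years), each = 12L),
    year = rep(rep(years, each = n_cells), each = 12L),
    month = rep(1:12, times = n_cells * n_years),
    o3 = as.vector(vapply(
      seq_len(n_years),
      function(j) t(outer(o3[, j], season)),
      matrix(0, 12L, n_cells)
    ))
  )

  # peak-season metric recomputed from the monthly series (7 windows/cell)
  o3_mat <- matrix(monthly$o3, ncol = 12L, byrow = TRUE)
  peak <- peak_season_matrix(o3_mat)
  annual <- tibble(
    cell_id = rep(seq_len(n_cells), times = n_years),
    year = rep(years, each = n_cells),
    pm25_annual = as.vector(pm),
    o3_peak_season = peak
  )

  n_truncated <- c(pm25 = n_trunc_pm, o3 = n_trunc_o3)
  if (sum(n_truncated) > 0) {
    inform(sprintf("truncated %d negative concentration values at 0",
                   sum(n_truncated)))
  }
  structure(list(annual = annual, monthly = monthly,
                 n_truncated = n_truncated),
            class = "exposure_history")
}

# shares over age bands per year: base pyramid tilted olderward by aging_rate
age_shares_by_year <- function(config) {
  mid <- config$age_bands$mid
  base <- exp(-0.045 * (mid - mid[1]))
  ref_age <- sum(mid * base) / sum(base)
  out <- lapply(config$years, function(y) {
    tilt <- exp(config$aging_rate * (y - config$years[1]) * (mid - ref_age) / 10)
    w <- base * tilt
    w / sum(w)
  })
  names(out) <- as.character(config$years)
  out
}

#' Generate the per-year population grid of a scenario
#'
#' Per-cell totals follow a smooth log-normal density field normalized so
#' the national total equals `config$total_population` every year. Subgroup
#' counts are the cell total times the product of the year's age-pyramid
#' share (tilted olderward by `aging_rate`), the sex share, and the cell's
#' urban/rural split (drawn smoothly within `urban_fraction_range`).
#'
#' @param config a [scenario_config()].
#' @return tibble of class `population_grid` with columns `cell_id`, `year`,
#'   `sex`, `age_band`, `residence`, `count`; the subgroup keys form a
#'   complete cross-product for every cell-year.
#' @export
generate_population <- function(config) {
  config <- validate_scenario_config(config)
  if (nrow(config$age_bands) == 0L) {
    stop_config("`age_bands` must not be empty")
  }
  set.seed(config$seed + SEED_POPULATION)
  n_cells <- config$n_rows * config$n_cols

  dens <- exp(config$pop_log_sd * smooth_field_vector(config))
  cell_total <- config$total_population * dens / sum(dens)
  ufr <- config$urban_fraction_range
  urban <- ufr[1] + (ufr[2] - ufr[1]) * pnorm(smooth_field_vector(config))

  shares <- age_shares_by_year(config)
  sexes <- c(male = config$sex_male_share, female = 1 - config$sex_male_share)
  bands <- config$age_bands$age_band

  per_year <- lapply(config$years, function(y) {
    sub <- tidyr::expand_grid(
      sex = names(sexes),
      age_band = bands,
      residence = c("urban", "rural")
    )
    sub$age_share <- shares[[as.character(y)]][match(sub$age_band, bands)]
    sub$sex_share <- sexes[sub$sex]
    cells <- tibble(cell_id = seq_len(n_cells), cell_total = cell_total,
                    urban_frac = urban)
    out <- tidyr::expand_grid(cells, sub)
    res_share <- ifelse(out$residence == "urban",
                        out$urban_frac, 1 - out$urban_frac)
    tibble(cell_id = out$cell_id, year = y, sex = out$sex,
           age_band = out$age_band, residence = out$residence,
           count = unname(out$cell_total * out$age_share * out$sex_share *
                            res_share))
  })
  pop <- bind_rows(per_year)
  class(pop) <- c("population_grid", class(pop))
  pop
}

#' Generate the baseline mortality schedule of a scenario
#'
#' All-cause adult mortality follows a Gompertz age schedule (rates double
#' roughly every eight years of age) with sex and residence multipliers,
#' scaled so the crude rate under the first-year population structure equals
#' `config$crude_mortality_rate`. Cause-specific rates are the all-cause
#' rate times the configured cause profile, so they sum exactly to the
#' all-cause rate. Residual life expectancy decreases smoothly with age;
#' `le0` is carried as the free scaling constant of the per-capita metrics.
#'
#' @param config a [scenario_config()].
#' @return object of class `mortality_schedule`: list with `rates` (tibble
#'   `sex`, `age_band`, `residence`, `cause`, `rate`), `all_cause` (same keys
#'   without `cause`), `life_table` (tibble `age_band`, `le`) and `le0`.
#' @export
generate_mortality <- function(config) {
  config <- validate_scenario_config(config)
  bands <- config$age_bands
  gompertz_b <- log(2) / 8
  age_factor <- exp(gompertz_b * (bands$mid - bands$mid[1]))

  sex_mult <- c(male = 1.2)
  sex_mult["female"] <- (1 - config$sex_male_share * sex_mult["male"]) /
    (1 - config$sex_male_share)
  mean_urban <- mean(config$urban_fraction_range)
  res_mult <- c(urban = 1.08)
  res_mult["rural"] <- (1 - mean_urban * res_mult["urban"]) / (1 - mean_urban)

  # calibrate the Gompertz scale against the first-year pyramid
  age_share <- age_shares_by_year(config)[[1]]
  sex_share <- c(male = config$sex_male_share,
                 female = 1 - config$sex_male_share)
  res_share <- c(urban = mean_urban, rural = 1 - mean_urban)
  strata <- tidyr::expand_grid(sex = names(sex_share),
                               age_band = bands$age_band,
                               residence = names(res_share))
  strata$share <- sex_share[strata$sex] *
    age_share[match(strata$age_band, bands$age_band)] *
    res_share[strata$residence]
  strata$shape <- age_factor[match(strata$age_band, bands$age_band)] *
    sex_mult[strata$sex] * res_mult[strata$residence]
  scale <- config$crude_mortality_rate / sum(strata$share * strata$shape)

  all_cause <- tibble(sex = strata$sex, age_band = strata$age_band,
                      residence = strata$residence,
                      rate = scale * strata$shape)
  all_cause$rate <- unname(all_cause$rate)
  profile <- config$cause_profile
  rates <- tidyr::expand_grid(all_cause, cause = names(profile))
  rates$rate <- unname(rates$rate * profile[rates$cause])
  rates <- as_tibble(rates[, c("sex", "age_band", "residence", "cause", "rate")])

  # reference residual life expectancy (aspirational standard, as used for
  # YLL accounting): smooth concave decline in age, floored at 1 year
  le <- pmax(93.82 - 1.3629 * bands$mid + 0.00456 * bands$mid^2, 1)
  life_table <- tibble(age_band = bands$age_band, le = le)

  structure(list(rates = rates, all_cause = all_cause,
                 life_table = life_table, le0 = config$le0),
            class = "mortality_schedule")
}

#' Generate one exposure-response curve with uncertainty draws
#'
#' The central curve follows the sublinear family
#' `RR(C) = 1 + alpha * (1 - exp(-beta * max(0, C - tmrel)^gamma))`
#' tabulated on a regular concentration grid. Draws perturb `alpha` and
#' `beta` log-normally, so every draw stays at or above 1 and non-decreasing
#' in concentration.
#'
#' @param family_params list or one-row data frame with `pollutant`,
#'   `cause`, `alpha`, `beta`, `gamma`, `tmrel`, optional `age_band`
#'   (default `"all"`), `conc_max` (default 300) and `conc_step`
#'   (default 0.5).
#' @param n_draws number of draws (>= 1).
#' @param noise_scale log-scale sd of the draw perturbation; 0 reproduces
#'   the central curve in every draw.
#' @param seed RNG seed for the draws.
#' @return an [erf_curve()] object.
#' @export
generate_erf_draws <- function(family_params, n_draws = 1L, noise_scale = 0,
                               seed = 1L) {
  p <- as.list(family_params)
  if (is.null(p$age_band)) p$age_band <- "all"
  if (is.null(p$conc_max)) p$conc_max <- 300
  if (is.null(p$conc_step)) p$conc_step <- 0.5
  if (n_draws < 1L) stop_config("`n_draws` must be at least 1")
  if (noise_scale < 0) stop_config("`noise_scale` must be non-negative")

  set.seed(seed)
  conc <- seq(0, p$conc_max, by = p$conc_step)
  central <- erf_family_rr(conc, p$alpha, p$beta, p$gamma, p$tmrel)
  if (noise_scale > 0) {
    eps_a <- rnorm(n_draws, 0, noise_scale)
    eps_b <- rnorm(n_draws, 0, noise_scale)
  } else {
    eps_a <- eps_b <- numeric(n_draws)
  }
  rr <- vapply(seq_len(n_draws), function(d) {
    erf_family_rr(conc, p$alpha * exp(eps_a[d]), p$beta * exp(eps_b[d]),
                  p$gamma, p$tmrel)
  }, numeric(length(conc)))
  rr <- matrix(rr, nrow = length(conc))

  erf_curve(pollutant = p$pollutant, cause = p$cause, age_band = p$age_band,
            tmrel = p$tmrel, conc = conc, rr_central = central, rr = rr,
            family = p[c("alpha", "beta", "gamma")])
}

#' Default exposure-response family parameters
#'
#' One row per pollutant-cause pair: six causes for PM2.5 and COPD for
#' ozone. Shapes are sublinear (`gamma < 1`) for PM2.5 and near-linear for
#' ozone; magnitudes are calibrated so that the default scenario reproduces
#' the national burden scale of the emulated setting (about 1.3 million
#' PM2.5-attributable adult deaths and a PM2.5 loss of life expectancy near
#' 1.9 years in the first year). Ischemic heart disease and stroke are
#' flagged `age_specific`: their curves are generated per age band with
#' risk declining at older ages.
#'
#' @return tibble with columns `pollutant`, `cause`, `alpha`, `beta`,
#'   `gamma`, `tmrel`, `age_specific`, `conc_max`.
#' @export
default_erf_params <- function() {
  tibble(
    pollutant = c(rep("pm25", 6), "o3"),
    cause = c("ihd", "stroke", "lung_cancer", "copd", "lri", "t2dm", "copd"),
    alpha = c(6.75, 7.50, 9.40, 8.25, 11.25, 5.60, 0.513),
    beta = c(0.0045, 0.0040, 0.0025, 0.0030, 0.00375, 0.0050, 0.010),
    gamma = c(0.75, 0.75, 0.85, 0.80, 0.80, 0.70, 1.00),
    tmrel = c(rep(4.15, 6), 64.0),
    age_specific = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    conc_max = c(rep(300, 6), 300)
  )
}

# risk multiplier applied to alpha for age-specific cardiovascular curves
erf_age_multiplier <- function(mid_age) {
  pmin(pmax(1.7 - 0.012 * mid_age, 0.3), 1.6)
}

#' Generate the full exposure-response curve set of a scenario
#'
#' @param config a [scenario_config()].
#' @param params family parameter table, see [default_erf_params()].
#' @param tmrel_interval optional named list of `c(lower, upper)` intervals
#'   per pollutant for per-draw TMREL sampling; `NULL` keeps TMREL fixed.
#' @return named list of [erf_curve()] objects (class `erf_set`).
#' @export
generate_erf_set <- function(config, params = default_erf_params(),
                             tmrel_interval = NULL) {
  config <- validate_scenario_config(config)
  curves <- list()
  idx <- 0L
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    if (isTRUE(row$age_specific)) {
      for (b in seq_len(nrow(config$age_bands))) {
        idx <- idx + 1L
        fam <- as.list(row)
        fam$age_band <- config$age_bands$age_band[b]
        fam$alpha <- row$alpha * erf_age_multiplier(config$age_bands$mid[b])
        cv <- generate_erf_draws(fam, n_draws = config$n_draws,
                                 noise_scale = config$erf_noise_scale,
                                 seed = config$seed + SEED_ERF + idx)
        cv <- erf_sample_tmrel(cv, tmrel_interval, config$seed + SEED_ERF + idx)
        curves[[erf_key(cv$pollutant, cv$cause, cv$age_band)]] <- cv
      }
    } else {
      idx <- idx + 1L
      cv <- generate_erf_draws(as.list(row), n_draws = config$n_draws,
                               noise_scale = config$erf_noise_scale,
                               seed = config$seed + SEED_ERF + idx)
      cv <- erf_sample_tmrel(cv, tmrel_interval, config$seed + SEED_ERF + idx)
      curves[[erf_key(cv$pollutant, cv$cause, cv$age_band)]] <- cv
    }
  }
  structure(curves, class = "erf_set")
}

erf_sample_tmrel <- function(curve, tmrel_interval, seed) {
  iv <- tmrel_interval[[curve$pollutant]]
  if (is.null(iv)) return(curve)
  set.seed(seed + 7L)
  curve$tmrel_draws <- stats::runif(curve$n_draws, iv[1], iv[2])
  curve
}

#' Assemble a complete synthetic bundle
#'
#' Runs every generator and records the generating parameters (`truth`) for
#' recovery tests. Identical config and seed yield a bit-identical bundle.
#'
#' @param config a [scenario_config()].
#' @param tmrel_interval see [generate_erf_set()].
#' @return object of class `synthetic_bundle`: list with `config`,
#'   `exposure` (see [generate_exposure_history()]), `population`,
#'   `mortality`, `erf_set` and `truth`.
#' @export
make_scenario <- function(config = scenario_config(), tmrel_interval = NULL) {
  config <- validate_scenario_config(config)
  exposure <- generate_exposure_history(config)
  population <- generate_population(config)
  mortality <- generate_mortality(config)
  erf_set <- generate_erf_set(config, tmrel_interval = tmrel_interval)
  truth <- list(
    seed = config$seed,
    years = config$years,
    pm25_path = config$pm25_baseline_mean *
      cumprod(c(1, 1 - config$pm25_stage_reductions)),
    o3_path = config$o3_baseline_mean + cumsum(c(0, config$o3_stage_deltas)),
    pm25_stage_reductions = config$pm25_stage_reductions,
    o3_stage_deltas = config$o3_stage_deltas,
    total_population = config$total_population,
    crude_mortality_rate = config$crude_mortality_rate,
    le0 = config$le0
  )
  structure(list(config = config, exposure = exposure,
                 population = population, mortality = mortality,
                 erf_set = erf_set, truth = truth),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  cat(sprintf("  %d cells x %d years, %d population strata rows\n",
              x$config$n_rows * x$config$n_cols, length(x$config$years),
              nrow(x$population)))
  cat(sprintf("  %d exposure-response curves, %d draws each\n",
              length(x$erf_set), x$erf_set[[1]]$n_draws))
  invisible(x)
}
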