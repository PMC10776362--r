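test_that("identical seed and config give a bit-identical bundle; seeds differ", {
  cfg <- small_config(seed = 11, n_rows = 6, n_cols = 6)
  b1 <- suppressMessages(make_scenario(cfg))
  b2 <- suppressMessages(make_scenario(cfg))
  expect_identical(b1, b2)

  b3 <- suppressMessages(make_scenario(small_config(seed = 12, n_rows = 6,
                                                    n_cols = 6)))
  expect_false(identical(b1$exposure$annual$pm25_annual,
                         b3$exposure$annual$pm25_annual))
})

test_that("degenerate no-change scenario yields identical fields across years", {
  cfg <- small_config(seed = 3, n_rows = 6, n_cols = 6,
                      pm25_baseline_sd = 0, pm25_stage_reductions = c(0, 0),
                      pm25_reduction_sd = 0, o3_baseline_sd = 0,
                      o3_stage_deltas = c(0, 0), o3_delta_sd = 0)
  ex <- generate_exposure_history(cfg)
  ann <- ex$annual
  for (y in cfg$years[-1]) {
    expect_equal(ann$pm25_annual[ann$year == y],
                 ann$pm25_annual[ann$year == cfg$years[1]])
    expect_equal(ann$o3_peak_season[ann$year == y],
                 ann$o3_peak_season[ann$year == cfg$years[1]])
  }
  expect_equal(unique(ann$pm25_annual), cfg$pm25_baseline_mean)
  expect_equal(unique(ann$o3_peak_season), cfg$o3_baseline_mean,
               tolerance = 1e-12)
})

test_that("realized population-weighted PM2.5 decline matches the configured stage reduction", {
  # 10 000 cells, 30% mean stage-1 decline, recomputed directly from fields
  cfg <- scenario_config(n_rows = 100, n_cols = 100, years = c(2013L, 2017L),
                         pm25_stage_reductions = 0.30,
                         pm25_reduction_sd = 0.10, o3_stage_deltas = 0,
                         seed = 21)
  ex <- generate_exposure_history(cfg)
  pop <- generate_population(cfg)
  pop_cell <- tapply(pop$count[pop$year == 2013],
                     pop$cell_id[pop$year == 2013], sum)
  ann <- ex$annual
  m1 <- population_weighted_mean(ann$pm25_annual[ann$year == 2013],
                                 as.vector(pop_cell))
  m2 <- population_weighted_mean(ann$pm25_annual[ann$year == 2017],
                                 as.vector(pop_cell))
  realized <- 1 - m2 / m1
  # sampling tolerance: ~100 effective cells at this correlation length
  expect_lt(abs(realized - 0.30), 0.05)
  expect_true(all(ann$pm25_annual >= 0))
})

test_that("population: complete normalized cross-product, conserved totals, aging pyramid", {
  cfg <- small_config(seed = 5, n_rows = 6, n_cols = 6)
  pop <- generate_population(cfg)

  # complete cross-product of subgroup keys per cell-year
  n_sub <- 2L * nrow(cfg$age_bands) * 2L
  counts <- dplyr::count(pop, cell_id, year)
  expect_true(all(counts$n == n_sub))
  expect_true(all(pop$count >= 0))

  # national total conserved each year (within 0.5%; exact by construction)
  totals <- tapply(pop$count, pop$year, sum)
  expect_true(all(abs(totals / cfg$total_population - 1) < 0.005))

  # subgroup shares sum to 1 per cell-year
  shares <- pop |>
    dplyr::group_by(cell_id, year) |>
    dplyr::summarise(s = sum(count), .groups = "drop")
  cell_tot <- shares$s
  per_cell <- pop |>
    dplyr::inner_join(shares, by = c("cell_id", "year")) |>
    dplyr::group_by(cell_id, year) |>
    dplyr::summarise(total_share = sum(count / s), .groups = "drop")
  expect_true(all(abs(per_cell$total_share - 1) < 1e-12))

  # aging: population-weighted mean age strictly increasing
  mids <- setNames(cfg$age_bands$mid, cfg$age_bands$age_band)
  mean_age <- pop |>
    dplyr::group_by(year) |>
    dplyr::summarise(a = sum(count * mids[age_band]) / sum(count)) |>
    dplyr::pull(a)
  expect_true(all(diff(mean_age) > 0))

  # zero aging keeps shares constant across years
  pop0 <- generate_population(small_config(seed = 5, n_rows = 6, n_cols = 6,
                                           aging_rate = 0))
  y1 <- pop0[pop0$year == cfg$years[1], ]
  for (y in cfg$years[-1]) {
    yk <- pop0[pop0$year == y, ]
    expect_equal(yk$count, y1$count, tolerance = 1e-12)
  }
})

test_that("mortality schedule: rates rise with age, residual LE falls, causes conserve the all-cause rate", {
  cfg <- small_config(seed = 2)
  ms <- generate_mortality(cfg)
  bands <- cfg$age_bands$age_band

  one <- ms$all_cause[ms$all_cause$sex == "female" &
                        ms$all_cause$residence == "rural", ]
  one <- one[match(bands, one$age_band), ]
  expect_true(all(diff(one$rate) > 0))
  expect_gt(one$rate[length(bands)], one$rate[1])

  lt <- ms$life_table[match(bands, ms$life_table$age_band), ]
  expect_true(all(diff(lt$le) < 0))
  expect_true(all(lt$le > 0))

  # cause-specific rates sum to the all-cause rate within 1e-12
  summed <- ms$rates |>
    dplyr::group_by(sex, age_band, residence) |>
    dplyr::summarise(rate = sum(rate), .groups = "drop") |>
    dplyr::inner_join(ms$all_cause, by = c("sex", "age_band", "residence"),
                      suffix = c("_sum", "_all"))
  expect_true(all(abs(summed$rate_sum - summed$rate_all) < 1e-12))

  # crude rate under the first-year structure matches the configured target
  pop <- generate_population(cfg)
  p1 <- pop[pop$year == cfg$years[1], ]
  key <- paste(p1$sex, p1$age_band, p1$residence)
  rv <- setNames(ms$all_cause$rate,
                 paste(ms$all_cause$sex, ms$all_cause$age_band,
                       ms$all_cause$residence))
  crude <- sum(p1$count * rv[key]) / sum(p1$count)
  expect_equal(crude, cfg$crude_mortality_rate, tolerance = 0.02)
})

test_that("ERF draws: zero noise collapses to the central curve, RR(TMREL)=1, sublinear increments", {
  par <- list(pollutant = "pm25", cause = "ihd", alpha = 1, beta = 0.01,
              gamma = 0.7, tmrel = 5)
  cv0 <- generate_erf_draws(par, n_draws = 5, noise_scale = 0, seed = 1)
  for (d in 1:5) expect_equal(cv0$rr[, d], cv0$rr_central)

  cv <- generate_erf_draws(par, n_draws = 10, noise_scale = 0.2, seed = 9)
  for (d in 1:10) {
    expect_equal(relative_risk(cv, par$tmrel, d), 1)
    expect_true(all(diff(cv$rr[, d]) >= 0))
    expect_true(all(cv$rr[, d] >= 1))
  }

  # gamma < 1: marginal RR increments shrink with concentration
  above <- cv$conc > par$tmrel + 1
  inc <- diff(cv$rr_central[above])
  expect_true(all(diff(inc) < 1e-12))

  expect_error(generate_erf_draws(par, n_draws = 5, noise_scale = -0.1),
               class = "glequity_config_error")
  expect_error(generate_erf_draws(par, n_draws = 0),
               class = "glequity_config_error")
})

test_that("exposure fields are spatially autocorrelated at the default correlation length", {
  b <- get_default_bundle()
  ann <- b$exposure$annual
  v <- ann$pm25_annual[ann$year == 2013]
  expect_gt(lag1_spatial_correlation(v, b$config$n_rows, b$config$n_cols), 0.5)
  v3 <- ann$o3_peak_season[ann$year == 2013]
  expect_gt(lag1_spatial_correlation(v3, b$config$n_rows, b$config$n_cols), 0.5)
})

test_that("bundle invariants hold and the truth record round-trips through JSON", {
  b <- get_small_bundle()
  expect_true(all(b$population$count >= 0))
  expect_true(all(b$exposure$annual$pm25_annual >= 0))
  expect_true(all(b$exposure$annual$o3_peak_season >= 0))
  expect_equal(b$truth$pm25_stage_reductions,
               b$config$pm25_stage_reductions)

  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(b$truth, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back, b$truth)
})

test_that("configuration validation rejects invalid scenarios", {
  expect_error(scenario_config(n_rows = 0), class = "glequity_config_error")
  expect_error(scenario_config(years = 2013), class = "glequity_config_error")
  expect_error(scenario_config(years = c(2017, 2013)),
               class = "glequity_config_error")
  expect_error(scenario_config(pm25_baseline_mean = -1),
               class = "glequity_config_error")
  expect_error(scenario_config(urban_fraction_range = c(0.5, 1.2)),
               class = "glequity_config_error")
  expect_error(scenario_config(age_bands = default_age_bands()[0, ]),
               class = "glequity_config_error")
})
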