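test_that("burden arithmetic: attributable deaths, YLL, LLE", {
  expect_equal(attributable_deaths(0.2, 0.01, 1000), 2)
  expect_equal(attributable_deaths(0, 0.05, 1e6), 0)
  # additive over disjoint strata with a common AF
  expect_equal(attributable_deaths(0.3, 0.01, 400) +
                 attributable_deaths(0.3, 0.01, 600),
               attributable_deaths(0.3, 0.01, 1000))
  expect_error(attributable_deaths(1.2, 0.01, 10),
               class = "glequity_validation_error")

  expect_equal(years_of_life_lost(c(2), c(20)), 40)
  expect_equal(years_of_life_lost(rep(0, 3), c(30, 20, 10)), 0)
  d <- c(a = 1, b = 2, c = 3)
  le <- c(c = 10, a = 30, b = 20)
  expect_equal(years_of_life_lost(d, le),
               years_of_life_lost(d[c(3, 1, 2)], le))
  expect_error(years_of_life_lost(c(a = 1, b = 1), c(a = 10)),
               class = "glequity_validation_error")

  expect_equal(loss_of_life_expectancy(40, 1000, 80), 3.2)
  expect_equal(loss_of_life_expectancy(0, 10, 70), 0)
  expect_equal(loss_of_life_expectancy(80, 2000, 80),
               loss_of_life_expectancy(40, 1000, 80))
  expect_error(loss_of_life_expectancy(1, 0, 80),
               class = "glequity_validation_error")
})

test_that("exposure at or below TMREL produces zero burden everywhere", {
  cfg <- small_config(seed = 6, n_rows = 4, n_cols = 4,
                      pm25_baseline_mean = 3, pm25_baseline_sd = 0,
                      pm25_stage_reductions = c(0.1, 0.1),
                      pm25_reduction_sd = 0,
                      o3_baseline_mean = 40, o3_baseline_sd = 0,
                      o3_stage_deltas = c(0, 0), o3_delta_sd = 0)
  b <- suppressMessages(make_scenario(cfg))
  bd <- compute_burden(b)
  expect_true(all(bd$by_cell$deaths == 0))
  expect_true(all(bd$by_cell$yll == 0))
  expect_true(all(bd$national$lle == 0))
})

test_that("single-cell burden equals the hand-computed chain AF*B*P*LE*LE0/P", {
  cfg <- small_config(seed = 7, n_rows = 1, n_cols = 1)
  b <- suppressMessages(make_scenario(cfg))
  bd <- compute_burden(b, pollutants = "o3", subgroup_detail = TRUE)

  # hand chain for ozone: one all-ages COPD curve
  ann <- b$exposure$annual[b$exposure$annual$year == 2013, ]
  cv <- b$erf_set[["o3.copd.all"]]
  af <- attributable_fraction(relative_risk(cv, ann$o3_peak_season))
  pop <- b$population[b$population$year == 2013, ]
  rt <- b$mortality$rates[b$mortality$rates$cause == "copd", ]
  m <- merge(pop, rt, by = c("sex", "age_band", "residence"))
  lt <- b$mortality$life_table
  m$le <- lt$le[match(m$age_band, lt$age_band)]
  d_hand <- sum(af * m$rate * m$count)
  yll_hand <- sum(af * m$rate * m$count * m$le)

  nat <- bd$national[bd$national$year == 2013, ]
  expect_equal(nat$deaths, d_hand, tolerance = 1e-12)
  expect_equal(nat$yll, yll_hand, tolerance = 1e-12)
  expect_equal(nat$lle,
               loss_of_life_expectancy(yll_hand, sum(pop$count), cfg$le0),
               tolerance = 1e-12)
})

test_that("national YLL matches the brute-force loop oracle", {
  cfg <- small_config(seed = 9, n_rows = 6, n_cols = 6)
  b <- suppressMessages(make_scenario(cfg))
  bd <- compute_burden(b, subgroup_detail = TRUE)
  for (p in c("pm25", "o3")) {
    oracle <- oracle_national_burden(b, 2013, p)
    nat <- bd$national[bd$national$year == 2013 & bd$national$pollutant == p, ]
    expect_equal(nat$yll, oracle$yll, tolerance = 1e-9)
    expect_equal(nat$deaths, oracle$deaths, tolerance = 1e-9)
  }
  # subgroup table sums back to the national totals
  sg <- bd$by_subgroup |>
    dplyr::group_by(year, pollutant) |>
    dplyr::summarise(deaths = sum(deaths), yll = sum(yll), .groups = "drop")
  nat <- bd$national[order(bd$national$year, bd$national$pollutant), ]
  sg <- sg[order(sg$year, sg$pollutant), ]
  expect_equal(sg$deaths, nat$deaths, tolerance = 1e-12)
  expect_equal(sg$yll, nat$yll, tolerance = 1e-12)
})

test_that("raising one cell's PM2.5 never decreases national YLL", {
  b <- get_small_bundle()
  bd0 <- compute_burden(b, pollutants = "pm25", subgroup_detail = FALSE)
  y0 <- sum(bd0$national$yll)
  b2 <- b
  i <- which(b2$exposure$annual$year == 2013)[5]
  b2$exposure$annual$pm25_annual[i] <-
    b2$exposure$annual$pm25_annual[i] + 25
  bd1 <- compute_burden(b2, pollutants = "pm25", subgroup_detail = FALSE)
  expect_gte(sum(bd1$national$yll), y0)
})

test_that("the draw-wise fast path agrees with the full per-draw computation", {
  b <- get_small_bundle()
  dtab <- national_burden_draws(b, draws = c(3, 11))
  for (d in c(3, 11)) {
    full <- compute_burden(b, draw = d, subgroup_detail = FALSE)$national
    sub <- dtab[dtab$draw == d, ]
    m <- merge(full, sub, by = c("year", "pollutant"),
               suffixes = c("_full", "_fast"))
    expect_equal(m$yll_fast, m$yll_full, tolerance = 1e-12)
    expect_equal(m$deaths_fast, m$deaths_full, tolerance = 1e-12)
    expect_equal(m$lle_fast, m$lle_full, tolerance = 1e-12)
  }
})

test_that("attributable deaths fall more heavily on males, the elderly and urban residents", {
  # emergent ordering of the default scenario (large grid smooths out the
  # sampling noise that can flip it at toy sizes)
  b <- get_default_bundle()
  sg <- compute_burden(b, pollutants = "pm25")$by_subgroup
  sg13 <- sg[sg$year == 2013, ]
  by_sex <- tapply(sg13$deaths, sg13$sex, sum)
  expect_gt(by_sex[["male"]], by_sex[["female"]])
  by_res <- tapply(sg13$deaths, sg13$residence, sum)
  expect_gt(by_res[["urban"]], by_res[["rural"]])
  mids <- setNames(b$config$age_bands$mid, b$config$age_bands$age_band)
  old <- mids[sg13$age_band] >= 65
  expect_gt(sum(sg13$deaths[old]), sum(sg13$deaths[!old]))
})
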