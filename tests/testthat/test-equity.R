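test_that("gain of life expectancy: difference definition, consistency, telescoping", {
  g <- gain_of_life_expectancy(1.86, 1.69, 1000, 77.6)
  expect_equal(g$gle, 0.17)
  expect_equal(g$gle * g$p_y2, 77.6 * g$ylg, tolerance = 1e-9)
  # ~2 months of life gained (printed stage summaries carry input rounding)
  expect_lt(abs(12 * g$gle - 2.11), 0.13)

  expect_equal(gain_of_life_expectancy(1.5, 1.5, 10, 70)$gle, 0)

  # telescoping across consecutive stages is exact
  set.seed(21)
  lle <- matrix(runif(30, 0.5, 2), ncol = 3)
  p <- runif(10, 100, 1000)
  g12 <- gain_of_life_expectancy(lle[, 1], lle[, 2], p, 70)$gle
  g23 <- gain_of_life_expectancy(lle[, 2], lle[, 3], p, 70)$gle
  g13 <- gain_of_life_expectancy(lle[, 1], lle[, 3], p, 70)$gle
  expect_equal(g12 + g23, g13, tolerance = 1e-12)
})

test_that("gle_field validates years and combines pollutants additively", {
  b <- get_small_bundle()
  bd <- compute_burden(b, subgroup_detail = FALSE)
  gf <- gle_field(bd, 2013, 2017)
  expect_equal(nrow(gf), 100)
  expect_equal(gf$gle * gf$p_y2, bd$le0 * gf$ylg, tolerance = 1e-9)

  gf_pm <- gle_field(bd, 2013, 2017, "pm25")
  gf_o3 <- gle_field(bd, 2013, 2017, "o3")
  expect_equal(gf$gle, gf_pm$gle + gf_o3$gle, tolerance = 1e-12)

  # telescoping through the pipeline objects
  g12 <- gle_field(bd, 2013, 2017)$gle
  g23 <- gle_field(bd, 2017, 2020)$gle
  g13 <- gle_field(bd, 2013, 2020)$gle
  expect_equal(g12 + g23, g13, tolerance = 1e-12)

  expect_error(gle_field(bd, 2013, 2019), class = "glequity_validation_error")
  bd_pm <- compute_burden(b, pollutants = "pm25", subgroup_detail = FALSE)
  expect_error(gle_field(bd_pm, 2013, 2017, c("pm25", "o3")),
               class = "glequity_validation_error")
})

test_that("Lorenz curve: equality diagonal, concentration shape, endpoints", {
  # uniform per-capita benefit: exact diagonal, Gini 0
  lz <- lorenz_curve(rep(0.2, 8), runif(8, 10, 100))
  expect_equal(lz$points$benefit_share, lz$points$pop_share, tolerance = 1e-12)
  expect_equal(lz$gini, 0, tolerance = 1e-12)

  # all benefit in one of four equal cells: flat until population share 0.75
  lz4 <- lorenz_curve(c(0, 0, 0, 1), rep(25, 4))
  expect_equal(lz4$points$pop_share, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(lz4$points$benefit_share, c(0, 0, 0, 0, 1))
  expect_equal(lz4$gini, 0.75)

  # endpoints and monotone coordinates for random non-negative instances
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    lz <- lorenz_curve(runif(n), runif(n, 1, 10))
    pts <- lz$points
    expect_equal(pts$pop_share[1], 0)
    expect_equal(pts$benefit_share[1], 0)
    expect_equal(pts$pop_share[nrow(pts)], 1)
    expect_equal(pts$benefit_share[nrow(pts)], 1)
    expect_true(all(diff(pts$pop_share) >= 0))
    expect_true(all(diff(pts$benefit_share) >= -1e-15))
    expect_true(lz$gini >= 0 && lz$gini < 1)
  }

  expect_error(lorenz_curve(numeric(0), numeric(0)),
               class = "glequity_validation_error")
  expect_error(lorenz_curve(c(0, 0), c(1, 1)),
               class = "glequity_computation_error")
})

test_that("trapezoid Gini equals the weighted pairwise-difference oracle", {
  # frozen two-point and four-point cases computed from the pairwise formula
  expect_equal(gini_index(c(0, 3), population = c(1, 1)), 0.5)
  expect_equal(gini_index(c(1, 1, 1, 5), population = rep(1, 4)), 0.375)

  set.seed(97)
  for (i in 1:1000) {
    n <- sample(2:25, 1)
    g <- runif(n)
    p <- runif(n, 0.5, 20)
    expect_equal(gini_index(g, population = p), gini_pairwise(g, p),
                 tolerance = 1e-10)
  }
})

test_that("Gini is invariant to scaling, replication, and obeys the transfer principle", {
  set.seed(41)
  g <- runif(30, 0, 2)
  p <- runif(30, 1, 50)
  gi <- gini_index(g, population = p)
  expect_equal(gini_index(5.7 * g, population = p), gi, tolerance = 1e-12)
  expect_equal(gini_index(c(g, g), population = c(p, p) / 2), gi,
               tolerance = 1e-10)

  # transfer from a higher-GLE cell to a lower one (order preserved) never
  # increases inequality
  g2 <- seq(1, 5, length.out = 10) # spacing 0.44 keeps order after transfers
  p2 <- rep(7, 10)
  gi0 <- gini_index(g2, population = p2)
  for (eps in c(0.05, 0.2)) {
    gt <- g2
    gt[3] <- gt[3] + eps # receives from the richer cell 8
    gt[8] <- gt[8] - eps
    expect_lte(gini_index(gt, population = p2), gi0 + 1e-12)
  }
})

test_that("negative-benefit cells are counted, warned about, or dropped on request", {
  g <- c(-0.5, 1, 2, 3)
  p <- rep(10, 4)
  expect_warning(lz <- lorenz_curve(g, p), "negative")
  expect_equal(lz$n_negative_cells, 1)
  expect_true(any(lz$points$benefit_share < 0))

  expect_message(lzd <- lorenz_curve(g, p, negatives = "drop"), "dropping")
  expect_equal(lzd$n_negative_cells, 1)
  expect_true(all(lzd$points$benefit_share >= 0))
  expect_lt(lzd$gini, 1)
})

test_that("pipeline Gini equals a standalone computation on the assembled field", {
  b <- get_small_bundle()
  bd <- compute_burden(b, subgroup_detail = FALSE)
  gf <- gle_field(bd, 2017, 2020)
  gi_pipe <- suppressWarnings(gini_index(gf))

  # assemble the field directly from the by-cell burden table
  bc <- bd$by_cell |>
    dplyr::group_by(cell_id, year) |>
    dplyr::summarise(lle = sum(lle), pop = population[1], .groups = "drop")
  l1 <- bc[bc$year == 2017, ]
  l2 <- bc[bc$year == 2020, ]
  stopifnot(identical(l1$cell_id, l2$cell_id))
  g_direct <- l1$lle - l2$lle
  expect_equal(gi_pipe, gini_trapezoid_oracle(g_direct, l2$pop),
               tolerance = 1e-12)
})
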