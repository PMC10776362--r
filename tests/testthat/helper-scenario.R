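# Shared fixtures (generated in code) and independent oracles.

small_config <- function(seed = 42, n_rows = 10, n_cols = 10, ...) {
  scenario_config(n_rows = n_rows, n_cols = n_cols, n_draws = 20,
                  total_population = 1e7, seed = seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

# 10x10 bundle reused across tests
get_small_bundle <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- suppressMessages(make_scenario(small_config()))
  }
  .fixtures$small
}

# the default 50x50 scenario (used by the deeper oracle checks)
get_default_bundle <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- suppressMessages(make_scenario(scenario_config(seed = 1)))
  }
  .fixtures$default
}

get_default_burden <- function() {
  if (is.null(.fixtures$default_burden)) {
    .fixtures$default_burden <- compute_burden(get_default_bundle(),
                                               subgroup_detail = FALSE)
  }
  .fixtures$default_burden
}

# --- independent oracles ----------------------------------------------------

# weighted pairwise-difference Gini: sum_ij P_i P_j |g_i - g_j| / (2 P^2 gbar)
gini_pairwise <- function(g, p) {
  gbar <- sum(g * p) / sum(p)
  s <- 0
  for (i in seq_along(g)) s <- s + sum(p[i] * p * abs(g[i] - g))
  s / (2 * sum(p)^2 * gbar)
}

# plain sorted-cumsum trapezoid Gini, written independently of the package
gini_trapezoid_oracle <- function(g, p) {
  o <- order(g)
  x <- c(0, cumsum(p[o]) / sum(p))
  y <- c(0, cumsum((g * p)[o]) / sum(g * p))
  area <- 0
  for (i in 2:length(x)) area <- area + (x[i] - x[i - 1]) * (y[i] + y[i - 1]) / 2
  1 - 2 * area
}

# manual linear interpolation of a curve's central relative risk
oracle_rr <- function(curve, conc) {
  x <- curve$conc
  y <- curve$rr_central
  ev <- function(q) {
    q <- min(max(q, x[1]), x[length(x)])
    j <- findInterval(q, x)
    if (j >= length(x)) return(y[length(x)])
    y[j] + (y[j + 1] - y[j]) * (q - x[j]) / (x[j + 1] - x[j])
  }
  max(ev(max(conc, curve$tmrel)) / ev(curve$tmrel), 1)
}

# brute-force national burden for one year/pollutant: explicit loops over
# cells, causes, age bands, sex and residence, recomputing AF * B * P * LE
# from the raw tables without any of the package's aggregation machinery
oracle_national_burden <- function(bundle, year, pollutant) {
  ann <- bundle$exposure$annual[bundle$exposure$annual$year == year, ]
  conc <- ann[[if (pollutant == "pm25") "pm25_annual" else "o3_peak_season"]]
  cell_ids <- ann$cell_id
  pop <- bundle$population[bundle$population$year == year, ]
  count <- tapply(pop$count,
                  list(pop$cell_id, pop$sex, pop$age_band, pop$residence),
                  sum)
  count <- count[as.character(cell_ids), , , , drop = FALSE]
  rt <- bundle$mortality$rates
  rate <- tapply(rt$rate, list(rt$sex, rt$age_band, rt$residence, rt$cause),
                 sum)
  sexes <- dimnames(count)[[2]]
  bands <- dimnames(count)[[3]]
  residences <- dimnames(count)[[4]]
  rate <- rate[sexes, bands, residences, , drop = FALSE]
  le <- setNames(bundle$mortality$life_table$le,
                 bundle$mortality$life_table$age_band)[bands]
  parts <- strsplit(names(bundle$erf_set), ".", fixed = TRUE)
  causes <- unique(vapply(parts[vapply(parts, `[[`, "", 1) == pollutant],
                          `[[`, "", 2))
  # curve per (cause, band), falling back to the shared all-ages curve
  curve_of <- lapply(causes, function(cs) {
    lapply(bands, function(b) {
      cv <- bundle$erf_set[[paste(pollutant, cs, b, sep = ".")]]
      if (is.null(cv)) bundle$erf_set[[paste(pollutant, cs, "all", sep = ".")]]
      else cv
    })
  })

  deaths <- 0
  yll <- 0
  for (i in seq_along(cell_ids)) {
    cc <- conc[i]
    for (k in seq_along(causes)) {
      ci <- match(causes[k], dimnames(rate)[[4]])
      for (bi in seq_along(bands)) {
        af <- 1 - 1 / oracle_rr(curve_of[[k]][[bi]], cc)
        for (si in seq_along(sexes)) {
          for (ri in seq_along(residences)) {
            d <- af * rate[si, bi, ri, ci] * count[i, si, bi, ri]
            deaths <- deaths + d
            yll <- yll + d * le[bi]
          }
        }
      }
    }
  }
  list(deaths = deaths, yll = unname(yll))
}
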