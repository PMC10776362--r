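#' Attributable deaths in one stratum
#'
#' `D = AF * B * P`: attributable fraction times baseline mortality rate
#' times population. Vectorized.
#'
#' @param af attributable fraction(s) in `[0, 1)`.
#' @param b baseline mortality rate(s), deaths per person-year.
#' @param p population(s) at risk, persons.
#' @return attributable deaths.
#' @export
attributable_deaths <- function(af, b, p) {
  if (any(af < 0 | af >= 1)) stop_validation("`af` must lie in [0, 1)")
  if (any(b < 0)) stop_validation("`b` must be non-negative")
  if (any(p < 0)) stop_validation("`p` must be non-negative")
  af * b * p
}

#' Years of life lost from age-banded deaths
#'
#' `YLL = sum_k D_k * LE_k` with `LE_k` the residual life expectancy of the
#' band in which the deaths occur. If both vectors are named they are
#' matched by band label.
#'
#' @param deaths attributable deaths per age band.
#' @param le residual life expectancy per age band (years).
#' @return total years of life lost.
#' @export
years_of_life_lost <- function(deaths, le) {
  if (!is.null(names(deaths)) && !is.null(names(le))) {
    le <- le[names(deaths)]
  } else {
    check_aligned(deaths, le, "deaths", "le")
  }
  if (any(is.na(le) & deaths > 0)) {
    stop_validation("missing life expectancy for an age band with deaths > 0")
  }
  sum(deaths * le, na.rm = TRUE)
}

#' Loss of life expectancy
#'
#' Per-capita rescaling of YLL: `LLE = LE0 * YLL / P`, in years per person.
#'
#' @param yll years of life lost.
#' @param population persons over which the loss is averaged.
#' @param le0 life expectancy at birth (years), the scaling constant.
#' @return loss of life expectancy (years).
#' @export
loss_of_life_expectancy <- function(yll, population, le0) {
  if (any(population <= 0)) stop_validation("population must be positive")
  le0 * yll / population
}

# causes covered by an ERF set, per pollutant
erf_causes <- function(erf_set, pollutant) {
  parts <- strsplit(names(erf_set), ".", fixed = TRUE)
  unique(vapply(parts[vapply(parts, `[[`, "", 1) == pollutant],
                `[[`, "", 2))
}

# has (pollutant, cause) got age-specific curves?
erf_is_age_specific <- function(erf_set, pollutant, cause) {
  is.null(erf_set[[erf_key(pollutant, cause, "all")]])
}

# per-(cell, year, cause, age_band) aggregated B*P and B*P*LE weights;
# hand-rolled match/rowsum aggregation because the naive many-to-many join
# over cells x strata x causes dominates runtime at realistic grid sizes
burden_weights <- function(bundle, causes) {
  pop <- bundle$population
  rates <- bundle$mortality$rates[bundle$mortality$rates$cause %in% causes, ]
  lt <- bundle$mortality$life_table

  skey <- paste(pop$sex, pop$age_band, pop$residence)
  gkey <- paste(pop$cell_id, pop$year, pop$age_band, sep = "\r")
  first <- !duplicated(gkey)
  gi <- match(gkey, gkey[first])
  meta <- tibble(cell_id = pop$cell_id[first], year = pop$year[first],
                 age_band = pop$age_band[first])
  le <- lt$le[match(meta$age_band, lt$age_band)]

  out <- vector("list", length(causes))
  for (k in seq_along(causes)) {
    rc <- rates[rates$cause == causes[k], ]
    rv <- setNames(rc$rate, paste(rc$sex, rc$age_band, rc$residence))
    r_row <- rv[skey]
    if (anyNA(r_row)) {
      stop_computation("missing baseline rate for cause %s in stratum %s",
                       causes[k], skey[which(is.na(r_row))[1]])
    }
    bp <- as.vector(rowsum(pop$count * unname(r_row), gi, reorder = FALSE))
    out[[k]] <- tibble(meta, cause = causes[k], bp = bp, le = le,
                       bpl = bp * le)
  }
  bind_rows(out)
}

# attributable-fraction table per pollutant: one row per
# (cell_id, year, cause[, age_band]); age_band NA for all-ages curves
af_table <- function(bundle, pollutant, draw) {
  ann <- bundle$exposure$annual
  conc <- if (pollutant == "pm25") ann$pm25_annual else ann$o3_peak_season
  causes <- erf_causes(bundle$erf_set, pollutant)
  if (length(causes) == 0L) {
    stop_computation("no exposure-response curve available for pollutant %s",
                     pollutant)
  }
  bands <- bundle$config$age_bands$age_band
  rows <- list()
  for (cs in causes) {
    if (erf_is_age_specific(bundle$erf_set, pollutant, cs)) {
      for (b in bands) {
        cv <- erf_lookup(bundle$erf_set, pollutant, cs, b)
        if (is.null(cv)) {
          stop_computation("missing exposure-response curve for %s / %s / %s",
                           pollutant, cs, b)
        }
        rows[[length(rows) + 1L]] <- tibble(
          cell_id = ann$cell_id, year = ann$year, cause = cs, age_band = b,
          af = attributable_fraction(relative_risk(cv, conc, draw)))
      }
    } else {
      cv <- erf_lookup(bundle$erf_set, pollutant, cs, "all")
      rows[[length(rows) + 1L]] <- tibble(
        cell_id = ann$cell_id, year = ann$year, cause = cs,
        age_band = NA_character_,
        af = attributable_fraction(relative_risk(cv, conc, draw)))
    }
  }
  bind_rows(rows)
}

# attach the attributable fraction to each weight row, preferring the
# age-band-specific curve and falling back to the shared all-ages one
af_for_weights <- function(w, af) {
  af_banded <- af[!is.na(af$age_band), ]
  af_shared <- af[is.na(af$age_band), ]
  out <- rep(NA_real_, nrow(w))
  if (nrow(af_banded) > 0) {
    i <- match(paste(w$cell_id, w$year, w$cause, w$age_band, sep = "\r"),
               paste(af_banded$cell_id, af_banded$year, af_banded$cause,
                     af_banded$age_band, sep = "\r"))
    out <- af_banded$af[i]
  }
  need <- is.na(out)
  if (any(need) && nrow(af_shared) > 0) {
    i <- match(paste(w$cell_id[need], w$year[need], w$cause[need], sep = "\r"),
               paste(af_shared$cell_id, af_shared$year, af_shared$cause,
                     sep = "\r"))
    out[need] <- af_shared$af[i]
  }
  if (anyNA(out)) {
    j <- which(is.na(out))[1]
    stop_computation("no exposure-response curve resolves for cause %s, age band %s",
                     w$cause[j], w$age_band[j])
  }
  out
}

#' Compute the attributable burden of a bundle
#'
#' Runs the risk assessment chain `AF(C) * B * P` per cell, year, subgroup
#' and cause, then aggregates to deaths, years of life lost (YLL), and
#' per-capita loss of life expectancy (LLE) per pollutant. PM2.5 uses the
#' annual-mean concentration; ozone uses the peak-season metric and its
#' single all-adult COPD curve.
#'
#' @param bundle a [make_scenario()] bundle (or one read back from disk).
#' @param draw `"central"` for the central curve or a draw index.
#' @param pollutants subset of `c("pm25", "o3")`.
#' @param subgroup_detail also compute the national by-subgroup table
#'   (heavier join; switch off inside Monte Carlo loops).
#' @return object of class `burden_result`: list with
#'   * `by_cell`: tibble `cell_id`, `year`, `pollutant`, `deaths`, `yll`,
#'     `population`, `lle`;
#'   * `national`: tibble `year`, `pollutant`, `deaths`, `yll`,
#'     `population`, `lle`;
#'   * `by_subgroup`: tibble `year`, `pollutant`, `sex`, `age_band`,
#'     `residence`, `cause`, `deaths`, `yll` (or `NULL`);
#'   * `le0`, `draw`, `pollutants`, `years`.
#' @export
compute_burden <- function(bundle, draw = "central",
                           pollutants = c("pm25", "o3"),
                           subgroup_detail = TRUE) {
  pollutants <- match.arg(pollutants, c("pm25", "o3"), several.ok = TRUE)
  le0 <- bundle$mortality$le0
  pop_cell <- bundle$population |>
    group_by(.data$cell_id, .data$year) |>
    summarise(population = sum(.data$count), .groups = "drop")

  by_cell <- list()
  by_subgroup <- list()
  for (p in pollutants) {
    causes <- erf_causes(bundle$erf_set, p)
    w <- burden_weights(bundle, causes)
    af <- af_table(bundle, p, draw)
    w$af <- af_for_weights(w, af)

    ckey <- paste(w$cell_id, w$year, sep = "\r")
    cfirst <- !duplicated(ckey)
    ci <- match(ckey, ckey[cfirst])
    agg <- rowsum(cbind(w$af * w$bp, w$af * w$bpl), ci, reorder = FALSE)
    cell <- tibble(cell_id = w$cell_id[cfirst], year = w$year[cfirst],
                   deaths = agg[, 1], yll = agg[, 2]) |>
      left_join(pop_cell, by = c("cell_id", "year")) |>
      mutate(pollutant = p,
             lle = loss_of_life_expectancy(.data$yll, .data$population, le0))
    by_cell[[p]] <- cell

    if (subgroup_detail) {
      by_subgroup[[p]] <- subgroup_burden(bundle, p, causes, af)
    }
  }

  by_cell <- bind_rows(by_cell)
  national <- by_cell |>
    group_by(.data$year, .data$pollutant) |>
    summarise(deaths = sum(.data$deaths), yll = sum(.data$yll),
              population = sum(.data$population), .groups = "drop") |>
    mutate(lle = loss_of_life_expectancy(.data$yll, .data$population, le0)) |>
    select("year", "pollutant", "deaths", "yll", "population", "lle")

  structure(list(
    by_cell = by_cell |>
      select("cell_id", "year", "pollutant", "deaths", "yll",
             "population", "lle"),
    national = national,
    by_subgroup = if (subgroup_detail) bind_rows(by_subgroup) else NULL,
    le0 = le0, draw = draw, pollutants = pollutants,
    years = sort(unique(by_cell$year))
  ), class = "burden_result")
}

# national by-subgroup aggregation: deaths = sum_cells AF * B * P per
# (year, sex, age_band, residence, cause)
subgroup_burden <- function(bundle, pollutant, causes, af) {
  pop <- bundle$population
  rates <- bundle$mortality$rates[bundle$mortality$rates$cause %in% causes, ]
  lt <- bundle$mortality$life_table
  skey <- paste(pop$sex, pop$age_band, pop$residence)
  le <- lt$le[match(pop$age_band, lt$age_band)]
  gkey <- paste(pop$year, pop$sex, pop$age_band, pop$residence, sep = "\r")
  gfirst <- !duplicated(gkey)
  gi <- match(gkey, gkey[gfirst])

  af_banded <- af[!is.na(af$age_band), ]
  af_shared <- af[is.na(af$age_band), ]
  key_cyb <- paste(pop$cell_id, pop$year, pop$age_band, sep = "\r")
  key_cy <- paste(pop$cell_id, pop$year, sep = "\r")

  out <- vector("list", length(causes))
  for (k in seq_along(causes)) {
    cs <- causes[k]
    ab <- af_banded[af_banded$cause == cs, ]
    if (nrow(ab) > 0) {
      af_row <- ab$af[match(key_cyb, paste(ab$cell_id, ab$year, ab$age_band,
                                           sep = "\r"))]
    } else {
      sh <- af_shared[af_shared$cause == cs, ]
      af_row <- sh$af[match(key_cy, paste(sh$cell_id, sh$year, sep = "\r"))]
    }
    rc <- rates[rates$cause == cs, ]
    rv <- setNames(rc$rate, paste(rc$sex, rc$age_band, rc$residence))
    d <- af_row * unname(rv[skey]) * pop$count
    agg <- rowsum(cbind(d, d * le), gi, reorder = FALSE)
    out[[k]] <- tibble(year = pop$year[gfirst], sex = pop$sex[gfirst],
                       age_band = pop$age_band[gfirst],
                       residence = pop$residence[gfirst],
                       cause = cs, deaths = agg[, 1], yll = agg[, 2])
  }
  bind_rows(out) |> mutate(pollutant = pollutant)
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result> draw = %s\n", toString(x$draw)))
  print(x$national)
  invisible(x)
}

# Precomputed fast path for draw-wise national burden: per pollutant a list
# of (curve, concentration, bp, bpl, year) components aligned on exposure
# rows, so each draw costs one interpolation pass per curve.
mc_burden_components <- function(bundle, pollutants) {
  ann <- bundle$exposure$annual
  comps <- list()
  for (p in pollutants) {
    conc <- if (p == "pm25") ann$pm25_annual else ann$o3_peak_season
    causes <- erf_causes(bundle$erf_set, p)
    w <- burden_weights(bundle, causes)
    for (cs in causes) {
      if (erf_is_age_specific(bundle$erf_set, p, cs)) {
        groups <- split(w[w$cause == cs, ],
                        w$age_band[w$cause == cs])
      } else {
        groups <- list(all = w[w$cause == cs, ] |>
                         group_by(.data$cell_id, .data$year) |>
                         summarise(bp = sum(.data$bp), bpl = sum(.data$bpl),
                                   .groups = "drop"))
      }
      for (g in names(groups)) {
        d <- groups[[g]]
        idx <- match(paste(d$cell_id, d$year), paste(ann$cell_id, ann$year))
        comps[[length(comps) + 1L]] <- list(
          pollutant = p,
          curve = erf_lookup(bundle$erf_set, p, cs,
                             if (g == "all") "all" else g),
          conc = conc[idx], bp = d$bp, bpl = d$bpl, year = d$year)
      }
    }
  }
  comps
}

#' National burden per exposure-response draw
#'
#' Recomputes national deaths, YLL and LLE for each draw of the
#' exposure-response curves; the raw material for empirical confidence
#' intervals.
#'
#' @param bundle a [make_scenario()] bundle.
#' @param draws draw indices (default all draws in the ERF set).
#' @param pollutants subset of `c("pm25", "o3")`.
#' @return tibble with `draw`, `year`, `pollutant`, `deaths`, `yll`, `lle`.
#' @export
national_burden_draws <- function(bundle, draws = NULL,
                                  pollutants = c("pm25", "o3")) {
  pollutants <- match.arg(pollutants, c("pm25", "o3"), several.ok = TRUE)
  if (is.null(draws)) draws <- seq_len(bundle$erf_set[[1]]$n_draws)
  comps <- mc_burden_components(bundle, pollutants)
  pop_year <- bundle$population |>
    group_by(.data$year) |>
    summarise(population = sum(.data$count), .groups = "drop")
  le0 <- bundle$mortality$le0
  years <- sort(unique(bundle$exposure$annual$year))

  yl <- as.character(years)
  out <- vector("list", length(draws))
  for (i in seq_along(draws)) {
    d <- draws[i]
    deaths <- matrix(0, length(pollutants), length(years),
                     dimnames = list(pollutants, yl))
    yll <- deaths
    for (cmp in comps) {
      af <- attributable_fraction(relative_risk(cmp$curve, cmp$conc, d))
      ds <- rowsum(cbind(af * cmp$bp, af * cmp$bpl), cmp$year)
      deaths[cmp$pollutant, rownames(ds)] <-
        deaths[cmp$pollutant, rownames(ds)] + ds[, 1]
      yll[cmp$pollutant, rownames(ds)] <-
        yll[cmp$pollutant, rownames(ds)] + ds[, 2]
    }
    out[[i]] <- tibble(
      draw = d,
      pollutant = rep(pollutants, times = length(years)),
      year = rep(years, each = length(pollutants)),
      deaths = as.vector(deaths), yll = as.vector(yll))
  }
  bind_rows(out) |>
    left_join(pop_year, by = "year") |>
    mutate(lle = loss_of_life_expectancy(.data$yll, .data$population, le0)) |>
    select("draw", "year", "pollutant", "deaths", "yll", "lle")
}
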