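#' Gain of life expectancy between two years
#'
#' The health-benefit metric of a control stage: the reduction in loss of
#' life expectancy, `GLE = LLE_y1 - LLE_y2` (years per capita; positive
#' when air quality improved). The population-adjusted years of life gain
#' is derived consistently as `YLG = GLE * P_y2 / LE0`, so that
#' `GLE * P_y2 = LE0 * YLG` holds exactly.
#'
#' @param lle_y1,lle_y2 loss of life expectancy (years) in the stage's
#'   beginning and ending year; vectorized over cells.
#' @param p_y2 population in the ending year.
#' @param le0 life expectancy at birth (years).
#' @return tibble with `gle`, `ylg`, `p_y2`.
#' @examples
#' gain_of_life_expectancy(1.86, 1.69, 1000, 77.6)$gle * 12 # ~2 months
#' @export
gain_of_life_expectancy <- function(lle_y1, lle_y2, p_y2, le0) {
  check_aligned(lle_y1, lle_y2, "lle_y1", "lle_y2")
  gle <- lle_y1 - lle_y2
  tibble(gle = gle, ylg = gle * p_y2 / le0, p_y2 = p_y2)
}

#' Per-cell gain-of-life-expectancy field for a stage
#'
#' Differences the per-cell LLE of a [compute_burden()] result between two
#' years, summing the chosen pollutants' LLE first (additive combination;
#' see the methods vignette for the caveat on pollutant synergy).
#'
#' @param burden a `burden_result`.
#' @param y1,y2 stage beginning and ending years (must be in the result).
#' @param pollutants pollutant set whose LLE is summed.
#' @return tibble of class `gle_field` with `cell_id`, `y1`, `y2`, `gle`,
#'   `ylg`, `p_y2`.
#' @export
gle_field <- function(burden, y1, y2, pollutants = c("pm25", "o3")) {
  if (!all(c(y1, y2) %in% burden$years)) {
    stop_validation("years %d and %d must both be present in the burden result (has: %s)",
                    y1, y2, paste(burden$years, collapse = ", "))
  }
  missing_p <- setdiff(pollutants, burden$pollutants)
  if (length(missing_p) > 0) {
    stop_validation("burden result lacks pollutant(s): %s",
                    paste(missing_p, collapse = ", "))
  }
  cell_lle <- burden$by_cell |>
    filter(.data$pollutant %in% pollutants) |>
    group_by(.data$cell_id, .data$year) |>
    summarise(lle = sum(.data$lle), population = .data$population[1],
              .groups = "drop")
  a <- cell_lle |> filter(.data$year == y1)
  b <- cell_lle |> filter(.data$year == y2)
  m <- inner_join(a, b, by = "cell_id", suffix = c("_1", "_2"))
  out <- tibble(cell_id = m$cell_id, y1 = y1, y2 = y2,
                gain_of_life_expectancy(m$lle_1, m$lle_2, m$population_2,
                                        burden$le0))
  class(out) <- c("gle_field", class(out))
  out
}

#' Population-weighted Lorenz curve of health benefits
#'
#' Cells are sorted by per-capita benefit (GLE) ascending, ties broken by
#' `cell_id` for reproducibility. The curve plots the cumulative population
#' share (horizontal) against the cumulative share of the total benefit
#' `GLE * P` (vertical), reported at every cell boundary, starting at
#' (0, 0). With all benefits non-negative it ends at (1, 1) and lies on or
#' below the diagonal.
#'
#' Cells with negative GLE (areas where pollution worsened) are included by
#' default, with a warning and a count; `negatives = "drop"` removes them
#' with a message instead. With negatives included the curve can dip below
#' zero and the Gini index may exceed 1.
#'
#' @param gle per-cell gain of life expectancy (years per capita), or a
#'   [gle_field()].
#' @param population per-cell population (ending-year).
#' @param cell_id optional cell ids used for stable tie-breaking.
#' @param negatives `"include"` or `"drop"`.
#' @param ... passed between methods.
#' @return object of class `lorenz_result`: list with `points` (tibble
#'   `pop_share`, `benefit_share`), `gini`, `n_negative_cells`,
#'   `negatives`.
#' @export
lorenz_curve <- function(gle, ...) UseMethod("lorenz_curve")

#' @rdname lorenz_curve
#' @export
lorenz_curve.gle_field <- function(gle, negatives = c("include", "drop"), ...) {
  lorenz_curve(gle$gle, gle$p_y2, cell_id = gle$cell_id,
               negatives = negatives)
}

#' @rdname lorenz_curve
#' @export
lorenz_curve.default <- function(gle, population,
                                 cell_id = seq_along(gle),
                                 negatives = c("include", "drop"), ...) {
  negatives <- match.arg(negatives)
  check_aligned(gle, population, "gle", "population")
  check_aligned(gle, cell_id, "gle", "cell_id")
  if (length(gle) < 1L) stop_validation("need at least one cell")
  if (any(population < 0)) stop_validation("population must be non-negative")

  n_neg <- sum(gle < 0)
  if (n_neg > 0) {
    if (negatives == "drop") {
      inform(sprintf("dropping %d cell(s) with negative benefit", n_neg))
      keep <- gle >= 0
      gle <- gle[keep]; population <- population[keep]; cell_id <- cell_id[keep]
    } else {
      warn(sprintf(
        "%d cell(s) have negative benefit; Lorenz curve may dip below zero and the Gini index may exceed 1",
        n_neg))
    }
  }
  if (sum(population) <= 0) stop_validation("total population must be positive")
  benefit <- gle * population
  if (sum(benefit) == 0) {
    stop_computation("total benefit is zero; Lorenz curve undefined")
  }

  ord <- order(gle, cell_id)
  pop_share <- c(0, cumsum(population[ord]) / sum(population))
  benefit_share <- c(0, cumsum(benefit[ord]) / sum(benefit))
  points <- tibble(pop_share = pop_share, benefit_share = benefit_share)
  gini <- 1 - sum(diff(pop_share) *
                    (benefit_share[-1] + benefit_share[-length(benefit_share)]))
  structure(list(points = points, gini = gini, n_negative_cells = n_neg,
                 negatives = negatives),
            class = "lorenz_result")
}

#' @export
print.lorenz_result <- function(x, ...) {
  cat(sprintf("<lorenz_result> %d points, Gini = %.4f, %d negative cell(s)\n",
              nrow(x$points) - 1L, x$gini, x$n_negative_cells))
  invisible(x)
}

#' Gini index of the benefit distribution
#'
#' Twice the area between the Lorenz curve and the diagonal, computed by
#' the trapezoid rule on the exact polygonal curve: 0 for perfectly equal
#' per-capita benefits, approaching 1 as benefits concentrate in a
#' vanishing population share (and possibly exceeding 1 when negative
#' benefits are included).
#'
#' @param x a `lorenz_result`, a [gle_field()], or a numeric vector of
#'   per-cell benefits.
#' @param ... for the numeric method: `population` and the other arguments
#'   of [lorenz_curve()].
#' @return the Gini index (scalar).
#' @examples
#' gini_index(c(1, 1, 1, 5), population = rep(1, 4)) # 0.375
#' @export
gini_index <- function(x, ...) UseMethod("gini_index")

#' @export
gini_index.lorenz_result <- function(x, ...) x$gini

#' @export
gini_index.gle_field <- function(x, ...) lorenz_curve(x, ...)$gini

#' @export
gini_index.default <- function(x, population, ...) {
  lorenz_curve(x, population, ...)$gini
}
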