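# Exposure-response curves are tabulated (MR-BRT-style): ordered
# concentration knots with one relative-risk column per draw plus a central
# column. Relative risk is evaluated as the ratio curve(C)/curve(TMREL),
# clipped to 1 below TMREL and extended flat beyond the last knot.

erf_family_rr <- function(conc, alpha, beta, gamma, tmrel) {
  1 + alpha * (1 - exp(-beta * pmax(0, conc - tmrel)^gamma))
}

erf_key <- function(pollutant, cause, age_band = "all") {
  paste(pollutant, cause, age_band, sep = ".")
}

#' Construct a tabulated exposure-response curve
#'
#' Validates the invariants every curve must satisfy: strictly increasing
#' concentration knots, relative risk at least 1, and per-draw monotonicity
#' in concentration.
#'
#' @param pollutant `"pm25"` or `"o3"`.
#' @param cause cause-of-death label.
#' @param age_band age band label, or `"all"` for a curve shared by all
#'   adult ages.
#' @param tmrel theoretical minimum-risk exposure level (ug/m3).
#' @param conc ordered concentration knots (ug/m3).
#' @param rr_central central relative-risk column.
#' @param rr matrix of relative risk, one column per draw.
#' @param family optional list of generating family parameters.
#' @param tmrel_draws optional per-draw TMREL values (same length as draws);
#'   used for TMREL-uncertainty sampling.
#' @return object of class `erf_curve`.
#' @export
erf_curve <- function(pollutant, cause, age_band, tmrel, conc, rr_central,
                      rr, family = NULL, tmrel_draws = NULL) {
  if (length(conc) == 0L) stop_validation("empty concentration table")
  x <- list(pollutant = pollutant, cause = cause, age_band = age_band,
            tmrel = tmrel, conc = conc, rr_central = rr_central,
            rr = rr, n_draws = ncol(rr), family = family,
            tmrel_draws = tmrel_draws)
  class(x) <- "erf_curve"
  validate_erf_curve(x)
}

validate_erf_curve <- function(curve) {
  lab <- erf_key(curve$pollutant, curve$cause, curve$age_band)
  if (any(diff(curve$conc) <= 0)) {
    stop_validation("curve %s: concentration knots must be strictly increasing", lab)
  }
  cols <- cbind(curve$rr_central, curve$rr)
  if (anyNA(cols)) {
    stop_validation("curve %s: missing relative-risk values (ragged draw columns?)", lab)
  }
  bad_rows <- which(apply(cols, 2, function(col) any(diff(col) < -1e-12)))
  if (length(bad_rows) > 0) {
    first <- bad_rows[1]
    col <- cols[, first]
    row <- which(diff(col) < -1e-12)[1]
    stop_validation(
      "curve %s: relative risk decreases with concentration (column %d, knot %g -> %g)",
      lab, first, curve$conc[row], curve$conc[row + 1L])
  }
  if (any(cols < 1 - 1e-9)) {
    stop_validation("curve %s: relative risk below 1 after normalization", lab)
  }
  if (!is.null(curve$tmrel_draws) &&
      length(curve$tmrel_draws) != curve$n_draws) {
    stop_validation("curve %s: tmrel_draws length differs from n_draws", lab)
  }
  curve
}

#' @export
print.erf_curve <- function(x, ...) {
  cat(sprintf("<erf_curve> %s / %s / %s: %d knots, %d draws, TMREL %.2f\n",
              x$pollutant, x$cause, x$age_band, length(x$conc), x$n_draws,
              x$tmrel))
  invisible(x)
}

#' Relative risk at a concentration
#'
#' Evaluates `curve(C) / curve(TMREL)` by linear interpolation between
#' knots, with RR clipped to 1 at and below TMREL and held flat beyond the
#' last knot. Vectorized over `concentration`.
#'
#' @param curve an [erf_curve()].
#' @param concentration concentration(s), ug/m3, non-negative.
#' @param draw `"central"` or a 1-based draw index.
#' @return relative risk(s), always `>= 1`.
#' @examples
#' cv <- erf_curve("pm25", "ihd", "all", tmrel = 5, conc = c(5, 15),
#'                 rr_central = c(1, 1.2), rr = cbind(c(1, 1.2)))
#' relative_risk(cv, 10) # 1.1
#' @export
relative_risk <- function(curve, concentration, draw = "central") {
  if (length(curve$conc) == 0L) stop_validation("empty curve table")
  if (any(concentration < 0)) stop_validation("concentration must be non-negative")
  if (identical(draw, "central")) {
    col <- curve$rr_central
    tmrel <- curve$tmrel
  } else {
    if (!is.numeric(draw) || draw < 1 || draw > curve$n_draws) {
      stop_validation("draw index %s out of range 1..%d",
                      toString(draw), curve$n_draws)
    }
    col <- curve$rr[, draw]
    tmrel <- if (!is.null(curve$tmrel_draws)) curve$tmrel_draws[draw] else curve$tmrel
  }
  eval_at <- function(x) {
    x <- pmin(pmax(x, curve$conc[1]), curve$conc[length(curve$conc)])
    if (length(curve$conc) == 1L) return(rep(col[1], length(x)))
    approx(curve$conc, col, xout = x, rule = 2)$y
  }
  v <- eval_at(pmax(concentration, tmrel))
  v0 <- eval_at(tmrel)
  pmax(v / v0, 1)
}

#' Attributable fraction from a relative risk
#'
#' `AF = 1 - 1/RR`; the share of deaths attributable to exposure above the
#' minimum-risk level. Vectorized.
#'
#' @param rr relative risk(s), strictly positive.
#' @return attributable fraction(s); in `[0, 1)` whenever `rr >= 1`.
#' @examples
#' attributable_fraction(c(1, 1.25, 2)) # 0, 0.2, 0.5
#' @export
attributable_fraction <- function(rr) {
  if (any(rr <= 0)) stop_validation("relative risk must be strictly positive")
  1 - 1 / rr
}

ERF_TABLE_HEADER <- "# glequity erf_table v1"

#' Write an exposure-response curve set to delimited text
#'
#' One row per (curve, knot); columns `pollutant`, `cause`, `age_band`,
#' `tmrel`, `concentration`, `rr_central`, then `draw_0` ... `draw_{n-1}`.
#' A versioned comment header line identifies the dialect.
#'
#' @param erf_set named list of [erf_curve()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_erf_table <- function(erf_set, path) {
  rows <- lapply(erf_set, function(cv) {
    draws <- as.data.frame(cv$rr)
    names(draws) <- sprintf("draw_%d", seq_len(cv$n_draws) - 1L)
    out <- tibble(pollutant = cv$pollutant, cause = cv$cause,
                  age_band = cv$age_band, tmrel = cv$tmrel,
                  concentration = cv$conc, rr_central = cv$rr_central)
    dplyr::bind_cols(out, draws)
  })
  tab <- bind_rows(rows)
  writeLines(ERF_TABLE_HEADER, path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Load an exposure-response curve set from delimited text
#'
#' Reads the dialect written by [write_erf_table()] and validates every
#' curve on load; monotonicity violations and ragged draw columns are
#' rejected with a message naming the offending curve and knot.
#'
#' @param path file path.
#' @return named list of validated [erf_curve()] objects (class `erf_set`).
#' @export
load_erf_table <- function(path) {
  if (!file.exists(path)) stop_validation("ERF table not found: %s", path)
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("pollutant", "cause", "age_band", "tmrel", "concentration")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop_validation("ERF table missing column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  draw_cols <- grep("^draw_[0-9]+$", names(tab), value = TRUE)
  draw_cols <- draw_cols[order(as.integer(sub("draw_", "", draw_cols)))]
  if (length(draw_cols) == 0L) stop_validation("ERF table has no draw columns")
  if (anyNA(tab$tmrel)) stop_validation("ERF table has rows with missing TMREL")

  keys <- split(seq_len(nrow(tab)),
                erf_key(tab$pollutant, tab$cause, tab$age_band))
  curves <- lapply(keys, function(idx) {
    d <- tab[idx, ]
    d <- d[order(d$concentration), ]
    rr_central <- if ("rr_central" %in% names(d)) d$rr_central else
      rowMeans(as.matrix(d[, draw_cols]))
    erf_curve(pollutant = d$pollutant[1], cause = d$cause[1],
              age_band = d$age_band[1], tmrel = d$tmrel[1],
              conc = d$concentration, rr_central = rr_central,
              rr = as.matrix(d[, draw_cols]))
  })
  structure(curves[order(names(curves))], class = "erf_set")
}

# resolve the curve for (pollutant, cause, age_band), falling back to the
# all-ages curve when no age-specific one exists
erf_lookup <- function(erf_set, pollutant, cause, age_band) {
  cv <- erf_set[[erf_key(pollutant, cause, age_band)]]
  if (is.null(cv)) cv <- erf_set[[erf_key(pollutant, cause, "all")]]
  cv
}
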