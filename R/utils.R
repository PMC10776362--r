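#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate select filter arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows rename n across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats approx dnorm pnorm quantile rnorm sd setNames
NULL

# Error classes: config/validation errors are user-input problems (CLI exit 2),
# computation errors arise mid-pipeline (CLI exit 3).
stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "glequity_config_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "glequity_validation_error")
}

stop_computation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "glequity_computation_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_aligned <- function(a, b, what_a, what_b) {
  if (length(a) != length(b)) {
    stop_validation("`%s` (length %d) and `%s` (length %d) must be aligned",
                    what_a, length(a), what_b, length(b))
  }
}
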