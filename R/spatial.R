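# Spatially autocorrelated standard fields: white noise smoothed with an
# isotropic Gaussian kernel of bandwidth `corr_length` cells, then empirically
# re-standardized to mean 0 / sd 1 so callers control location and scale
# exactly. Smoothing is separable: a banded row kernel times a banded column
# kernel, with edge renormalization so border cells are unbiased.

gaussian_kernel_matrix <- function(n, bw) {
  if (bw <= 0 || n == 1L) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- dnorm(d, sd = bw)
  k[abs(d) > ceiling(3 * bw)] <- 0
  k / rowSums(k)
}

smooth_standard_field <- function(n_rows, n_cols, corr_length) {
  z <- matrix(rnorm(n_rows * n_cols), nrow = n_rows, ncol = n_cols)
  if (corr_length > 0) {
    kr <- gaussian_kernel_matrix(n_rows, corr_length)
    kc <- gaussian_kernel_matrix(n_cols, corr_length)
    z <- kr %*% z %*% t(kc)
  }
  s <- sd(as.vector(z))
  if (!is.finite(s) || s == 0) return(matrix(0, n_rows, n_cols))
  (z - mean(z)) / s
}

# Field as a vector ordered by row-major cell_id (grid_cells() order).
smooth_field_vector <- function(config) {
  as.vector(t(smooth_standard_field(config$n_rows, config$n_cols,
                                    config$spatial_corr_length)))
}

#' Lag-1 spatial autocorrelation of a gridded field
#'
#' Pearson correlation between horizontally adjacent cell pairs; a quick
#' diagnostic that generated exposure fields are spatially structured.
#'
#' @param values numeric vector in row-major cell order.
#' @param n_rows,n_cols grid dimensions.
#' @return correlation coefficient.
#' @export
lag1_spatial_correlation <- function(values, n_rows, n_cols) {
  m <- matrix(values, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  if (n_cols < 2L) stop_computation("need at least two columns")
  stats::cor(as.vector(m[, -n_cols]), as.vector(m[, -1L]))
}
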