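#' Uniform acquisition time grid
#'
#' DCE-MRI dynamic series are acquired on a uniform temporal grid. The grid
#' holds the number of frames and the sampling interval; times start at zero,
#' `t_i = i * dt` for `i = 0, ..., n_points - 1`.
#'
#' @param n_points Number of frames (default 75).
#' @param dt Sampling interval in seconds (default 5).
#' @return An object of class `time_grid` with fields `n_points`, `dt` and the
#'   derived `times` (seconds).
#' @examples
#' g <- time_grid()
#' length(g$times)  # 75
#' @export
time_grid <- function(n_points = 75L, dt = 5.0) {
  if (!is.numeric(n_points) || length(n_points) != 1L || !is.finite(n_points) ||
      n_points < 2 || n_points != round(n_points)) {
    stop("`n_points` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  structure(
    list(n_points = n_points, dt = as.numeric(dt),
         times = seq(0, by = dt, length.out = n_points)),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d points, dt = %g s, duration %g s\n",
              x$n_points, x$dt, x$times[x$n_points]))
  invisible(x)
}

is_time_grid <- function(x) inherits(x, "time_grid")

assert_grid <- function(grid) {
  if (!is_time_grid(grid)) stop("expected a `time_grid` object", call. = FALSE)
  invisible(grid)
}

# Fine grid used for convolution quadrature: subdivides each acquisition
# interval into `factor` steps. Returns times and the indices of the original
# acquisition samples within the fine grid.
supersample_grid <- function(grid, factor = 10L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("supersampling factor must be >= 1", call. = FALSE)
  dtf <- grid$dt / factor
  n_fine <- (grid$n_points - 1L) * factor + 1L
  list(times = seq(0, by = dtf, length.out = n_fine),
       dt = dtf,
       pick = seq(1L, n_fine, by = factor))
}
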