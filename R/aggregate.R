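# Cross-device aggregation and utility metrics.
#
# The collector averages the reconstructed value of every device at each
# timestamp; utility of the private estimate is scored against the mean of
# the raw streams by mean relative error (usability) and root-mean-square
# error (bias, attribute units).

# Average a list of data.frames (t, x) sharing one grid.
aggregate_mean <- function(streams) {
  grid <- common_grid(streams)
  vals <- vapply(streams, function(s) s$x, numeric(length(grid)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = length(grid))
  data.frame(t = grid, avg = rowMeans(vals))
}

#' Per-timestamp mean of reconstructed streams
#'
#' `AVG_est(x_i) = (1/w) * sum over devices of the reconstructed value at
#' t_i`. All streams must share an identical timestamp grid.
#'
#' @param reconstructed list of reconstructed streams (data.frames `t`,
#'   `x`) on a common grid.
#' @return data.frame `t`, `avg` with one row per grid timestamp.
#' @export
mean_estimate <- function(reconstructed) aggregate_mean(reconstructed)

#' Per-timestamp mean of raw streams
#'
#' As [mean_estimate()] but on the original, unperturbed device streams:
#' the ground truth `AVG_actual`.
#'
#' @param streams list of device streams on a common grid.
#' @return data.frame `t`, `avg`.
#' @export
mean_actual <- function(streams) aggregate_mean(streams)

check_same_grid <- function(actual, est) {
  if (!isTRUE(all.equal(actual$t, est$t)))
    stop("actual and estimated series must share the same grid")
}

#' Mean relative error
#'
#' `MRE = (1/n) * sum |AVG_actual(x_i) - AVG_est(x_i)| / AVG_actual(x_i)`.
#' Dimensionless; requires every actual mean to be nonzero (guaranteed for
#' physiological attributes such as heart rate).
#'
#' @param actual,est data.frames `t`, `avg` on the same grid.
#' @return nonnegative scalar.
#' @export
mre <- function(actual, est) {
  check_same_grid(actual, est)
  if (any(actual$avg == 0))
    stop("MRE undefined: actual mean is zero at some timestamp")
  mean(abs(actual$avg - est$avg) / actual$avg)
}

#' Root-mean-square error
#'
#' `RMSE = sqrt((1/n) * sum (AVG_actual(x_i) - AVG_est(x_i))^2)`, in
#' attribute units; more sensitive than MRE to single large deviations.
#'
#' @param actual,est data.frames `t`, `avg` on the same grid.
#' @return nonnegative scalar.
#' @export
rmse <- function(actual, est) {
  check_same_grid(actual, est)
  sqrt(mean((actual$avg - est$avg)^2))
}
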