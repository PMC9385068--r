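# Collector-side curve reconstruction.
#
# The collector receives perturbed salient points and interpolates them
# back onto the device's full timestamp grid. All three methods pass
# exactly through the knots (interpolation, never smoothing):
#   linear -- straight chords between consecutive knots;
#   pchip  -- C1 shape-preserving piecewise-cubic Hermite (Fritsch-Carlson
#             weighted-harmonic-mean knot slopes);
#   spline -- C2 cubic spline with the not-a-knot end condition.
# Queries outside the knot span are refused; the pipeline guarantees the
# grid lies inside it because stream endpoints are always salient.

recon_methods <- c("linear", "pchip", "spline")

check_knots_grid <- function(tk, grid) {
  if (length(tk) < 2L) stop("need at least 2 knots to reconstruct")
  if (any(grid < tk[1L]) || any(grid > tk[length(tk)]))
    stop("grid extends beyond the knot span; extrapolation is refused")
}

recon_values <- function(tk, xk, grid, method) {
  check_knots_grid(tk, grid)
  switch(method,
    linear = stats::approx(tk, xk, xout = grid, method = "linear")$y,
    pchip = if (length(tk) == 2L)
      stats::approx(tk, xk, xout = grid)$y
    else
      pracma::pchip(tk, xk, grid),
    spline = spline_notaknot(tk, xk, grid),
    stop("unknown reconstruction method '", method, "'")
  )
}

# Not-a-knot cubic spline evaluated at `grid`. Moments M_i = S''(t_i) solve
# the standard continuity system; the first and last rows impose third-
# derivative continuity at the second and second-to-last knots. Degenerate
# knot counts collapse as the end condition dictates: 2 knots -> the
# chord, 3 knots -> the single interpolating parabola.
spline_notaknot <- function(tk, xk, grid) {
  n <- length(tk)
  if (n == 2L)
    return(stats::approx(tk, xk, xout = grid)$y)
  if (n == 3L) {
    co <- solve(outer(tk, 0:2, `^`), xk)   # quadratic through 3 points
    return(co[1] + co[2] * grid + co[3] * grid^2)
  }
  h <- diff(tk)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i]     <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((xk[i + 1] - xk[i]) / h[i] -
                   (xk[i] - xk[i - 1]) / h[i - 1])
  }
  # not-a-knot: S''' continuous across t_2 and t_{n-1}
  A[1, 1:3] <- c(h[2], -(h[1] + h[2]), h[1])
  A[n, (n - 2):n] <- c(h[n - 1], -(h[n - 2] + h[n - 1]), h[n - 2])
  M <- solve(A, rhs)
  idx <- pmin(pmax(findInterval(grid, tk), 1L), n - 1L)
  hi <- h[idx]
  a <- tk[idx + 1L] - grid
  b <- grid - tk[idx]
  (M[idx] * a^3 + M[idx + 1L] * b^3) / (6 * hi) +
    (xk[idx] / hi - M[idx] * hi / 6) * a +
    (xk[idx + 1L] / hi - M[idx + 1L] * hi / 6) * b
}

#' Linear reconstruction
#'
#' Connects consecutive perturbed salient points by straight lines and
#' evaluates on the full grid.
#'
#' @param perturbed data.frame `t`, `x` of perturbed salient points
#'   (>= 2 rows, `t` increasing).
#' @param grid numeric vector of timestamps to reconstruct on; must lie
#'   within the knot span.
#' @return data.frame `t`, `x` covering `grid`.
#' @export
reconstruct_linear <- function(perturbed, grid)
  data.frame(t = grid, x = recon_values(perturbed$t, perturbed$x, grid,
                                        "linear"))

#' Shape-preserving cubic Hermite reconstruction
#'
#' Piecewise-cubic Hermite interpolation with Fritsch-Carlson knot slopes
#' (weighted harmonic mean of adjacent secants; zero at local extrema), so
#' the interpolant is C1 and never overshoots the bracketing knot values.
#' With two knots it reduces to the straight line.
#'
#' @inheritParams reconstruct_linear
#' @return data.frame `t`, `x` covering `grid`.
#' @export
reconstruct_pchip <- function(perturbed, grid)
  data.frame(t = grid, x = recon_values(perturbed$t, perturbed$x, grid,
                                        "pchip"))

#' Cubic spline reconstruction
#'
#' C2 cubic spline through the perturbed salient points with the
#' not-a-knot end condition; smoother than pchip but not shape-preserving.
#'
#' @inheritParams reconstruct_linear
#' @return data.frame `t`, `x` covering `grid`.
#' @export
reconstruct_spline <- function(perturbed, grid)
  data.frame(t = grid, x = recon_values(perturbed$t, perturbed$x, grid,
                                        "spline"))

#' Reconstruct a perturbed stream on the full grid
#'
#' Dispatch over the three reconstruction methods.
#'
#' @inheritParams reconstruct_linear
#' @param method one of `"linear"`, `"pchip"`, `"spline"`.
#' @return data.frame `t`, `x` covering `grid`.
#' @export
reconstruct <- function(perturbed, grid, method = c("linear", "pchip",
                                                    "spline")) {
  method <- match.arg(method)
  data.frame(t = grid, x = recon_values(perturbed$t, perturbed$x, grid,
                                        method))
}
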