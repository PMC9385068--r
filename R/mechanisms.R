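# Device-side perturbation mechanisms.
#
# The adaptive Laplace mechanism perturbs each salient value x_i as
#   x*_i = x_i + r_i * Lap(delta_s / eps_i),    eps_i = eps / p,
# where delta_s = x_max - x_min over the device's salient values and the
# adaptive random value r_i in [0,1] shrinks the noise according to the
# normalized value y_i and the TOTAL budget eps:
#   r_i = ((e^eps - 1) / (2 e^eps + 2)) * y_i + 1/2.
# The noise has zero mean, so every x*_i is unbiased. Two baselines are
# provided for comparison: the same pipeline without the adaptive factor
# (salient-point Laplace), and plain per-point Laplace over the whole
# stream with budget eps/n.

#' Normalize values to [-1, 1]
#'
#' Computes `y_i = (x_i - x_mean) / (x_max - x_min)` with statistics taken
#' from the supplied (salient) values themselves. When all values are equal
#' the range is zero; the convention `y_i = 0` is used and the result is
#' flagged degenerate.
#'
#' @param x numeric vector of (salient) values.
#' @return list with `y` (normalized values), `stats` (list `x_min`,
#'   `x_max`, `x_mean`, `delta_s`), and `degenerate` (logical).
#' @export
normalize_values <- function(x) {
  if (!length(x)) stop("empty value list")
  x_min <- min(x); x_max <- max(x); x_mean <- mean(x)
  delta_s <- x_max - x_min
  degenerate <- delta_s == 0
  y <- if (degenerate) rep(0, length(x)) else (x - x_mean) / delta_s
  list(y = y,
       stats = list(x_min = x_min, x_max = x_max, x_mean = x_mean,
                    delta_s = delta_s),
       degenerate = degenerate)
}

#' Adaptive random value
#'
#' `r = ((e^eps - 1)/(2 e^eps + 2)) * y + 1/2`, the per-point weight that
#' scales the Laplace noise. For any `y` in `[-1, 1]` and `eps >= 0` the
#' result lies in `[0, 1]`: the slope factor increases from 0 at `eps = 0`
#' towards its supremum 1/2. Computed as `(1 - e^-eps)/(2 (1 + e^-eps))`
#' for numerical stability at large `eps`. Vectorized over `y` and `eps`.
#'
#' @param y normalized value(s) in `[-1, 1]`.
#' @param epsilon total privacy budget, `>= 0`.
#' @return numeric value(s) in `[0, 1]`.
#' @examples
#' adaptive_random_value(1, log(3))  # 0.75
#' @export
adaptive_random_value <- function(y, epsilon) {
  if (any(y < -1 | y > 1)) stop("y must lie in [-1, 1]")
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  e <- exp(-epsilon)
  (1 - e) / (2 * (1 + e)) * y + 0.5
}

#' Draw Laplace noise
#'
#' Samples from the zero-mean Laplace density `(1/2b) exp(-|x|/b)` by
#' inverse-CDF transform of a single uniform draw per sample, so the output
#' is a deterministic function of R's RNG state (seed with [set.seed()]).
#'
#' @param n number of draws.
#' @param scale the scale `b > 0`; the variance is `2 b^2`.
#' @return numeric vector of length `n`.
#' @export
rlaplace <- function(n, scale) {
  if (scale <= 0) stop("scale must be > 0")
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Split the privacy budget across salient points
#'
#' @param epsilon total budget, `> 0`.
#' @param p number of salient points, `>= 1`.
#' @return list with `epsilon_total`, `p`, and the per-point budget
#'   `epsilon_i = epsilon / p`.
#' @export
allocate_budget <- function(epsilon, p) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (p < 1) stop("p must be >= 1")
  list(epsilon_total = epsilon, p = p, epsilon_i = epsilon / p)
}

#' Adaptive Laplace perturbation of salient points
#'
#' Implements the adaptive Laplace mechanism: each salient value receives
#' Laplace noise of scale `delta_s / (epsilon/p)` multiplied by its
#' adaptive random value (computed from the total budget). Timestamps are
#' unchanged; values are not clamped to any physiological range. When all
#' salient values are equal (`delta_s = 0`) the values pass through
#' unperturbed with a warning.
#'
#' @param salient data.frame `t`, `x` of salient points.
#' @param epsilon total privacy budget (`> 0`).
#' @param noise_factor multiplier on the noise term; 1 for the mechanism
#'   proper, 0 for a noise-free diagnostic run.
#' @return data.frame `t`, `x` with perturbed values.
#' @export
perturb_adaptive <- function(salient, epsilon, noise_factor = 1) {
  p <- nrow(salient)
  b <- allocate_budget(epsilon, p)
  nrm <- normalize_values(salient$x)
  if (nrm$degenerate) {
    warning("zero sensitivity (all salient values equal); ",
            "emitting values unperturbed")
    return(data.frame(t = salient$t, x = salient$x))
  }
  r <- adaptive_random_value(nrm$y, epsilon)
  lambda <- nrm$stats$delta_s / b$epsilon_i
  data.frame(t = salient$t,
             x = salient$x + noise_factor * r * rlaplace(p, lambda))
}

#' Salient-point Laplace baseline
#'
#' Comparison arm: identical budget split and sensitivity as
#' [perturb_adaptive()] but without the adaptive factor, i.e.
#' `x*_i = x_i + Lap(delta_s / (epsilon/p))`.
#'
#' @inheritParams perturb_adaptive
#' @return data.frame `t`, `x` with perturbed values.
#' @export
perturb_kim <- function(salient, epsilon, noise_factor = 1) {
  p <- nrow(salient)
  b <- allocate_budget(epsilon, p)
  delta_s <- max(salient$x) - min(salient$x)
  if (delta_s == 0) {
    warning("zero sensitivity (all salient values equal); ",
            "emitting values unperturbed")
    return(data.frame(t = salient$t, x = salient$x))
  }
  lambda <- delta_s / b$epsilon_i
  data.frame(t = salient$t,
             x = salient$x + noise_factor * rlaplace(p, lambda))
}

#' Whole-stream Laplace baseline
#'
#' Comparison arm without salient-point compression: every one of the `n`
#' original points is perturbed with `Lap(delta_s / (epsilon/n))`. The
#' output already covers the full grid, so no reconstruction is needed.
#'
#' @param stream a full device stream.
#' @inheritParams perturb_adaptive
#' @return data.frame `t`, `x` with perturbed values on the full grid.
#' @export
perturb_dwork <- function(stream, epsilon, noise_factor = 1) {
  n <- nrow(stream)
  b <- allocate_budget(epsilon, n)
  delta_s <- max(stream$x) - min(stream$x)
  if (delta_s == 0) {
    warning("zero sensitivity (all values equal); ",
            "emitting values unperturbed")
    return(data.frame(t = stream$t, x = stream$x))
  }
  lambda <- delta_s / b$epsilon_i
  data.frame(t = stream$t,
             x = stream$x + noise_factor * rlaplace(n, lambda))
}
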