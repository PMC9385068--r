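knots3 <- data.frame(t = c(1, 4, 5), x = c(70, 74, 73))

test_that("linear reconstruction follows the chord and hits knots
          exactly", {
  expect_equal(reconstruct_linear(data.frame(t = c(0, 2), x = c(0, 4)),
                                  1)$x, 2)
  expect_equal(reconstruct_linear(knots3, 2)$x, 70 + 4 / 3)
  for (m in c("linear", "pchip", "spline"))
    expect_equal(reconstruct(knots3, knots3$t, m)$x, knots3$x,
                 tolerance = 1e-12)
})

test_that("pchip is shape preserving: monotone data, no overshoot, and the
          2-knot case is the chord", {
  two <- data.frame(t = c(0, 2), x = c(1, 5))
  g <- seq(0, 2, by = 0.1)
  expect_equal(reconstruct_pchip(two, g)$x, 1 + 2 * g)

  mono <- data.frame(t = c(0, 1, 3, 7, 8), x = c(60, 61, 75, 76, 90))
  dense <- seq(0, 8, by = 0.01)
  expect_true(all(diff(reconstruct_pchip(mono, dense)$x) >= -1e-10))

  set.seed(42)
  for (i in 1:10) {
    tk <- sort(sample(0:50, 6))
    xk <- runif(6, 60, 120)
    pk <- data.frame(t = tk, x = xk)
    gg <- seq(min(tk), max(tk), length.out = 400)
    v <- reconstruct_pchip(pk, gg)$x
    seg <- findInterval(gg, tk, rightmost.closed = TRUE)
    lo <- pmin(xk[seg], xk[seg + 1]); hi <- pmax(xk[seg], xk[seg + 1])
    expect_true(all(v >= lo - 1e-8 & v <= hi + 1e-8))
  }
})

test_that("spline reconstruction is C2 and reproduces cubics", {
  tk <- c(0, 1, 2.5, 4, 6, 7)
  set.seed(3)
  xk <- runif(length(tk), 60, 120)
  pk <- data.frame(t = tk, x = xk)
  # each side of a knot is one cubic; recover it exactly from 4 dense
  # samples and compare second derivatives at the knot
  d2_at <- function(i, side) {
    gap <- if (side < 0) tk[i] - tk[i - 1] else tk[i + 1] - tk[i]
    z <- tk[i] + side * gap * c(0.1, 0.2, 0.3, 0.4)
    v <- reconstruct_spline(pk, z)$x
    co <- solve(outer(z - tk[i], 0:3, `^`), v)
    2 * co[3]
  }
  for (i in 2:(length(tk) - 1)) {
    jump <- abs(d2_at(i, -1) - d2_at(i, 1))
    expect_lt(jump / max(1, abs(d2_at(i, -1))), 1e-8)
  }

  # exact reproduction of a single cubic through the knots
  cub <- function(z) z^3 - 2 * z^2 + 3 * z + 5
  pk2 <- data.frame(t = tk, x = cub(tk))
  g <- seq(min(tk), max(tk), length.out = 500)
  expect_equal(reconstruct_spline(pk2, g)$x, cub(g), tolerance = 1e-9)
  # independent route: stats::spline's fmm end condition is also exact on
  # cubics, so both must agree there
  expect_equal(reconstruct_spline(pk2, g)$x,
               stats::spline(tk, cub(tk), xout = g, method = "fmm")$y,
               tolerance = 1e-9)
})

test_that("degenerate spline knot counts collapse to line and parabola", {
  g <- seq(0, 2, by = 0.25)
  expect_equal(reconstruct_spline(data.frame(t = c(0, 2), x = c(0, 4)),
                                  g)$x, 2 * g)
  par3 <- data.frame(t = c(0, 1, 2), x = c(1, 2, 5))
  co <- solve(outer(par3$t, 0:2, `^`), par3$x)  # unique parabola
  expect_equal(reconstruct_spline(par3, g)$x,
               co[1] + co[2] * g + co[3] * g^2, tolerance = 1e-12)
})

test_that("all methods agree on collinear knots", {
  pk <- data.frame(t = c(0, 3, 7, 10), x = 50 + 2 * c(0, 3, 7, 10))
  g <- seq(0, 10, by = 0.5)
  truth <- 50 + 2 * g
  for (m in c("linear", "pchip", "spline"))
    expect_equal(reconstruct(pk, g, m)$x, truth, tolerance = 1e-10)
})

test_that("dispatch, unknown methods and extrapolation contracts", {
  g <- seq(1, 5, by = 0.5)
  expect_identical(reconstruct(knots3, g, "linear"),
                   reconstruct_linear(knots3, g))
  expect_error(reconstruct(knots3, g, "quintic"))
  expect_error(reconstruct_linear(knots3, c(0, 3)), "extrapolation")
  expect_error(reconstruct_spline(knots3, 5.1), "extrapolation")
  expect_error(reconstruct_linear(data.frame(t = 1, x = 70), 1),
               "at least 2")
})
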