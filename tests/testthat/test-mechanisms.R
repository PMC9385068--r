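test_that("normalization maps salient values into [-1, 1]", {
  out <- normalize_values(c(60, 80, 100))
  expect_equal(out$y, c(-0.5, 0, 0.5))
  expect_equal(out$stats$delta_s, 40)
  expect_false(out$degenerate)

  deg <- normalize_values(c(70, 70, 70))
  expect_equal(deg$y, c(0, 0, 0))
  expect_true(deg$degenerate)

  set.seed(5)
  for (i in 1:20) {
    v <- runif(sample(2:50, 1), 40, 140)
    expect_lte(max(abs(normalize_values(v)$y)), 1)
  }
})

test_that("adaptive random value matches the closed form and stays in
          [0, 1]", {
  expect_equal(adaptive_random_value(0.7, 0), 0.5)
  expect_equal(adaptive_random_value(0, 5), 0.5)
  expect_equal(adaptive_random_value(1, log(3)), 0.75)
  expect_error(adaptive_random_value(1.2, 1), "\\[-1, 1\\]")
  expect_error(adaptive_random_value(0.5, -1), ">= 0")

  eps <- seq(0, 20, length.out = 401)
  y <- seq(-1, 1, length.out = 401)
  r <- outer(y, eps, adaptive_random_value)
  expect_gte(min(r), 0)
  expect_lte(max(r), 1)

  # slope factor f(eps): monotone increasing from 0, supremum 1/2
  f <- adaptive_random_value(1, eps) - 0.5
  expect_equal(f[1], 0)
  expect_true(all(diff(f) > 0))
  expect_lt(f[length(f)], 0.5)
})

test_that("Laplace sampler is deterministic under a seed and has the
          closed-form variance", {
  set.seed(99); a <- rlaplace(1000, 3)
  set.seed(99); b <- rlaplace(1000, 3)
  expect_identical(a, b)
  expect_error(rlaplace(10, 0), "scale")

  set.seed(123)
  draws <- rlaplace(1e6, 1)
  expect_equal(var(draws), 2, tolerance = 0.02 / 2)  # 2*lambda^2
  expect_lt(abs(median(draws)), 0.01)
})

test_that("budget allocation splits epsilon equally", {
  expect_equal(allocate_budget(2, 4)$epsilon_i, 0.5)
  expect_equal(allocate_budget(0.5, 1)$epsilon_i, 0.5)
  expect_equal(allocate_budget(1, 3)$epsilon_i, 1 / 3)
  expect_equal(allocate_budget(2, 600)$epsilon_i, 1 / 300)
  expect_error(allocate_budget(1, 0), "p")
  expect_error(allocate_budget(0, 3), "epsilon")
})

test_that("perturbation keeps timestamps, is seed-deterministic, and
          passes through degenerate sensitivity", {
  sal <- data.frame(t = c(1, 40, 90), x = c(80, 100, 120))
  set.seed(7); a <- perturb_adaptive(sal, 1)
  set.seed(7); b <- perturb_adaptive(sal, 1)
  expect_identical(a, b)
  expect_identical(a$t, sal$t)

  flat <- data.frame(t = c(1, 10), x = c(70, 70))
  expect_warning(out <- perturb_adaptive(flat, 1), "sensitivity")
  expect_identical(out$x, flat$x)
  expect_warning(perturb_kim(flat, 1), "sensitivity")

  # noise_factor = 0 reproduces the input exactly
  set.seed(1)
  expect_equal(perturb_adaptive(sal, 1, noise_factor = 0)$x, sal$x)
})

test_that("every mechanism is unbiased (Monte-Carlo)", {
  sal <- data.frame(t = c(1, 40, 90), x = c(80, 100, 120))
  stream <- device_stream(1:20, 80 + (1:20))
  cases <- list(
    list(draw = function() perturb_adaptive(sal, 1)$x[2], truth = 100),
    list(draw = function() perturb_kim(sal, 1)$x[2], truth = 100),
    list(draw = function() perturb_dwork(stream, 1)$x[5], truth = 85)
  )
  set.seed(2024)
  for (cs in cases) {
    xs <- replicate(2e4, cs$draw())
    se <- sd(xs) / sqrt(length(xs))
    expect_lt(abs(mean(xs) - cs$truth), 4 * se)
  }
})

test_that("adaptive noise is never larger in variance than the unweighted
          salient baseline", {
  sal <- data.frame(t = c(1, 40, 60, 90), x = c(80, 95, 105, 120))
  reps <- 4000
  da <- dk <- matrix(0, reps, nrow(sal))
  for (r in seq_len(reps)) {
    set.seed(5000 + r)  # shared draws: paired comparison
    da[r, ] <- perturb_adaptive(sal, 1)$x - sal$x
    set.seed(5000 + r)
    dk[r, ] <- perturb_kim(sal, 1)$x - sal$x
  }
  va <- apply(da, 2, var)
  vk <- apply(dk, 2, var)
  expect_true(all(va <= vk))
  r <- adaptive_random_value(normalize_values(sal$x)$y, 1)
  expect_true(all(va[r < 1] < vk[r < 1]))
})
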