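triple_exp <- function(tt, a, lam)
  a[1] + a[2] * exp(-lam[1] * tt) + a[3] * exp(-lam[2] * tt) +
  a[4] * exp(-lam[3] * tt)

test_that("a constant series fits as pure intercept", {
  f <- fit_triple_exponential(rep(-70, 50), times = 0:49, seed = 1)
  expect_equal(f$a0, -70, tolerance = 1e-6)
  expect_lt(max(abs(c(f$a1, f$a2, f$a3))), 1e-6 * 70 + 1e-6)
})

test_that("well-separated noiseless transients are recovered to within 1%", {
  set.seed(21)
  tt <- seq(0, 180, by = 0.25)
  for (r in 1:8) {
    l1 <- runif(1, 0.005, 0.02)
    lam <- l1 * c(1, runif(1, 5, 8), runif(1, 25, 40))
    a <- c(-90, runif(3, 5, 30) * sample(c(-1, 1), 3, replace = TRUE))
    f <- fit_triple_exponential(triple_exp(tt, a, lam), times = tt, seed = r)
    expect_lt(max(abs(c(f$lambda1, f$lambda2, f$lambda3) - lam) / lam), 0.01)
    expect_lt(max(abs(c(f$a0, f$a1, f$a2, f$a3) - a) / pmax(abs(a), 1)), 0.01)
    expect_true(f$converged)
    expect_true(f$lambda1 < f$lambda2 && f$lambda2 < f$lambda3)
  }
})

test_that("nested single-exponential inputs reach the numerical noise floor", {
  tt <- seq(0, 120, by = 0.2)
  y <- -80 + 35 * exp(-0.04 * tt)
  f <- fit_triple_exponential(y, times = tt, seed = 2)
  expect_lt(f$sse, 1e-8 * var(y) * length(y))
})

test_that("the fit never does worse than the best constant model", {
  set.seed(22)
  tt <- seq(0, 60, by = 0.5)
  for (r in 1:5) {
    y <- -90 + cumsum(rnorm(length(tt)))   # not an exponential at all
    f <- fit_triple_exponential(y, times = tt, seed = r)
    expect_lte(f$sse, sum((y - mean(y))^2) * (1 + 1e-9))
  }
})

test_that("fit accessors are coherent", {
  tt <- seq(0, 90, by = 0.3)
  y <- -85 + 25 * exp(-0.05 * tt) + 10 * exp(-0.6 * tt)
  f <- fit_triple_exponential(y, times = tt, seed = 3)
  expect_named(coef(f), c("a0", "a1", "a2", "a3",
                          "lambda1", "lambda2", "lambda3"))
  expect_equal(fitted(f) + residuals(f), y, tolerance = 1e-9)
  expect_equal(predict(f, newdata = tt), fitted(f), tolerance = 1e-9)
  expect_error(fit_triple_exponential(y[1:5], times = tt[1:5]),
               "at least 10 samples")
})

test_that("time to maximum deflection matches the closed form", {
  k <- 0.05
  tt <- seq(0, 10 / k, by = 0.05)
  y <- -90 - 40 * (1 - exp(-k * tt))
  expect_equal(time_to_max_deflection(y, times = tt), log(20) / k,
               tolerance = 0.02 * log(20) / k)
  # doubling the rate halves the arrival time
  y2 <- -90 - 40 * (1 - exp(-2 * k * tt / 2))  # same curve family, rate 2k
  tt2 <- seq(0, 5 / k, by = 0.05)
  y2 <- -90 - 40 * (1 - exp(-2 * k * tt2))
  expect_equal(time_to_max_deflection(y2, times = tt2),
               time_to_max_deflection(y, times = tt) / 2, tolerance = 0.05)
})

test_that("arrival time ignores offsets and deflection sign", {
  k <- 0.03
  tt <- seq(0, 300, by = 0.2)
  base <- 40 * (1 - exp(-k * tt))
  t0 <- time_to_max_deflection(base, times = tt)
  expect_equal(time_to_max_deflection(base - 200, times = tt), t0)
  expect_equal(time_to_max_deflection(-base, times = tt), t0)
})

test_that("flat trials are flagged as undefined responses", {
  set.seed(5)
  y <- rnorm(200, -90, 1)
  out <- time_to_max_deflection(y, times = seq(0, 39.8, by = 0.2))
  expect_true(is.na(out))
  expect_true(attr(out, "undefined_response"))
})

test_that("delta tip angle is the telescoped end-minus-start change", {
  expect_equal(delta_tip_angle(rep(-90, 10)), 0)
  k <- 0.1
  tt <- seq(0, 100, by = 0.1)
  y <- -90 - 50 * (1 - exp(-k * tt))
  expect_equal(delta_tip_angle(y), -50, tolerance = 0.01)
  expect_equal(delta_tip_angle(y), sum(diff(y)))
  wob <- c(-90, -130, -100)
  expect_equal(delta_tip_angle(wob), -10)
  expect_equal(delta_tip_angle(wob, method = "extremum"), -40)
})
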