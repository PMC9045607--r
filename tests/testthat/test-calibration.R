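test_that("r_squared is the squared Pearson correlation", {
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(-x, x), 1)   # sign-blind by convention
  # construct vectors with exact correlation 0.67
  set.seed(9)
  a <- scale(rnorm(200))[, 1]
  b <- scale(resid(lm(rnorm(200) ~ a)))[, 1]
  y <- 0.67 * a + sqrt(1 - 0.67^2) * b
  expect_equal(r_squared(y, a), 0.4489, tolerance = 1e-6)
  expect_error(r_squared(x, rep(1, 6)), "constant")
  expect_error(r_squared(1:2, 2:3), "at least 3")
})

test_that("the forward model recovers an exactly linear response", {
  set.seed(10)
  n <- 30
  tab <- data.frame(f_acetone = runif(n), f_ethanol = runif(n),
                    initial_angle = rnorm(n, -90, 3))
  beta <- c(5, -40, -15, 0.3)
  tab$delta_theta <- beta[1] + beta[2] * tab$f_acetone +
    beta[3] * tab$f_ethanol + beta[4] * tab$initial_angle
  m <- fit_forward_model(tab)
  expect_equal(m$r2[["delta_theta"]], 1, tolerance = 1e-9)
  expect_equal(unname(coef(m)$delta_theta), beta, tolerance = 1e-6)
  expect_equal(unname(predict(m, tab)), tab$delta_theta, tolerance = 1e-9)
})

test_that("permuted response labels carry no explanatory power on average", {
  set.seed(11)
  n <- 30
  tab <- data.frame(f_acetone = runif(n), f_ethanol = runif(n),
                    initial_angle = rnorm(n, -90, 3))
  tab$delta_theta <- -40 * tab$f_acetone - 15 * tab$f_ethanol + rnorm(n, 0, 2)
  r2s <- vapply(1:100, function(s) {
    perm <- tab
    perm$delta_theta <- withr::with_seed(s, sample(tab$delta_theta))
    fit_forward_model(perm)$r2[["delta_theta"]]
  }, numeric(1))
  expect_lte(mean(r2s), 0.15)
})

test_that("the initial angle never reduces in-sample fit (nesting)", {
  set.seed(12)
  n <- 25
  tab <- data.frame(f_acetone = runif(n), f_ethanol = runif(n),
                    initial_angle = rnorm(n, -90, 3))
  tab$delta_theta <- -30 * tab$f_acetone + rnorm(n, 0, 5)
  with_init <- fit_forward_model(tab, include_initial_angle = TRUE)
  without <- fit_forward_model(tab, include_initial_angle = FALSE)
  expect_gte(with_init$r2[["delta_theta"]], without$r2[["delta_theta"]] - 1e-12)
})

test_that("collinear forward designs fail loudly, naming the features", {
  n <- 12
  tab <- data.frame(f_acetone = runif(n))
  tab$f_ethanol <- 1 - tab$f_acetone
  tab$initial_angle <- -90 + 2 * tab$f_acetone - 2 * (1 - tab$f_ethanol)
  tab$delta_theta <- rnorm(n)
  expect_error(fit_forward_model(tab), "collinear.*initial_angle")
  expect_error(fit_forward_model(tab[1:4, ]), "at least 5 trials")
})

test_that("inverse model recovers composition from single-mode dynamics", {
  # single relaxation mode: the fitted rate features carry the composition
  d <- generate_exposure_design(5, seed = 31)
  p <- generator_params(sigma_theta = 0, frame_rate = 5,
                        mode_weights = c(1, 0, 0))
  s <- simulate_session(d, p)
  segs <- split_trials(s)
  fits <- lapply(segs, fit_triple_exponential, seed = 1)
  tab <- vocbend:::trial_summary(segs, d, fits)
  m <- fit_inverse_model(tab, tab[, c("f_acetone", "f_ethanol")])
  expect_gte(m$r2[["f_acetone"]], 0.9)
  # in-sample nesting of the reduced feature set
  red <- fit_inverse_model(tab, tab[, c("f_acetone", "f_ethanol")],
                           feature_subset = "reduced")
  expect_gte(m$r2[["f_acetone"]], red$r2[["f_acetone"]] - 1e-9)
  expect_gte(m$r2[["f_ethanol"]], red$r2[["f_ethanol"]] - 1e-9)
  expect_equal(m$r2_full_minus_reduced[["f_acetone"]],
               m$r2[["f_acetone"]] - red$r2[["f_acetone"]], tolerance = 1e-9)
})

test_that("under-determined inverse fits are rejected", {
  tab <- data.frame(a0 = rnorm(8), a1 = rnorm(8), a2 = rnorm(8),
                    a3 = rnorm(8), lambda1 = runif(8), lambda2 = runif(8),
                    lambda3 = runif(8), converged = TRUE)
  tg <- data.frame(f_acetone = runif(8), f_ethanol = runif(8))
  expect_error(fit_inverse_model(tab, tg), "under-determined")
  expect_error(fit_inverse_model(tab[1:5, ], tg[1:5, ]), "at least 8")
})

test_that("in-sample fit is invariant to affine feature rescaling", {
  set.seed(13)
  n <- 30
  tab <- data.frame(f_acetone = runif(n), f_ethanol = runif(n),
                    initial_angle = rnorm(n, -90, 3))
  tab$delta_theta <- -30 * tab$f_acetone + 5 * tab$initial_angle + rnorm(n)
  r2_raw <- fit_forward_model(tab)$r2
  tab$initial_angle <- 100 * tab$initial_angle - 7
  expect_equal(fit_forward_model(tab)$r2, r2_raw, tolerance = 1e-9)
})

test_that("hysteresis diagnostic separates drifting and constant series", {
  set.seed(14)
  y <- -90 + 0.5 * (1:30) + rnorm(30, 0, 0.1)
  h <- hysteresis_diagnostic(y)
  expect_equal(h$drift_slope_deg_per_trial, 0.5, tolerance = 0.05)
  hc <- hysteresis_diagnostic(rep(-90, 15))
  expect_equal(hc$drift_slope_deg_per_trial, 0)
  expect_true(hc$undefined)
  expect_true(is.na(hc$lag1_autocorrelation))
  expect_error(hysteresis_diagnostic(rnorm(5)), "at least 10")
})
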