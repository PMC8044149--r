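simulate_var1 <- function(n = 3, t_n = 4000, rho = 0.5, sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(0, n, t_n)
    x[, 1] <- rnorm(n, sd = sd)
    for (t in 2:t_n) x[, t] <- rho * x[, t - 1] + rnorm(n, sd = sd)
  })
  x
}

test_that("OLS recovers VAR(1) coefficients from simulated data", {
  x <- simulate_var1()
  fit <- var_fit_ols(x, 1)
  a1 <- fit$coeffs[[1]]
  expect_true(all(abs(diag(a1) - 0.5) < 0.05))
  expect_true(all(abs(a1[row(a1) != col(a1)]) < 0.05))
  expect_true(all(abs(fit$intercept) < 0.05))
})

test_that("OLS residuals are orthogonal to the lagged design and constants are recovered", {
  x <- simulate_var1(n = 2, t_n = 800, seed = 4)
  fit <- var_fit_ols(x, 2)
  # residual-regressor orthogonality (normal equations)
  rows <- 3:800
  resid <- t(x[, rows]) -
    cbind(1, t(x[, rows - 1]), t(x[, rows - 2])) %*%
      rbind(fit$intercept, t(fit$coeffs[[1]]), t(fit$coeffs[[2]]))
  z <- cbind(1, t(x[, rows - 1]), t(x[, rows - 2]))
  expect_lt(max(abs(crossprod(z, resid))), 1e-8)

  # near-constant series: A ~ 0, intercept ~ the constant
  withr::with_seed(9, {
    const <- matrix(5, 2, 500) + matrix(rnorm(1000, sd = 1e-4), 2, 500)
  })
  cf <- var_fit_ols(const, 1)
  expect_lt(max(abs(cf$coeffs[[1]])), 0.2)
  expect_equal(drop(cf$intercept + cf$coeffs[[1]] %*% c(5, 5)), c(5, 5),
               tolerance = 1e-3)
})

test_that("iterated forecasts match a literal loop oracle", {
  # A1 = I: persistence
  m_id <- structure(list(lag_order = 1L, coeffs = list(diag(3)),
                         intercept = rep(0, 3), method = "ols"),
                    class = "bc_var")
  h <- matrix(rnorm(9), 3, 3)
  expect_equal(var_forecast(m_id, h, 4),
               matrix(h[, 3], 3, 4))
  # A = 0: forecast pins to the intercept
  m_c <- structure(list(lag_order = 2L,
                        coeffs = list(matrix(0, 3, 3), matrix(0, 3, 3)),
                        intercept = c(1, -2, 0.5), method = "ols"),
                   class = "bc_var")
  expect_equal(var_forecast(m_c, h, 3), matrix(c(1, -2, 0.5), 3, 3))

  # random stable model vs an explicit loop
  withr::with_seed(14, {
    a1 <- matrix(rnorm(9, sd = 0.2), 3, 3)
    a2 <- matrix(rnorm(9, sd = 0.1), 3, 3)
    b <- rnorm(3)
    hist <- matrix(rnorm(12), 3, 4)
  })
  m <- structure(list(lag_order = 2L, coeffs = list(a1, a2), intercept = b,
                      method = "ols"), class = "bc_var")
  pred <- var_forecast(m, hist, 5)
  z <- hist
  for (t in 1:5) {
    nxt <- b + a1 %*% z[, ncol(z)] + a2 %*% z[, ncol(z) - 1]
    z <- cbind(z, nxt)
  }
  expect_equal(pred, z[, 5:9], tolerance = 1e-12)

  expect_error(var_forecast(m, hist[, 1, drop = FALSE], 2), "lag order")
})

test_that("stable VAR forecasts approach the unconditional mean", {
  withr::with_seed(15, a1 <- matrix(rnorm(9, sd = 0.15), 3, 3))
  b <- c(0.4, -0.1, 0.2)
  m <- structure(list(lag_order = 1L, coeffs = list(a1), intercept = b,
                      method = "ols"), class = "bc_var")
  mu <- solve(diag(3) - a1, b)
  far <- var_forecast(m, matrix(rnorm(3), 3, 1), 200)
  expect_equal(far[, 200], mu, tolerance = 1e-8)
})

test_that("SGD fit recovers coefficients on the OLS benchmark and is reproducible", {
  x <- simulate_var1()
  ds <- split_samples(windowize(graph_signal(x, 0.72), 4, 4))
  fit <- var_fit_sgd(ds, 1, seed = 2)
  expect_true(all(abs(diag(fit$coeffs[[1]]) - 0.5) < 0.1))
  expect_true(all(abs(fit$coeffs[[1]][row(diag(3)) != col(diag(3))]) < 0.1))

  fit2 <- var_fit_sgd(ds, 1, seed = 2)
  expect_identical(fit$coeffs, fit2$coeffs)

  zero <- var_fit_sgd(ds, 1, epochs = 0)
  expect_true(all(zero$coeffs[[1]] == 0) && all(zero$intercept == 0))
})

test_that("SGD recovers an exact linear system to high precision", {
  # noiseless x(t) = b + A x(t-1), excited by random restarts across
  # sessions; zero iterated-forecast loss is attained only at the truth
  withr::with_seed(16, {
    a1 <- matrix(c(0.5, 0.2, -0.1, 0.4), 2, 2)
    b <- c(0.1, -0.05)
    sessions <- lapply(1:10, function(s) {
      x <- matrix(0, 2, 40)
      x[, 1] <- rnorm(2, sd = 2)
      for (t in 2:40) x[, t] <- b + a1 %*% x[, t - 1]
      graph_signal(x, 0.72)
    })
  })
  ds <- split_samples(windowize(sessions, 3, 3))
  fit <- var_fit_sgd(ds, 1, epochs = 200,
                     decay_epochs = c(80, 120, 150, 170, 186), seed = 3)
  expect_lt(max(abs(fit$coeffs[[1]] - a1)), 1e-6)
  expect_lt(max(abs(fit$intercept - b)), 1e-6)
  # horizon-1 forecast equals the one-step regression prediction
  withr::with_seed(18, h <- matrix(rnorm(2), 2, 1))
  expect_equal(var_forecast(fit, h, 1),
               fit$intercept + fit$coeffs[[1]] %*% h, tolerance = 1e-12)
})

test_that("unit-root screen separates white noise from random walks", {
  withr::with_seed(22, {
    wn_flags <- vapply(1:200, function(i) {
      adf_test(rnorm(1000))$p_value < 0.01
    }, TRUE)
    rw_flags <- vapply(1:100, function(i) {
      adf_test(cumsum(rnorm(1000)))$p_value < 0.01
    }, TRUE)
  })
  expect_gte(mean(wn_flags), 0.95)
  expect_lte(mean(rw_flags), 0.10)
  expect_error(adf_test(rep(1, 100)), "constant")
  expect_error(adf_test(rnorm(10)), "20")
})

test_that("the ADF gate reports per-region flags and the nonstationary fraction", {
  withr::with_seed(23, {
    m <- rbind(rnorm(600), cumsum(rnorm(600)), rnorm(600))
  })
  gate <- adf_gate(graph_signal(m, 0.72, region_labels = c("a", "b", "c")))
  expect_equal(gate$region, c("a", "b", "c"))
  expect_true(gate$stationary[1] && gate$stationary[3])
  expect_false(gate$stationary[2])
  expect_equal(attr(gate, "frac_nonstationary"), 1 / 3)
})
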