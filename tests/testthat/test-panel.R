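test_that("Newey-West at lag 0 equals White's estimator", {
  set.seed(1)
  X <- cbind(1, rnorm(40))
  e <- rnorm(40) * (1 + abs(X[, 2]))
  V0 <- newey_west_vcov(X, e, lag = 0)
  bread <- solve(crossprod(X))
  white <- bread %*% (t(X) %*% diag(e^2) %*% X) %*% bread
  expect_equal(V0, white, tolerance = 1e-12)
})

test_that("Newey-West lag 1 matches the hand-computed Bartlett sum", {
  # single regressor, 4 observations, worked by hand from the definition
  x <- c(1, 2, 3, 4)
  e <- c(0.5, -1, 0.25, 0.75)
  h <- x * e
  S_hand <- sum(h^2) + 2 * (1 - 1 / 2) * sum(h[-4] * h[-1])
  V_hand <- S_hand / sum(x^2)^2
  V <- newey_west_vcov(matrix(x), e, lag = 1)
  expect_equal(V[1, 1], V_hand, tolerance = 1e-12)
  expect_error(newey_west_vcov(matrix(x), e, lag = 4), "lag")
  expect_error(newey_west_vcov(matrix(x), e, lag = -1), "lag")
})

test_that("Newey-West agrees with the sandwich package on a time series", {
  skip_if_not_installed("sandwich")
  set.seed(2)
  n <- 60
  x <- rnorm(n)
  y <- 1 + 2 * x + as.numeric(stats::arima.sim(list(ar = 0.4), n))
  fit <- lm(y ~ x)
  X <- cbind(1, x)
  V_pkg <- newey_west_vcov(X, residuals(fit), lag = 3)
  V_ref <- sandwich::NeweyWest(fit, lag = 3, prewhite = FALSE, adjust = FALSE)
  expect_equal(unname(V_pkg), unname(as.matrix(V_ref)), tolerance = 1e-8)
})

test_that("with iid residuals and large n, HAC approaches the OLS variance", {
  set.seed(3)
  n <- 4000
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  V <- newey_west_vcov(X, e, lag = 3)
  s2 <- sum(e^2) / n
  V_ols <- s2 * solve(crossprod(X))
  expect_equal(V, V_ols, tolerance = 0.08)
})

test_that("zero between-subject variance degenerates to pooled OLS", {
  set.seed(4)
  p <- make_null_panel(n_per_arm = 6, T_len = 15, sd_u = 0)
  # make the between-subject variance exactly zero
  p$value <- p$value - ave(p$value, p$subject_id)
  expect_warning(fit <- fit_random_effects_panel(p), "pooled OLS")
  expect_identical(fit$method, "pooled OLS")
  y <- p$value[order(p$subject_id, p$breath_index)]
  g <- as.numeric(p$group[order(p$subject_id, p$breath_index)] ==
                    sort(unique(p$group))[2])
  ols <- lm(y ~ g)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
})

test_that("the group contrast is unbiased on null panels", {
  set.seed(5)
  est <- replicate(300, {
    p <- make_null_panel(n_per_arm = 8, T_len = 20)
    suppressWarnings(fit_random_effects_panel(p)$coefficients[["group"]])
  })
  # |mean bias| below 0.05 residual SD
  expect_lt(abs(mean(est)), 0.05 * 1)
})

test_that("the panel test detects a 5 mbar offset with AR(1) errors", {
  set.seed(6)
  pv <- replicate(60, {
    p <- make_null_panel(n_per_arm = 18, T_len = 25, delta = 5, phi = 0.5)
    suppressWarnings(fit_random_effects_panel(p)$p_value[["group"]])
  })
  expect_gt(mean(pv < 0.05), 0.8)
})

test_that("panel input validation catches degenerate designs", {
  p <- make_null_panel(n_per_arm = 1, T_len = 10)
  expect_error(fit_random_effects_panel(p), "subjects")
  p2 <- make_null_panel(n_per_arm = 4, T_len = 10)
  p2$group <- "M"
  expect_error(fit_random_effects_panel(p2), "two values")
})

test_that("the ADF screen separates stationary from unit-root series", {
  set.seed(7)
  stat <- adf_screen(as.numeric(stats::arima.sim(list(ar = 0.3), 200)),
                     warn = FALSE)
  expect_true(stat$stationary)
  rw <- cumsum(rnorm(200))
  expect_warning(res <- adf_screen(rw), "unit root")
  expect_false(res$stationary)
})
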