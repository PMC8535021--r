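test_that("identical and negated curves give rho of 1 and -1", {
  set.seed(1)
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(dyncorr_from_matrices(X, X)$rho, 1, tolerance = 1e-12)
  expect_equal(dyncorr_from_matrices(X, -X)$rho, -1, tolerance = 1e-12)
  p <- panel_from_matrices(X, X)
  expect_equal(dynamical_correlation(p, "PIP", "eV_T")$rho, 1,
               tolerance = 1e-12)
})

test_that("a 3-subject toy table matches the brute-force oracle to 1e-10", {
  set.seed(2)
  X <- matrix(rnorm(15), 3, 5)
  Y <- matrix(rnorm(15), 3, 5)
  got <- dynamical_correlation(panel_from_matrices(X, Y), "PIP", "eV_T")
  expect_equal(got$rho, brute_force_dyncorr(X, Y), tolerance = 1e-10)
  expect_identical(got$n_subjects, 3L)
})

test_that("rho is bounded and invariant to positive affine rescaling", {
  set.seed(3)
  for (k in 1:10) {
    X <- matrix(rnorm(6 * 7), 6, 7)
    Y <- matrix(rnorm(6 * 7), 6, 7)
    r <- dyncorr_from_matrices(X, Y)$rho
    expect_gte(r, -1); expect_lte(r, 1)
  }
  X <- matrix(rnorm(6 * 7), 6, 7)
  Y <- matrix(rnorm(6 * 7), 6, 7)
  a <- runif(6, 0.5, 3); b <- rnorm(6)
  r1 <- dyncorr_from_matrices(X, Y)$rho
  r2 <- dyncorr_from_matrices(X * a + b, Y * a + b)$rho
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("zero-variance subjects are excluded with a warning", {
  set.seed(4)
  X <- matrix(rnorm(4 * 5), 4, 5)
  Y <- matrix(rnorm(4 * 5), 4, 5)
  X[1, ] <- 7  # flat curve
  expect_warning(r <- dyncorr_from_matrices(X, Y), "zero-variance")
  expect_identical(length(r$rho_i), 3L)
})

test_that("curves of unequal length are truncated to shared indices", {
  set.seed(5)
  X <- matrix(rnorm(5 * 10), 5, 10)
  Y <- matrix(rnorm(5 * 10), 5, 10)
  p <- panel_from_matrices(X, Y)
  # shorten one subject to 6 indices: everyone is truncated to 6
  p <- p[!(p$subject_id == "s1" & p$breath_index > 6), ]
  got <- dynamical_correlation(p, "PIP", "eV_T")
  expect_identical(got$n_indices, 6L)
  expect_equal(got$rho, brute_force_dyncorr(X[, 1:6], Y[, 1:6]),
               tolerance = 1e-10)
})

test_that("bootstrap inference is deterministic and sane", {
  set.seed(6)
  X <- matrix(rnorm(8 * 10), 8, 10)
  p_perf <- panel_from_matrices(X, 2 * X + 1)
  b1 <- bootstrap_dyncorr(p_perf, "PIP", "eV_T", n_boot = 200, seed = 9)
  b2 <- bootstrap_dyncorr(p_perf, "PIP", "eV_T", n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  # perfectly correlated curves: CI excludes 0, minimal p
  expect_gt(b1$ci_low, 0)
  expect_equal(b1$rho, 1, tolerance = 1e-10)
  expect_lte(b1$p_value, 2 / 200 + 1e-12)
  expect_true(b1$ci_low <= b1$rho && b1$rho <= b1$ci_high)
})

test_that("bootstrap CI covers 0 for independent curves and narrows with subjects", {
  set.seed(7)
  cover <- replicate(60, {
    X <- matrix(rnorm(10 * 8), 10, 8)
    Y <- matrix(rnorm(10 * 8), 10, 8)
    b <- bootstrap_dyncorr(panel_from_matrices(X, Y), "PIP", "eV_T",
                           n_boot = 200, seed = 1)
    b$ci_low <= 0 && 0 <= b$ci_high
  })
  expect_gte(mean(cover), 0.9)

  width <- function(n_sub) {
    X <- matrix(rnorm(n_sub * 8), n_sub, 8)
    Y <- matrix(rnorm(n_sub * 8), n_sub, 8) + 0.5 * X
    b <- bootstrap_dyncorr(panel_from_matrices(X, Y), "PIP", "eV_T",
                           n_boot = 300, seed = 2)
    b$ci_high - b$ci_low
  }
  set.seed(8)
  w10 <- mean(replicate(10, width(10)))
  w40 <- mean(replicate(10, width(40)))
  expect_lt(w40, w10)
})
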