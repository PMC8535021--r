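test_that("median and IQR summarise pooled group values", {
  d <- data.frame(subject_id = "a", breath_index = 1:5, parameter = "PIP",
                  value = c(1, 2, 3, 4, 5), group_label = "MS")
  s <- summarize_median_iqr(d)
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)

  d$value <- 7
  s2 <- summarize_median_iqr(d)
  expect_equal(s2$median, 7)
  expect_equal(s2$iqr, 0)

  expect_error(summarize_median_iqr(d[0, ]), "no values")
})

test_that("LOESS trend reproduces a line exactly and respects the subject floor", {
  # 6 subjects on the same straight line
  p <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(subject_id = paste0("s", i), breath_index = 1:20,
               parameter = "PIP", value = 2 + 0.5 * (1:20))
  }))
  tr <- loess_trend(p, "PIP")
  expect_equal(tr$smoothed_mean, 2 + 0.5 * tr$breath_index, tolerance = 1e-6)

  # indices carried by fewer than 5 subjects are dropped
  p2 <- p[!(p$subject_id %in% c("s1", "s2") & p$breath_index > 10), ]
  tr2 <- loess_trend(p2, "PIP", min_subjects = 5)
  expect_identical(max(tr2$breath_index), 10L)
  expect_true(all(tr2$n_subjects_at_index >= 5))

  expect_error(loess_trend(p[p$breath_index <= 2, ], "PIP"), "fewer than 3")
})

test_that("LOESS trend is invariant to duplicating every data point", {
  set.seed(1)
  p <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(subject_id = paste0("s", i), breath_index = 1:15,
               parameter = "eV_T", value = sin((1:15) / 3) + rnorm(15, 0, 0.1))
  }))
  tr1 <- loess_trend(p, "eV_T")
  tr2 <- loess_trend(rbind(p, p), "eV_T")
  expect_equal(tr1$smoothed_mean, tr2$smoothed_mean, tolerance = 1e-8)
})

test_that("constant data give a constant trend with shrinking standard error", {
  make_const <- function(n_sub) {
    do.call(rbind, lapply(seq_len(n_sub), function(i) {
      data.frame(subject_id = paste0("s", i), breath_index = 1:12,
                 parameter = "PEEP", value = 5)
    }))
  }
  tr <- loess_trend(make_const(6), "PEEP")
  expect_equal(tr$smoothed_mean, rep(5, nrow(tr)), tolerance = 1e-9)
  expect_lt(max(tr$standard_error), 1e-9)
})

test_that("Pearson correlation handles vectors and panel pairs", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1, 2), "at least 2")
})

test_that("leak and eV_T are negatively coupled in simulated manikin data", {
  st <- simulate_study(n_providers = 4, seed = 8)
  m <- lapply(st$manikin, analyze_episode)
  b <- lapply(st$baby_pool, analyze_episode)
  g <- assign_groups(pair_by_duration(m, b), m, b)
  panel <- build_panel_dataset(g)
  # manikin short: no closed-valve run-in, so the leak-formula coupling is
  # undiluted (the S4 pre-aeration phase adds low-eV_T points at any leak)
  mpanel <- panel[panel$group_label == "MS", ]
  expect_lt(pearson_r(mpanel, parameter_x = "leak", parameter_y = "eV_T"),
            -0.4)
})

test_that("chi-square on the 2x2 obstruction table matches the hand formula", {
  # oracle: direct sum of (O - E)^2 / E over the four cells
  hand_chisq <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  got <- chi_square_obstruction(4, 18, 7, 18)
  expect_equal(got$statistic,
               hand_chisq(matrix(c(4, 14, 7, 11), 2, byrow = TRUE)),
               tolerance = 1e-10)
  expect_equal(got$df, 1)

  expect_equal(chi_square_obstruction(5, 18, 5, 18)$statistic, 0)
  # perfect separation of 18 vs 18 gives the maximal statistic, n = 36
  expect_equal(chi_square_obstruction(18, 18, 0, 18)$statistic, 36)
  expect_error(chi_square_obstruction(0, 18, 0, 18), "zero margin")

  # equals the squared two-proportion z statistic
  z <- {
    p1 <- 4 / 18; p2 <- 7 / 18; pp <- 11 / 36
    (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 18 + 1 / 18))
  }
  expect_equal(got$statistic, z^2, tolerance = 1e-10)
})
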