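square_pulse_record <- function(peep = 5, pip = 30, dt = 0.01) {
  # 1 s at PEEP, 0.5 s at PIP, 1 s at PEEP
  p <- c(rep(peep, 100), rep(pip, 50), rep(peep, 100))
  waveform_record((seq_along(p) - 1) * dt, p, rep(0, length(p)))
}

test_that("segmentation finds one window per inflation", {
  # flat trace: no inflations
  flat <- waveform_record(seq(0, 5, 0.01), rep(5, 501), rep(0, 501))
  expect_identical(nrow(segment_breaths(flat)), 0L)
  expect_error(segment_breaths(flat, min_rise = 0), "min_rise")

  expect_identical(nrow(segment_breaths(square_pulse_record())), 1L)

  # simulated S1 at 50/min for 30 s: 25 inflations, matching ground truth
  ep <- simulate_scenario("S1", seed = 61)
  w <- segment_breaths(ep$record)
  expect_identical(nrow(w), 25L)
  expect_identical(nrow(w), nrow(ep$record$truth))
})

test_that("breath count matches ground truth across recipients and scenarios", {
  eps <- list(simulate_scenario("S4", seed = 62),
              simulate_baby_episode(45, seed = 63),
              simulate_baby_episode(90, seed = 64))
  for (ep in eps) {
    expect_identical(nrow(segment_breaths(ep$record)),
                     nrow(ep$record$truth))
  }
})

test_that("PIP and PEEP are read off the waveform", {
  rec <- square_pulse_record()
  w <- segment_breaths(rec)
  pr <- compute_pressures(w[1, ], rec)
  expect_equal(pr$pip, 30)
  expect_equal(pr$peep, 5)
  expect_true(pr$peep_plateau)

  # raised set PIP is recovered from simulation
  ep <- simulate_scenario("S1", seed = 65,
                          settings = resuscitator_settings(set_pip = 35),
                          control = ctl_quiet())
  s <- analyze_episode(ep)
  expect_equal(median(s$breaths$pip), 35, tolerance = 0.5)

  # slow decay that never settles is flagged
  p <- c(rep(5, 50), rep(30, 30), seq(30, 14, length.out = 120))
  dec <- waveform_record((seq_along(p) - 1) * 0.01, p, rep(0, length(p)))
  wd <- segment_breaths(dec)
  expect_false(compute_pressures(wd[1, ], dec)$peep_plateau)
})

test_that("median extracted PIP/PEEP recover the simulated settings", {
  set.seed(66)
  pips <- peeps <- peep_truth <- c()
  for (seed in 71:76) {
    ep <- simulate_scenario("S1", seed = seed)
    s <- analyze_episode(ep)
    pips <- c(pips, s$breaths$pip)
    peeps <- c(peeps, s$breaths$peep)
    peep_truth <- c(peep_truth, ep$record$truth$peep_drive)
  }
  expect_lt(abs(median(pips) - 30), 1)
  expect_lt(abs(median(peeps) - median(peep_truth)), 1)
})

test_that("volume integration is trapezoidal on flow in mL/s", {
  # constant +6 L/min for 0.5 s -> 100 mL/s * 0.5 s = 50 mL
  rec <- waveform_record(seq(0, 0.5, 0.01), rep(10, 51), rep(6000, 51))
  v <- integrate_volumes(list(start = 1, fall = 51, end = 51), rec)
  expect_equal(v$v_t_insp, 50)
  expect_equal(v$v_t_exp, 0)

  # pure sine over a full period: inspired equals expired
  tt <- seq(0, 1.2, 0.01)
  rec2 <- waveform_record(tt, rep(10, length(tt)),
                          3000 * sin(2 * pi * tt / 1.2))
  v2 <- integrate_volumes(list(start = 1, fall = 61, end = length(tt)), rec2)
  expect_equal(v2$v_t_insp, v2$v_t_exp, tolerance = 1e-6)
})

test_that("leak percentage follows the clamped formula", {
  expect_equal(compute_leak(10, 5)$leak_pct, 50)
  expect_equal(compute_leak(10, 10)$leak_pct, 0)
  neg <- compute_leak(10, 12)
  expect_equal(neg$leak_pct, 0)
  expect_identical(neg$flag, "negative_clamped")
  expect_equal(neg$leak_raw, -20)
  und <- compute_leak(0, 0)
  expect_true(is.na(und$leak_pct))
  expect_identical(und$flag, "undefined")
  expect_error(compute_leak(-1, 0), "v_t_insp")
})

test_that("eV_T normalisation divides by weight", {
  expect_equal(normalize_ev_t(11, 3.14), 11 / 3.14)
  expect_equal(normalize_ev_t(15.7, 3.14), 5)
  expect_equal(normalize_ev_t(0, 3.14), 0)
  expect_error(normalize_ev_t(10, 0), "weight")
})

test_that("pauses over 5 s are found and excluded from total PPV time", {
  ep <- simulate_baby_episode(90, seed = 81, pause_after_breath = 30,
                              pause_duration = 10)
  s <- analyze_episode(ep)
  expect_identical(nrow(s$pauses), 1L)
  expect_equal(s$pauses$duration, 10, tolerance = 0.5)
  expect_equal(s$total_ppv_time, 90, tolerance = 2)

  # gaps under the threshold produce no pauses
  s2 <- analyze_episode(simulate_scenario("S1", seed = 82))
  expect_identical(nrow(s2$pauses), 0L)
})

test_that("obstruction calls require sustained low flow at target PIP with typical neighbours", {
  base <- data.frame(index = 1:10, pip = rep(30, 10), ev_t = rep(4, 10))

  three_low <- base; three_low$ev_t[5:7] <- 0.1
  expect_identical(nrow(detect_obstruction(three_low, pip_target = 30)), 1L)

  two_low <- base; two_low$ev_t[5:6] <- 0.1
  expect_identical(nrow(detect_obstruction(two_low, pip_target = 30)), 0L)

  # low flow with collapsed pressure is failed inflation, not obstruction
  collapsed <- base
  collapsed$ev_t[5:7] <- 0.1
  collapsed$pip[5:7] <- 15
  expect_identical(nrow(detect_obstruction(collapsed, pip_target = 30)), 0L)

  # a leading low-flow run (unaerated lung) is not obstruction by default
  leading <- base; leading$ev_t[1:4] <- 0.1
  expect_identical(nrow(detect_obstruction(leading, pip_target = 30)), 0L)
  expect_identical(nrow(detect_obstruction(leading, pip_target = 30,
                                           ignore_leading = FALSE)), 1L)
})

test_that("leak recovery regression over 200 breaths is near identity", {
  set.seed(90)
  fr <- rep(seq(0.1, 0.9, 0.1), length.out = 200)
  ext <- vapply(fr, function(f) {
    rec <- simulate_breath(leak = mask_leak_model(f, 0))
    v <- integrate_volumes(segment_breaths(rec)[1, ], rec)
    compute_leak(v$v_t_insp, v$v_t_exp)$leak_pct
  }, numeric(1))
  co <- coef(lm(ext ~ I(fr * 100)))
  expect_gte(co[[2]], 0.95)
  expect_lte(co[[2]], 1.05)
  expect_gte(co[[1]], -3)
  expect_lte(co[[1]], 3)
})
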