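test_that("constructors validate their invariants", {
  expect_error(resuscitator_settings(set_pip = 4, set_peep = 5), "set_pip")
  expect_error(resuscitator_settings(inspiratory_fraction = 1.2),
               "inspiratory_fraction")
  expect_error(lung_model(resistance = 0), "resistance")
  expect_error(mask_leak_model(mean_leak_fraction = 1), "mean_leak_fraction")
  expect_error(subject_profile("manikin", spontaneous_effort_rate = 3),
               "manikin")
  expect_error(simulate_breath(dt = Inf), "dt")
  expect_error(waveform_record(c(0, 0.1, 0.15), 1:3, 1:3), "uniform")
})

test_that("a long zero-leak breath conserves volume within 2 percent", {
  set.seed(1)
  # C = 1 mL/mbar needs a long expiration to empty; use a slow cycle
  rec <- simulate_breath(resuscitator_settings(inflation_rate = 15),
                         lung_model(compliance = 1),
                         mask_leak_model(0, 0), control = ctl_quiet())
  w <- segment_breaths(rec)
  v <- integrate_volumes(w[1, ], rec)
  expect_gt(v$v_t_insp, 5)
  expect_lt(abs(v$v_t_insp - v$v_t_exp) / v$v_t_insp, 0.02)
})

test_that("closed valve yields target PIP but almost no expired volume", {
  set.seed(2)
  rec <- simulate_breath(lung = lung_model(valve_open = FALSE),
                         leak = mask_leak_model(0, 0), control = ctl_quiet())
  w <- segment_breaths(rec)
  pr <- compute_pressures(w[1, ], rec)
  v <- integrate_volumes(w[1, ], rec)
  expect_gt(pr$pip, 0.95 * 30)
  expect_lt(v$v_t_exp, 1)
})

test_that("injected leak fraction is recovered by the leak formula", {
  set.seed(3)
  for (f in c(0.25, 0.5, 0.75)) {
    rec <- simulate_breath(leak = mask_leak_model(f, 0), control = ctl_quiet())
    w <- segment_breaths(rec)
    v <- integrate_volumes(w[1, ], rec)
    lk <- compute_leak(v$v_t_insp, v$v_t_exp)
    expect_lt(abs(lk$leak_pct - 100 * f), 1.5)
  }
})

test_that("expired volume strictly decreases with injected leak at fixed compliance", {
  ve <- vapply(seq(0.1, 0.9, 0.2), function(f) {
    rec <- simulate_breath(leak = mask_leak_model(f, 0), control = ctl_quiet())
    integrate_volumes(segment_breaths(rec)[1, ], rec)$v_t_exp
  }, numeric(1))
  expect_true(all(diff(ve) < 0))
})

test_that("optimal PPV succeeds at the scenario constant; suboptimal later", {
  s1 <- simulate_scenario("S1", quality = "optimal", seed = 11)
  s4 <- simulate_scenario("S4", quality = "optimal", seed = 12)
  expect_identical(s1$success_time, 30)
  expect_identical(s4$success_time, 90)
  sub <- simulate_scenario("S1", quality = "suboptimal", seed = 13,
                           ineffective_fraction = 0.5)
  expect_gt(sub$success_time, 30)
  expect_error(scenario_spec("S9"))
})

test_that("S4 valve opens abruptly after the adequate-inflation threshold", {
  ep <- simulate_scenario("S4", seed = 14, control = ctl_quiet())
  truth <- ep$record$truth
  thr <- ep$scenario$valve_threshold
  expect_false(any(truth$valve_open[seq_len(thr)]))
  expect_true(all(truth$valve_open[(thr + 1L):nrow(truth)]))
  s <- analyze_episode(ep)
  closed <- s$breaths$ev_t[seq_len(thr)]
  open <- s$breaths$ev_t[(thr + 2L):nrow(s$breaths)]
  expect_lt(max(closed), 1)     # step increase in expired volume
  expect_gt(min(open), 2)
})

test_that("manikin heart rate rises monotonically with effective PPV", {
  ep <- simulate_scenario("S4", seed = 15)
  expect_true(all(diff(ep$heart_rate$heart_rate) >= 0))
  expect_lt(max(ep$heart_rate$heart_rate), 160 + 1e-9)
  expect_equal(ep$heart_rate$heart_rate[1L], 60, tolerance = 5)
})

test_that("baby episodes establish FRC, jitter more than the manikin, and end gradually", {
  bep <- simulate_baby_episode(90, seed = 21)
  s <- analyze_episode(bep)
  b <- s$breaths
  expect_gt(mean(tail(b$ev_t, 20)), mean(head(b$ev_t, 20)))
  expect_gt(median(tail(b$leak_pct, 3)), median(b$leak_pct, na.rm = TRUE))

  mep <- simulate_scenario("S1", seed = 21)
  sm <- analyze_episode(mep)
  bshort <- analyze_episode(simulate_baby_episode(30, seed = 22))
  expect_gt(var(bshort$breaths$pip), var(sm$breaths$pip))

  expect_error(simulate_baby_episode(-5), "duration_target")
  expect_error(simulate_baby_episode(30, profile = subject_profile("manikin")),
               "baby")
})

test_that("episode pressure stays within physical bounds", {
  for (seed in 31:33) {
    ep <- simulate_scenario(sample(c("S1", "S4"), 1), seed = seed)
    expect_gte(min(ep$record$pressure), 0)
    expect_lte(max(ep$record$pressure), 30 + 1)
  }
  bep <- simulate_baby_episode(60, seed = 34)
  expect_gte(min(bep$record$pressure), 0)
  expect_lte(max(bep$record$pressure), 31)
})

test_that("obstruction injection matches the detector contract", {
  ep <- simulate_scenario("S1", seed = 41, control = ctl_quiet())
  s3 <- analyze_episode(inject_obstruction(ep, 10, 3))
  expect_identical(nrow(s3$obstruction_events), 1L)
  expect_identical(s3$obstruction_events$start_index, 10L)
  expect_identical(s3$obstruction_events$end_index, 12L)

  s2 <- analyze_episode(inject_obstruction(ep, 10, 2))
  expect_identical(nrow(s2$obstruction_events), 0L)

  s5 <- analyze_episode(inject_obstruction(ep, 10, 5))
  expect_identical(s5$obstruction_events$start_index, 10L)
  expect_identical(s5$obstruction_events$end_index, 14L)

  expect_error(inject_obstruction(ep, 24, 5), "exceeds")
})

test_that("simulate_study emits the full design with ground truth and determinism", {
  st <- simulate_study(n_providers = 3, seed = 5)
  expect_length(st$manikin, 6)
  expect_length(st$baby_pool, 6)
  # every manikin episode has an unused pool episode within 15 percent
  m_dur <- vapply(st$manikin, function(e) diff(range(e$record$time)), numeric(1))
  b_dur <- vapply(st$baby_pool, function(e) diff(range(e$record$time)), numeric(1))
  for (d in m_dur) expect_true(any(abs(b_dur - d) / d <= 0.15))
  # ground-truth rows equal simulated inflations
  for (e in c(st$manikin, st$baby_pool)) {
    expect_identical(nrow(e$record$truth),
                     nrow(segment_breaths(e$record)))
  }
  st2 <- simulate_study(n_providers = 3, seed = 5)
  expect_identical(st, st2)
  expect_false(identical(st, simulate_study(n_providers = 3, seed = 6)))
})

test_that("episodes survive a CSV/JSON round trip", {
  dir <- withr::local_tempdir()
  ep <- simulate_scenario("S1", seed = 51)
  ep$episode_id <- "M99-S1"
  write_episode(ep, dir)
  back <- read_episode(dir, "M99-S1")
  expect_equal(back$record$pressure, ep$record$pressure, tolerance = 1e-8)
  expect_equal(back$record$flow, ep$record$flow, tolerance = 1e-8)
  expect_identical(back$profile$recipient, "manikin")
  expect_equal(back$success_time, 30)
  s1 <- analyze_episode(ep)
  s2 <- analyze_episode(back)
  expect_equal(s1$breaths$pip, s2$breaths$pip, tolerance = 1e-6)
})
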