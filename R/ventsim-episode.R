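# Episode assembly: a per-breath "plan" (delivered pressures, leak fraction,
# compliance, adequacy, pauses) is drawn first, then rendered into a single
# continuous pressure-flow trace breath by breath, with state (airway
# pressure, residual lung volume) carried across breath boundaries.

# baseline per-breath jitter SDs, scaled by profile$parameter_jitter_scale
# (PIP jitter is one-sided: a T-piece caps delivered pressure at the set PIP,
# so technique/leak losses only pull the achieved PIP down)
JITTER_PIP_SD <- 0.3       # mbar
JITTER_PEEP_SD <- 0.8      # mbar, not scaled: PEEP spread is similar in
                           # manikin and baby ventilation
JITTER_COMPLIANCE_CV <- 0.05

draw_pip <- function(n, set_pip, scale, ineffective = rep(FALSE, n)) {
  base <- ifelse(ineffective, 0.75 * set_pip, set_pip)
  pmax(base - abs(rnorm(n, 0, JITTER_PIP_SD * scale)), set_pip * 0.5)
}

draw_peep <- function(n, set_peep) {
  clamp(set_peep + rnorm(n, 0, JITTER_PEEP_SD), 0.5, set_peep + 2)
}

draw_leak <- function(n, leak) {
  clamp(leak$mean_leak_fraction + leak$drift_per_breath * (seq_len(n) - 1) +
          rnorm(n, 0, leak$per_breath_sd), 0, 0.95)
}

# render a breath plan into a waveform_record (+ heart-rate hook via credit)
synth_from_plan <- function(plan, settings, profile, control,
                            seed = NULL, scenario = NULL) {
  dt <- control$dt
  n <- nrow(plan)
  press <- vector("list", 2L * n)
  flow <- vector("list", 2L * n)
  p0 <- plan$peep_drive[1L]
  v0 <- 0
  t_cursor <- 0
  t_start <- t_end <- numeric(n)
  for (i in seq_len(n)) {
    seg <- sim_breath_core(plan$pip_drive[i], plan$peep_drive[i],
                           plan$leak_fraction[i], plan$compliance[i],
                           plan$t_insp[i], plan$t_exp[i], control,
                           v0 = v0, p0 = p0, noise = TRUE)
    press[[2L * i - 1L]] <- seg$pressure
    flow[[2L * i - 1L]] <- seg$flow
    t_start[i] <- t_cursor
    t_cursor <- t_cursor + length(seg$pressure) * dt
    t_end[i] <- t_cursor
    p0 <- seg$p_end
    v0 <- seg$v_end
    if (plan$pause_after[i] > 0) {
      m <- round(plan$pause_after[i] / dt)
      press[[2L * i]] <- plan$peep_drive[i] +
        rnorm(m, 0, control$pressure_noise_sd)
      flow[[2L * i]] <- rnorm(m, 0, control$flow_noise_sd) * 60
      t_cursor <- t_cursor + m * dt
      p0 <- plan$peep_drive[i]
      v0 <- 0
    }
  }
  pressure <- unlist(press)
  fl <- unlist(flow)
  time <- (seq_along(pressure) - 1L) * dt

  # spontaneous respiratory efforts: short sine-shaped flow artefacts
  if (profile$spontaneous_effort_rate > 0) {
    dur_total <- length(pressure) * dt
    n_eff <- rbinom(1L, max(1L, round(dur_total / 60 * 10)),
                    min(1, profile$spontaneous_effort_rate / 10))
    if (n_eff > 0) {
      for (tt in runif(n_eff, 0, dur_total - 0.3)) {
        idx <- which(time >= tt & time < tt + 0.2)
        if (length(idx) > 1L) {
          amp <- runif(1, 15, 35) * 60  # mL/min
          fl[idx] <- fl[idx] + amp * sin(2 * pi * (time[idx] - tt) / 0.2)
        }
      }
    }
  }

  truth <- data.frame(index = seq_len(n), t_start = t_start, t_end = t_end,
                      leak_fraction = plan$leak_fraction,
                      compliance = plan$compliance,
                      pip_drive = plan$pip_drive,
                      peep_drive = plan$peep_drive,
                      adequate = plan$adequate,
                      obstructed = rep(FALSE, n),
                      valve_open = plan$valve_open,
                      pause_after = plan$pause_after)
  waveform_record(time, pressure, fl,
                  metadata = list(settings = settings, profile = profile,
                                  scenario = scenario, seed = seed,
                                  control = control),
                  truth = truth)
}

#' Simulate a manikin resuscitation scenario
#'
#' Runs one training scenario on the valve-gated manikin lung. The scenario
#' clock credits only adequate inflations (achieved PIP at least 0.9 x set
#' PIP); under optimal PPV, success (baby-cry) is declared at exactly the
#' scenario's required cumulative PPV time (30 s for S1, 90 s for S4).
#' Suboptimal PPV - a stated fraction of inflations made ineffective - earns
#' no credit for those inflations, so success comes later. For S4 the
#' compliance valve opens abruptly once `valve_threshold` adequate inflations
#' have accrued, producing a step increase in expired volume. The manikin's
#' heart rate rises logistically toward 160 bpm with accumulated effective
#' PPV.
#'
#' @param spec A [scenario_spec()] (or a scenario id string).
#' @param profile A [subject_profile()]; must be the manikin for the standard
#'   scenarios.
#' @param settings A [resuscitator_settings()].
#' @param quality `"optimal"` or `"suboptimal"`.
#' @param seed Integer seed; the episode is a deterministic function of
#'   (arguments, seed).
#' @param leak A [mask_leak_model()].
#' @param control A [sim_control()].
#' @param ineffective_fraction Fraction of inflations rendered ineffective
#'   under suboptimal quality (default 0.5).
#' @return An object of class `ppv_episode`: a list with `record`
#'   ([waveform_record()] with ground-truth log), `success_time` (s),
#'   `heart_rate` (per-breath data frame), `scenario`, `profile`, `quality`.
#' @export
#' @examples
#' ep <- simulate_scenario("S1", quality = "optimal", seed = 1)
#' ep$success_time  # 30
simulate_scenario <- function(spec = scenario_spec("S1"),
                              profile = subject_profile("manikin"),
                              settings = resuscitator_settings(),
                              quality = c("optimal", "suboptimal"),
                              seed = 1,
                              leak = mask_leak_model(),
                              control = sim_control(),
                              ineffective_fraction = 0.5) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  quality <- match.arg(quality)
  set.seed(seed)

  rate <- settings$inflation_rate
  cycle <- 60 / rate
  t_insp <- cycle * settings$inspiratory_fraction
  goal <- spec$optimal_ppv_to_success
  n_max <- ceiling(goal / cycle) * 4L + 10L

  ineffective <- if (quality == "suboptimal") {
    runif(n_max) < ineffective_fraction
  } else rep(FALSE, n_max)
  pip_drive <- draw_pip(n_max, settings$set_pip,
                        profile$parameter_jitter_scale, ineffective)
  peep_drive <- draw_peep(n_max, settings$set_peep)
  leak_fraction <- draw_leak(n_max, leak)
  adequate <- pip_drive >= 0.9 * settings$set_pip
  valve_open <- cumsum(c(0, head(adequate, -1L))) >= spec$valve_threshold
  c_jit <- pmax(1 + rnorm(n_max, 0, JITTER_COMPLIANCE_CV *
                            profile$parameter_jitter_scale), 0.1)
  compliance <- ifelse(valve_open, spec$open_compliance * c_jit,
                       control$closed_compliance)

  # continuous credit accrual: success the instant credited PPV reaches goal
  credit_per <- ifelse(adequate, cycle, 0)
  cum_credit <- cumsum(credit_per)
  i_succ <- which(cum_credit >= goal - 1e-9)[1L]
  if (is.na(i_succ)) i_succ <- n_max
  wall_before <- (i_succ - 1L) * cycle
  credit_before <- if (i_succ > 1L) cum_credit[i_succ - 1L] else 0
  success_time <- wall_before + (goal - credit_before)

  n <- i_succ
  plan <- data.frame(index = seq_len(n), pip_drive = pip_drive[1:n],
                     peep_drive = peep_drive[1:n],
                     leak_fraction = leak_fraction[1:n],
                     compliance = compliance[1:n], adequate = adequate[1:n],
                     valve_open = valve_open[1:n],
                     t_insp = t_insp, t_exp = cycle - t_insp,
                     pause_after = 0)
  record <- synth_from_plan(plan, settings, profile, control,
                            seed = seed, scenario = spec)
  sig <- function(cr) 1 / (1 + exp(-(cr - goal / 2) / (goal / 8)))
  hr <- spec$initial_heart_rate + (160 - spec$initial_heart_rate) *
    (sig(cum_credit[1:n]) - sig(0)) / (1 - sig(0))
  structure(list(record = record, success_time = success_time,
                 heart_rate = data.frame(index = seq_len(n),
                                         t_end = record$truth$t_end,
                                         credit_s = cum_credit[1:n],
                                         heart_rate = hr),
                 scenario = spec, profile = profile, settings = settings,
                 quality = quality, seed = seed),
            class = "ppv_episode")
}

#' Simulate a real-newborn ventilation episode
#'
#' Generates a clinical-style PPV episode: effective compliance rises
#' smoothly over roughly the first 20 inflations as functional residual
#' capacity is established, per-breath parameter jitter is several times the
#' manikin's, mask leak is large and variable with a slow downward drift, and
#' (with a gradual end transition) the final inflations show falling
#' delivered PIP/PEEP with a simultaneous rise in leak, as when the mask is
#' held loosely while spontaneous breathing is assessed. Optional spontaneous
#' respiratory efforts are superimposed as brief flow artefacts, and an
#' over-5-s pause may be injected.
#'
#' @param duration_target Target ventilated duration, s (> 0).
#' @param settings A [resuscitator_settings()].
#' @param profile A baby [subject_profile()].
#' @param seed Integer seed.
#' @param leak A [mask_leak_model()] (baby default: mean 0.5, sd 0.28).
#' @param control A [sim_control()].
#' @param frc_k Exponential rate of the compliance ramp per breath; the
#'   default 0.15 puts ~95 percent of the plateau at breath 20.
#' @param plateau_compliance Plateau compliance, mL/mbar (subject-jittered).
#' @param pause_prob Probability of injecting one >5 s pause.
#' @param pause_after_breath,pause_duration Deterministic pause injection
#'   (breath index and duration in s); overrides `pause_prob` when given.
#' @return A `ppv_episode` (with `success_time = NA`).
#' @export
simulate_baby_episode <- function(duration_target,
                                  settings = resuscitator_settings(),
                                  profile = subject_profile("baby"),
                                  seed = 1,
                                  leak = mask_leak_model(0.5, 0.28, -0.002),
                                  control = sim_control(),
                                  frc_k = 0.15,
                                  plateau_compliance = 0.55,
                                  pause_prob = 0.15,
                                  pause_after_breath = NULL,
                                  pause_duration = NULL) {
  if (!is.finite(duration_target) || duration_target <= 0) {
    stop("duration_target must be positive", call. = FALSE)
  }
  if (profile$recipient != "baby") {
    stop("simulate_baby_episode requires a baby profile", call. = FALSE)
  }
  set.seed(seed)
  cycle <- 60 / settings$inflation_rate
  t_insp <- cycle * settings$inspiratory_fraction
  n <- max(3L, round(duration_target / cycle))

  pip_drive <- draw_pip(n, settings$set_pip, profile$parameter_jitter_scale)
  peep_drive <- draw_peep(n, settings$set_peep)
  leak_fraction <- draw_leak(n, leak)
  c_plat <- plateau_compliance * max(1 + rnorm(1, 0, 0.1), 0.3)
  frc0 <- 0.25
  ramp <- frc0 + (1 - frc0) * (1 - exp(-frc_k * (seq_len(n) - 1)))
  c_jit <- pmax(1 + rnorm(n, 0, JITTER_COMPLIANCE_CV *
                            profile$parameter_jitter_scale), 0.1)
  compliance <- c_plat * ramp * c_jit

  if (profile$end_transition == "gradual" && n > 6L) {
    tail_idx <- (n - 2L):n
    fade <- c(0.85, 0.75, 0.65)
    pip_drive[tail_idx] <- settings$set_peep +
      (pip_drive[tail_idx] - settings$set_peep) * fade
    peep_drive[tail_idx] <- pmax(peep_drive[tail_idx] * fade, 0.5)
    leak_fraction[tail_idx] <- clamp(leak_fraction[tail_idx] +
                                       c(0.15, 0.25, 0.35), 0, 0.95)
  }

  pause_after <- numeric(n)
  if (!is.null(pause_after_breath)) {
    stopifnot(pause_after_breath >= 1, pause_after_breath < n)
    pause_after[pause_after_breath] <- pause_duration %||% 8
  } else if (runif(1) < pause_prob && n > 10L) {
    at <- sample(seq(floor(n * 0.2), ceiling(n * 0.8)), 1L)
    pause_after[at] <- runif(1, 6, 12)
  }

  plan <- data.frame(index = seq_len(n), pip_drive = pip_drive,
                     peep_drive = peep_drive, leak_fraction = leak_fraction,
                     compliance = compliance,
                     adequate = pip_drive >= 0.9 * settings$set_pip,
                     valve_open = TRUE,
                     t_insp = t_insp, t_exp = cycle - t_insp,
                     pause_after = pause_after)
  record <- synth_from_plan(plan, settings, profile, control, seed = seed)
  structure(list(record = record, success_time = NA_real_, heart_rate = NULL,
                 scenario = NULL, profile = profile, settings = settings,
                 quality = NA_character_, seed = seed),
            class = "ppv_episode")
}

#' @export
print.ppv_episode <- function(x, ...) {
  cat(sprintf("<ppv_episode> %s, %d inflations, %.1f s%s\n",
              x$profile$recipient, nrow(x$record$truth),
              diff(range(x$record$time)),
              if (is.finite(x$success_time)) {
                sprintf(", success at %.1f s of effective PPV", x$success_time)
              } else ""))
  invisible(x)
}

#' Inject an upper-airway obstruction into a simulated episode
#'
#' Attenuates gas flow to near zero during `n_breaths` consecutive
#' inflations while the pressure waveform is left untouched (target PIP is
#' still achieved), reproducing the flow/volume-disappearance signature of an
#' obstructed upper airway. The ground-truth log is updated so that detector
#' output can be scored against the injection.
#'
#' @param x A `ppv_episode` or a [waveform_record()] carrying a truth log.
#' @param start_breath 1-based index of the first obstructed inflation.
#' @param n_breaths Number of consecutive obstructed inflations (>= 1).
#' @return The modified object, same class as `x`.
#' @export
inject_obstruction <- function(x, start_breath, n_breaths) {
  rec <- if (inherits(x, "ppv_episode")) x$record else x
  stopifnot(inherits(rec, "waveform_record"), !is.null(rec$truth))
  if (n_breaths < 1L) stop("n_breaths must be >= 1", call. = FALSE)
  n <- nrow(rec$truth)
  if (start_breath < 1L || start_breath + n_breaths - 1L > n) {
    stop("obstruction window exceeds episode length", call. = FALSE)
  }
  idx <- start_breath:(start_breath + n_breaths - 1L)
  att <- (rec$metadata$control %||% sim_control())$obstruction_attenuation
  for (i in idx) {
    sel <- rec$time >= rec$truth$t_start[i] & rec$time < rec$truth$t_end[i]
    rec$flow[sel] <- rec$flow[sel] * att
  }
  rec$truth$obstructed[idx] <- TRUE
  if (inherits(x, "ppv_episode")) {
    x$record <- rec
    x
  } else {
    rec
  }
}
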