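# Core single-breath physics.
#
# Airway pressure at the sensor follows a square wave between the delivered
# PEEP and PIP, with short exponential rise/fall at phase switches. The lung
# is a linear RC compartment; its driving pressure amplitude is reduced by a
# droop factor proportional to the leak fraction (pressure loss across a
# leaky mask-face interface), which makes delivered tidal volume strictly
# decrease with leak while the sensor still records set PIP. Leak flow is an
# inspiratory-phase component sized so that the leak formula
# 100 * (V_insp - V_exp) / V_insp recovers the injected fraction.

sim_breath_core <- function(pip_drive, peep_drive, leak_fraction,
                            compliance, t_insp, t_exp, control,
                            v0 = 0, p0 = NULL, noise = TRUE) {
  dt <- control$dt
  R <- control$resistance
  C <- max(compliance, 1e-6)
  f <- clamp(leak_fraction, 0, 0.95)
  p0 <- p0 %||% peep_drive

  n_i <- max(2L, round(t_insp / dt))
  n_e <- max(2L, round(t_exp / dt))
  t_rel <- seq_len(n_i + n_e) * dt

  # sensor (airway) pressure: exponential approach to the set levels
  ti <- seq_len(n_i) * dt
  p_insp <- pip_drive + (p0 - pip_drive) * exp(-ti / control$tau_rise)
  te <- seq_len(n_e) * dt
  p_exp <- peep_drive + (p_insp[n_i] - peep_drive) * exp(-te / control$tau_fall)
  pressure <- c(p_insp, p_exp)

  # lung driving pressure above PEEP, attenuated by leak droop
  x <- (pressure - peep_drive) * (1 - control$droop * f)

  # exact exponential update for piecewise-constant drive over each step
  a <- exp(-dt / (R * C))
  v <- stats::filter(x * C * (1 - a), a, method = "recursive", init = v0)
  v <- as.numeric(v)
  q_lung <- (x - v / C) / R                      # mL/s at the airway opening

  # inspiratory leak flow shaped like the pressure excursion
  v_lung_insp <- trapz_uniform(pmax(q_lung, 0), dt)
  shape <- pmax(pressure - peep_drive, 0)
  shape[(n_i + 1L):(n_i + n_e)] <- 0
  denom <- trapz_uniform(shape, dt)
  v_leak <- if (f > 0) f / (1 - f) * v_lung_insp else 0
  q_leak <- if (denom > 0 && v_leak > 0) shape * (v_leak / denom) else 0 * shape

  q_sensor <- q_lung + q_leak                    # mL/s
  if (noise) {
    pressure <- pressure + rnorm(length(pressure), 0, control$pressure_noise_sd)
    q_sensor <- q_sensor + rnorm(length(q_sensor), 0, control$flow_noise_sd)
  }

  list(time = t_rel, pressure = pressure, flow = q_sensor * 60, # mL/min
       v_end = v[length(v)], p_end = pressure[length(pressure)],
       v_lung_insp = v_lung_insp, v_leak = v_leak)
}

#' Simulate a single inflation-expiration cycle
#'
#' Generates the pressure-flow waveform of one T-piece inflation against a
#' single-compartment RC lung, with a mask-leak fraction drawn from the leak
#' model. With the valve closed (compliance near zero) the pressure waveform
#' still reaches set PIP while almost no volume moves, reproducing the
#' no-chest-rise pattern of the unaerated manikin lung.
#'
#' @param settings A [resuscitator_settings()] object.
#' @param lung A [lung_model()] object.
#' @param leak A [mask_leak_model()] object; the breath's leak fraction is
#'   `mean_leak_fraction + N(0, per_breath_sd)`, clamped to `[0, 0.95]`.
#' @param dt Sampling step in s (default 0.01).
#' @param control A [sim_control()] object (its `dt` is overridden by `dt`).
#' @return A [waveform_record()] covering one cycle, whose `truth` holds the
#'   injected leak fraction, compliance and delivered volumes.
#' @export
#' @examples
#' set.seed(1)
#' br <- simulate_breath(resuscitator_settings(), lung_model(),
#'                       mask_leak_model(0.3, 0))
#' range(br$pressure)
simulate_breath <- function(settings = resuscitator_settings(),
                            lung = lung_model(),
                            leak = mask_leak_model(),
                            dt = 0.01, control = sim_control()) {
  stopifnot(inherits(settings, "resuscitator_settings"),
            inherits(lung, "lung_model"),
            inherits(leak, "mask_leak_model"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  control$dt <- dt
  cycle <- 60 / settings$inflation_rate
  t_insp <- cycle * settings$inspiratory_fraction
  t_exp <- cycle - t_insp
  f <- clamp(leak$mean_leak_fraction + rnorm(1, 0, leak$per_breath_sd), 0, 0.95)
  C <- if (lung$valve_open) {
    lung$compliance * max(lung$frc_established_fraction, 1e-3)
  } else {
    control$closed_compliance
  }
  seg <- sim_breath_core(settings$set_pip, settings$set_peep, f, C,
                         t_insp, t_exp, control)
  truth <- data.frame(index = 1L, t_start = 0, t_end = seg$time[length(seg$time)],
                      leak_fraction = f, compliance = C,
                      pip_drive = settings$set_pip,
                      peep_drive = settings$set_peep,
                      adequate = TRUE, obstructed = FALSE,
                      valve_open = lung$valve_open)
  waveform_record(seg$time, seg$pressure, seg$flow,
                  metadata = list(settings = settings, lung = lung,
                                  leak = leak),
                  truth = truth)
}
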