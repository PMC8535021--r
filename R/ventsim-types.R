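#' T-piece resuscitator settings
#'
#' Settings of a flow-driven T-piece resuscitator (e.g. NeoPuff) delivering a
#' square pressure wave between a set PEEP and a set PIP. Standard delivery-
#' room settings are 8 L/min gas flow, PIP 30 mbar and PEEP 5 mbar; PIP may be
#' increased to 35 mbar. Pressures are stored in mbar (1 mbar = 1.02 cmH2O).
#'
#' @param set_pip Set peak inflating pressure, mbar (default 30, at most 35).
#' @param set_peep Set positive end-expiratory pressure, mbar (default 5).
#' @param gas_flow Circuit gas flow, L/min (default 8).
#' @param inflation_rate Inflations per minute (default 50).
#' @param inspiratory_fraction Fraction of the cycle spent in inspiration,
#'   in (0, 1) (default 0.4).
#' @return An object of class `resuscitator_settings`.
#' @export
#' @examples
#' resuscitator_settings()
resuscitator_settings <- function(set_pip = 30, set_peep = 5, gas_flow = 8,
                                  inflation_rate = 50,
                                  inspiratory_fraction = 0.4) {
  stop_if_not_finite(set_pip = set_pip, set_peep = set_peep,
                     gas_flow = gas_flow, inflation_rate = inflation_rate,
                     inspiratory_fraction = inspiratory_fraction)
  if (!(set_pip > set_peep && set_peep >= 0)) {
    stop("need set_pip > set_peep >= 0", call. = FALSE)
  }
  if (gas_flow <= 0) stop("gas_flow must be positive", call. = FALSE)
  if (inflation_rate <= 0) stop("inflation_rate must be positive", call. = FALSE)
  if (inspiratory_fraction <= 0 || inspiratory_fraction >= 1) {
    stop("inspiratory_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(set_pip = set_pip, set_peep = set_peep, gas_flow = gas_flow,
                 inflation_rate = inflation_rate,
                 inspiratory_fraction = inspiratory_fraction),
            class = "resuscitator_settings")
}

#' Single-compartment lung model
#'
#' Linear resistance-compliance lung. The manikin's low initial compliance is
#' realised by a closed internal valve that opens abruptly after a number of
#' adequate inflations; while closed the effective compliance is near zero, so
#' inflations deliver almost no tidal volume although target PIP is reached.
#'
#' @param compliance Compliance, mL/mbar (>= 0).
#' @param resistance Airway resistance, mbar/(mL/s) (> 0).
#' @param valve_open Is the compliance valve open? (babies: always `TRUE`).
#' @param valve_threshold Number of adequate inflations (PIP >= 0.9 x set PIP)
#'   needed to open the valve.
#' @param frc_established_fraction Fraction of the compliance plateau already
#'   established (functional residual capacity), in `[0, 1]`.
#' @return An object of class `lung_model`.
#' @export
lung_model <- function(compliance = 0.5, resistance = 0.2, valve_open = TRUE,
                       valve_threshold = 0, frc_established_fraction = 1) {
  stop_if_not_finite(compliance = compliance, resistance = resistance,
                     valve_threshold = valve_threshold,
                     frc_established_fraction = frc_established_fraction)
  if (compliance < 0) stop("compliance must be >= 0", call. = FALSE)
  if (resistance <= 0) stop("resistance must be > 0", call. = FALSE)
  if (valve_threshold < 0) stop("valve_threshold must be >= 0", call. = FALSE)
  structure(list(compliance = compliance, resistance = resistance,
                 valve_open = isTRUE(valve_open),
                 valve_threshold = valve_threshold,
                 frc_established_fraction =
                   clamp(frc_established_fraction, 0, 1)),
            class = "lung_model")
}

#' Training scenario specification
#'
#' The manikin offers four scenarios of increasing difficulty. S1 (apnoea,
#' normal compliance, compensated heart rate) requires 30 s of optimal PPV to
#' reach baby-cry; S4 (apnoea, low initial compliance behind a closed valve,
#' decompensated heart rate) requires 90 s. Suboptimal PPV lengthens the
#' scenario. S2 and S3 are configuration stubs with nominal parameters; they
#' are not exercised by the study design.
#'
#' @param scenario_id One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return An object of class `scenario_spec` with fields `scenario_id`,
#'   `initial_compliance` (mL/mbar), `open_compliance` (mL/mbar, compliance
#'   once the valve is open), `initial_heart_rate` (bpm),
#'   `optimal_ppv_to_success` (s), `heart_rate_recovery_rate` (bpm per second
#'   of effective PPV, nominal), and `valve_threshold`.
#' @export
#' @examples
#' scenario_spec("S4")$optimal_ppv_to_success  # 90
scenario_spec <- function(scenario_id = c("S1", "S2", "S3", "S4")) {
  scenario_id <- match.arg(scenario_id)
  tab <- list(
    S1 = list(initial_compliance = 0.50, open_compliance = 0.50,
              initial_heart_rate = 120, optimal_ppv_to_success = 30,
              valve_threshold = 0),
    S2 = list(initial_compliance = 0.40, open_compliance = 0.45,
              initial_heart_rate = 100, optimal_ppv_to_success = 45,
              valve_threshold = 0),
    S3 = list(initial_compliance = 0.25, open_compliance = 0.50,
              initial_heart_rate = 80, optimal_ppv_to_success = 60,
              valve_threshold = 5),
    S4 = list(initial_compliance = 0.012, open_compliance = 0.65,
              initial_heart_rate = 60, optimal_ppv_to_success = 90,
              valve_threshold = 10)
  )
  p <- tab[[scenario_id]]
  structure(c(list(scenario_id = scenario_id), p,
              list(heart_rate_recovery_rate =
                     (160 - p$initial_heart_rate) / p$optimal_ppv_to_success)),
            class = "scenario_spec")
}

#' Mask-leak model
#'
#' Per-breath mask-leak fraction is drawn as
#' `mean + drift * (breath - 1) + N(0, sd)`, clamped to `[0, 0.95]`. A
#' negative drift models leak-reducing mask adjustments over the course of an
#' episode, which is why longer sequences tend toward lower median leak.
#'
#' @param mean_leak_fraction Mean leak fraction in `[0, 1)`.
#' @param per_breath_sd Per-breath standard deviation (>= 0).
#' @param drift_per_breath Additive drift per breath (may be negative).
#' @return An object of class `mask_leak_model`.
#' @export
mask_leak_model <- function(mean_leak_fraction = 0.35, per_breath_sd = 0.25,
                            drift_per_breath = -0.002) {
  stop_if_not_finite(mean_leak_fraction = mean_leak_fraction,
                     per_breath_sd = per_breath_sd,
                     drift_per_breath = drift_per_breath)
  if (mean_leak_fraction < 0 || mean_leak_fraction >= 1) {
    stop("mean_leak_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (per_breath_sd < 0) stop("per_breath_sd must be >= 0", call. = FALSE)
  structure(list(mean_leak_fraction = mean_leak_fraction,
                 per_breath_sd = per_breath_sd,
                 drift_per_breath = drift_per_breath),
            class = "mask_leak_model")
}

#' Ventilated-subject profile
#'
#' Who receives PPV: the manikin (nominal analysis weight 3.14 kg, the median
#' birth weight of the newborns behind its heart-rate algorithm) or a real
#' newborn. Babies carry larger per-breath parameter jitter, occasional
#' spontaneous respiratory efforts, and a gradual end-of-episode transition in
#' which delivered pressures fall while leak rises; the manikin's transition
#' at baby-cry is abrupt.
#'
#' @param recipient `"manikin"` or `"baby"`.
#' @param weight Body weight in kg used for volume normalisation
#'   (manikin default 3.14).
#' @param parameter_jitter_scale Multiplier on baseline per-breath jitter
#'   (manikin 1, baby larger).
#' @param spontaneous_effort_rate Spontaneous-effort events per minute
#'   (must be 0 for the manikin).
#' @param end_transition `"abrupt"` or `"gradual"` (manikin must be abrupt).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(recipient = c("manikin", "baby"),
                            weight = NULL,
                            parameter_jitter_scale = NULL,
                            spontaneous_effort_rate = NULL,
                            end_transition = NULL) {
  recipient <- match.arg(recipient)
  if (recipient == "manikin") {
    weight <- weight %||% 3.14
    parameter_jitter_scale <- parameter_jitter_scale %||% 1
    spontaneous_effort_rate <- spontaneous_effort_rate %||% 0
    end_transition <- end_transition %||% "abrupt"
    if (spontaneous_effort_rate != 0 || end_transition != "abrupt") {
      stop("manikin profile requires spontaneous_effort_rate = 0 and an abrupt end transition",
           call. = FALSE)
    }
  } else {
    weight <- weight %||% 3.5
    parameter_jitter_scale <- parameter_jitter_scale %||% 5
    spontaneous_effort_rate <- spontaneous_effort_rate %||% 2
    end_transition <- end_transition %||% "gradual"
  }
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0", call. = FALSE)
  structure(list(recipient = recipient, weight = weight,
                 parameter_jitter_scale = parameter_jitter_scale,
                 spontaneous_effort_rate = spontaneous_effort_rate,
                 end_transition = match.arg(end_transition,
                                            c("abrupt", "gradual"))),
            class = "subject_profile")
}

#' Simulator numerical controls
#'
#' Numerical and noise parameters shared by all waveform generators.
#'
#' @param dt Sampling step, s (default 0.01, i.e. 100 Hz; must be <= 0.01 so
#'   trapezoidal integration error stays below 1 percent).
#' @param tau_rise,tau_fall Time constants (s) of the airway-pressure approach
#'   to set PIP / set PEEP at phase switches.
#' @param resistance Airway resistance, mbar/(mL/s).
#' @param droop Fractional loss of lung-driving pressure amplitude per unit
#'   leak fraction (mask-to-pharynx pressure loss at a leaky seal); airway
#'   pressure measured at the sensor still reaches set PIP.
#' @param closed_compliance Effective compliance of the closed manikin valve,
#'   mL/mbar.
#' @param pressure_noise_sd Gaussian sensor noise on pressure, mbar.
#' @param flow_noise_sd Gaussian sensor noise on flow, mL/s.
#' @param obstruction_attenuation Multiplier applied to flow during an
#'   injected airway obstruction.
#' @return An object of class `sim_control`.
#' @export
sim_control <- function(dt = 0.01, tau_rise = 0.035, tau_fall = 0.05,
                        resistance = 0.2, droop = 0.5,
                        closed_compliance = 0.012,
                        pressure_noise_sd = 0.1, flow_noise_sd = 1.5,
                        obstruction_attenuation = 0.02) {
  if (dt <= 0 || dt > 0.01 + 1e-12) {
    stop("dt must be positive and at most 0.01 s (>= 100 Hz sampling)", call. = FALSE)
  }
  structure(list(dt = dt, tau_rise = tau_rise, tau_fall = tau_fall,
                 resistance = resistance, droop = droop,
                 closed_compliance = closed_compliance,
                 pressure_noise_sd = pressure_noise_sd,
                 flow_noise_sd = flow_noise_sd,
                 obstruction_attenuation = obstruction_attenuation),
            class = "sim_control")
}

#' Construct a waveform record
#'
#' A sampled airway pressure-gas flow trace of one ventilation episode, as a
#' respiratory function monitor at the mask would record it. Flow is stored in
#' mL/min with positive values indicating flow toward the recipient.
#'
#' @param time Strictly increasing, uniformly spaced time stamps, s.
#' @param pressure Airway pressure per sample, mbar.
#' @param flow Gas flow per sample, mL/min.
#' @param metadata Named list (subject profile, settings, scenario, seed, ...).
#' @param truth Optional per-breath ground-truth data frame (simulator log).
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(time, pressure, flow, metadata = list(),
                            truth = NULL) {
  if (length(time) != length(pressure) || length(time) != length(flow)) {
    stop("time, pressure and flow must have equal length", call. = FALSE)
  }
  if (length(time) >= 2L) {
    steps <- diff(time)
    if (any(steps <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (max(steps) - min(steps) > 1e-6) {
      stop("time must lie on a uniform grid", call. = FALSE)
    }
    if (steps[1L] > 0.01 + 1e-9) {
      stop("grid step must be at most 10 ms", call. = FALSE)
    }
  }
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 flow = as.numeric(flow), metadata = metadata, truth = truth),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  dur <- if (length(x$time)) diff(range(x$time)) else 0
  cat(sprintf("<waveform_record> %.1f s @ %.0f Hz, %d samples\n",
              dur, 1 / (x$time[2L] - x$time[1L]), length(x$time)))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth: %d breaths\n", nrow(x$truth)))
  }
  invisible(x)
}
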