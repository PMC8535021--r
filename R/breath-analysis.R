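# Measurement pipeline: waveform -> per-inflation parameters -> sequence.
# Mirrors what a respiratory function monitor reports per inflation: PIP,
# PEEP, inspired/expired tidal volume (flow integrated over time), mask leak
# percent, plus pause exclusion and upper-airway obstruction calls.

#' Segment a waveform into inflation windows
#'
#' An inflation window starts where airway pressure rises above the baseline
#' PEEP estimate by at least `min_rise` and runs until the onset of the next
#' inflation (or the end of the trace), so each window contains one
#' inspiration and the following expiration.
#'
#' @param record A [waveform_record()].
#' @param min_rise Minimum pressure rise above baseline to call an
#'   inflation, mbar (> 0, default 5).
#' @param min_samples Minimum number of consecutive supra-threshold samples
#'   (noise guard, default 3).
#' @return A data frame with one row per inflation: sample indices `start`,
#'   `fall` (end of the supra-threshold segment) and `end`, plus times
#'   `t_start`, `t_end`. Zero rows for a flat or empty trace.
#' @export
#' @examples
#' rec <- simulate_breath(leak = mask_leak_model(0, 0))
#' nrow(segment_breaths(rec))  # 1
segment_breaths <- function(record, min_rise = 5, min_samples = 3L) {
  stopifnot(inherits(record, "waveform_record"))
  if (min_rise <= 0) stop("min_rise must be > 0", call. = FALSE)
  p <- record$pressure
  empty <- data.frame(start = integer(), fall = integer(), end = integer(),
                      t_start = numeric(), t_end = numeric())
  if (length(p) < 2L) return(empty)
  peep_est <- as.numeric(quantile(p, 0.1, names = FALSE))
  thr <- peep_est + min_rise
  above <- p > thr
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_samples
  on <- starts[keep]
  off <- ends[keep]
  if (!length(on)) return(empty)

  n <- length(p)
  win_end <- c(on[-1L] - 1L, n)
  # back the onset up a few samples to catch the first instants of the rise
  win_start <- pmax(c(1L, win_end[-length(win_end)] + 1L), on - 5L)
  data.frame(start = win_start, fall = off, end = win_end,
             t_start = record$time[win_start], t_end = record$time[win_end])
}

#' Extract PIP and PEEP from one inflation window
#'
#' PIP is the maximum airway pressure in the window. PEEP is the expiratory
#' plateau, estimated as the median pressure over the last `tail_frac` of the
#' expiratory segment; if that segment has not settled into a plateau the
#' value is flagged.
#'
#' @param window One row of [segment_breaths()] output (list or data frame
#'   row with `start`, `fall`, `end`).
#' @param record The [waveform_record()].
#' @param tail_frac Fraction of the expiratory segment used for the PEEP
#'   plateau (default 0.2).
#' @return List with `pip`, `peep` (mbar) and logical `peep_plateau`.
#' @export
compute_pressures <- function(window, record, tail_frac = 0.2) {
  i1 <- window$start; i2 <- window$end; ifall <- window$fall
  if (length(i1) != 1L || i2 < i1) stop("invalid window", call. = FALSE)
  p <- record$pressure
  pip <- max(p[i1:i2])
  exp_seg <- p[min(ifall + 1L, i2):i2]
  m <- length(exp_seg)
  if (m < 5L) {
    return(list(pip = pip, peep = p[i2], peep_plateau = FALSE))
  }
  k <- max(3L, ceiling(tail_frac * m))
  tail_seg <- exp_seg[(m - k + 1L):m]
  prev_seg <- exp_seg[max(1L, m - 2L * k + 1L):(m - k)]
  peep <- median(tail_seg)
  plateau <- abs(peep - median(prev_seg)) < 0.5
  list(pip = pip, peep = peep, peep_plateau = plateau)
}

#' Integrate inspired and expired tidal volume from flow
#'
#' Tidal volume is flow integrated over time: the inspired volume is the
#' trapezoidal integral of positive flow (mL/min converted to mL/s), the
#' expired volume the absolute integral of negative flow.
#'
#' @param window One row of [segment_breaths()] output.
#' @param record The [waveform_record()] (uniform grid required).
#' @return List with `v_t_insp` and `v_t_exp` in mL.
#' @export
#' @examples
#' # constant +6 L/min for 0.5 s is 100 mL/s * 0.5 s = 50 mL
#' rec <- waveform_record(seq(0, 0.5, 0.01), rep(5, 51), rep(6000, 51))
#' integrate_volumes(list(start = 1, fall = 51, end = 51), rec)$v_t_insp
integrate_volumes <- function(window, record) {
  stopifnot(inherits(record, "waveform_record"))
  idx <- window$start:window$end
  tt <- record$time[idx]
  if (length(tt) >= 3L && (max(diff(tt)) - min(diff(tt))) > 1e-6) {
    stop("non-uniform time grid", call. = FALSE)
  }
  dt <- if (length(tt) >= 2L) tt[2L] - tt[1L] else 0
  q <- record$flow[idx] / 60  # mL/min -> mL/s
  list(v_t_insp = trapz_uniform(pmax(q, 0), dt),
       v_t_exp = trapz_uniform(-pmin(q, 0), dt))
}

#' Mask leak percentage
#'
#' `100 * (v_t_insp - v_t_exp) / v_t_insp`, clamped to `[0, 100]`. Expired
#' volume exceeding inspired volume (possible with spontaneous efforts)
#' clamps to 0 with a flag; zero inspired volume yields a flagged missing
#' value rather than an error. The unclamped value is retained for
#' diagnostics.
#'
#' @param v_t_insp,v_t_exp Inspired and expired volumes, mL (`v_t_insp >= 0`).
#' @return List with `leak_pct`, `leak_raw` and `flag` (one of `"ok"`,
#'   `"negative_clamped"`, `"undefined"`).
#' @export
#' @examples
#' compute_leak(10, 5)$leak_pct   # 50
#' compute_leak(10, 12)$flag      # clamped
compute_leak <- function(v_t_insp, v_t_exp) {
  if (!is.finite(v_t_insp) || v_t_insp < 0) {
    stop("v_t_insp must be finite and >= 0", call. = FALSE)
  }
  if (v_t_insp == 0) {
    return(list(leak_pct = NA_real_, leak_raw = NA_real_, flag = "undefined"))
  }
  raw <- 100 * (v_t_insp - v_t_exp) / v_t_insp
  list(leak_pct = clamp(raw, 0, 100), leak_raw = raw,
       flag = if (raw < 0) "negative_clamped" else "ok")
}

#' Weight-normalised expired tidal volume
#'
#' @param v_t_exp Expired volume, mL.
#' @param weight Body weight, kg (> 0); manikin episodes use 3.14 kg, the
#'   median birth weight of the newborns behind the manikin's heart-rate
#'   algorithm.
#' @return eV_T in mL/kg.
#' @export
#' @examples
#' normalize_ev_t(15.7, 3.14)  # 5
normalize_ev_t <- function(v_t_exp, weight) {
  if (!all(is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be > 0", call. = FALSE)
  }
  v_t_exp / weight
}

#' Detect ventilation pauses longer than 5 s
#'
#' A pause is an onset-to-onset gap between consecutive inflations exceeding
#' the typical cycle time by more than `threshold` seconds; its duration is
#' the excess over the typical cycle.
#'
#' @param record The [waveform_record()].
#' @param windows Output of [segment_breaths()].
#' @param threshold Pause threshold, s (default 5).
#' @return Data frame with `t_start`, `t_end`, `duration` per pause.
#' @export
detect_pauses <- function(record, windows, threshold = 5) {
  empty <- data.frame(t_start = numeric(), t_end = numeric(),
                      duration = numeric())
  if (nrow(windows) < 2L) return(empty)
  t_on <- windows$t_start
  gaps <- diff(t_on)
  cycle_typ <- median(gaps)
  is_pause <- (gaps - cycle_typ) > threshold
  if (!any(is_pause)) return(empty)
  i <- which(is_pause)
  data.frame(t_start = t_on[i] + cycle_typ, t_end = t_on[i + 1L],
             duration = gaps[i] - cycle_typ)
}

#' Detect upper-airway obstruction
#'
#' An obstruction window is three or more consecutive inflations with
#' minimal expired volume (eV_T below `flow_floor`) despite achieving target
#' PIP (at least `pip_tol` times `pip_target`), where at least one adjacent
#' non-window inflation achieved an eV_T typical of the sequence (at least
#' half the sequence median). Maximal windows are reported. A qualifying run
#' that starts at the very first inflation is, by default, attributed to the
#' not-yet-aerated lung (the manikin's closed valve) rather than obstruction,
#' because no preceding typical inflation exists.
#'
#' @param breaths Breath table (as built by [assemble_sequence()]) or a
#'   `ventilation_sequence`.
#' @param flow_floor "Minimal" eV_T threshold, mL/kg (default 1).
#' @param pip_target Target PIP, mbar (default: the set PIP).
#' @param pip_tol Fraction of target PIP that must be reached (default 0.9).
#' @param adjacency_frac Fraction of the sequence median eV_T an adjacent
#'   inflation must reach (default 0.5).
#' @param ignore_leading Drop a qualifying run starting at inflation 1.
#' @return Data frame with `start_index`, `end_index`, `n_breaths`.
#' @export
detect_obstruction <- function(breaths, flow_floor = 1, pip_target = 30,
                               pip_tol = 0.9, adjacency_frac = 0.5,
                               ignore_leading = TRUE) {
  if (inherits(breaths, "ventilation_sequence")) breaths <- breaths$breaths
  empty <- data.frame(start_index = integer(), end_index = integer(),
                      n_breaths = integer())
  n <- nrow(breaths)
  if (n < 3L) return(empty)
  low <- breaths$ev_t < flow_floor & breaths$pip >= pip_tol * pip_target
  med_evt <- median(breaths$ev_t, na.rm = TRUE)
  typical <- breaths$ev_t >= adjacency_frac * med_evt

  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  out <- empty
  for (k in which(keep)) {
    s <- starts[k]; e <- ends[k]
    if (ignore_leading && s == 1L) next
    adj_ok <- (s > 1L && typical[s - 1L]) || (e < n && typical[e + 1L])
    if (adj_ok) {
      out <- rbind(out, data.frame(start_index = s, end_index = e,
                                   n_breaths = e - s + 1L))
    }
  }
  out
}

#' Assemble a ventilation sequence from a waveform
#'
#' Runs segmentation, pressure and volume extraction, leak computation,
#' pause exclusion and obstruction detection, yielding the per-episode
#' object all downstream statistics operate on. Total PPV time is the
#' ventilated span minus all pauses over 5 s.
#'
#' @param record A [waveform_record()].
#' @param weight Weight in kg for eV_T normalisation.
#' @param pip_target Target PIP (mbar) for the obstruction rule.
#' @param episode_id,recipient Identifiers carried through to statistics.
#' @param min_rise Segmentation threshold, mbar.
#' @param flow_floor Obstruction eV_T floor, mL/kg.
#' @param ... Further arguments passed to [detect_obstruction()].
#' @return An object of class `ventilation_sequence`: list with `breaths`
#'   (one row per inflation), `pauses`, `total_ppv_time`,
#'   `obstruction_events`, `episode_id`, `recipient`, `weight`,
#'   `duration_class` (filled by [assign_groups()]).
#' @export
assemble_sequence <- function(record, weight, pip_target = 30,
                              episode_id = NULL, recipient = NULL,
                              min_rise = 5, flow_floor = 1, ...) {
  windows <- segment_breaths(record, min_rise = min_rise)
  n <- nrow(windows)
  if (n == 0L) {
    breaths <- data.frame(index = integer(), t_start = numeric(),
                          t_end = numeric(), pip = numeric(),
                          peep = numeric(), peep_plateau = logical(),
                          v_t_insp = numeric(), v_t_exp = numeric(),
                          ev_t = numeric(), leak_pct = numeric(),
                          leak_raw = numeric(), leak_flag = character(),
                          obstructed = logical(),
                          reached_target_pip = logical())
    return(structure(list(episode_id = episode_id, recipient = recipient,
                          breaths = breaths, pauses = detect_pauses(record, windows),
                          total_ppv_time = 0, duration_class = NA_character_,
                          obstruction_events = detect_obstruction(breaths),
                          weight = weight, pip_target = pip_target),
                     class = "ventilation_sequence"))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- windows[i, ]
    pr <- compute_pressures(w, record)
    vol <- integrate_volumes(w, record)
    lk <- compute_leak(vol$v_t_insp, vol$v_t_exp)
    rows[[i]] <- data.frame(
      index = i, t_start = w$t_start, t_end = w$t_end,
      pip = pr$pip, peep = pr$peep, peep_plateau = pr$peep_plateau,
      v_t_insp = vol$v_t_insp, v_t_exp = vol$v_t_exp,
      ev_t = normalize_ev_t(vol$v_t_exp, weight),
      leak_pct = lk$leak_pct, leak_raw = lk$leak_raw, leak_flag = lk$flag,
      obstructed = FALSE,
      reached_target_pip = pr$pip >= 0.9 * pip_target)
  }
  breaths <- do.call(rbind, rows)
  pauses <- detect_pauses(record, windows)
  span <- windows$t_end[n] - windows$t_start[1L]
  total_ppv <- span - sum(pauses$duration)
  obs <- detect_obstruction(breaths, flow_floor = flow_floor,
                            pip_target = pip_target, ...)
  if (nrow(obs)) {
    for (k in seq_len(nrow(obs))) {
      breaths$obstructed[obs$start_index[k]:obs$end_index[k]] <- TRUE
    }
  }
  structure(list(episode_id = episode_id, recipient = recipient,
                 breaths = breaths, pauses = pauses,
                 total_ppv_time = total_ppv,
                 duration_class = NA_character_,
                 obstruction_events = obs,
                 weight = weight, pip_target = pip_target),
            class = "ventilation_sequence")
}

#' Analyze a simulated or recorded episode
#'
#' Convenience wrapper: pulls weight, set PIP and episode identity from the
#' episode metadata and calls [assemble_sequence()].
#'
#' @param x A `ppv_episode` or [waveform_record()].
#' @param weight,pip_target Overrides for the metadata defaults.
#' @param ... Passed to [assemble_sequence()].
#' @return A `ventilation_sequence`.
#' @export
#' @examples
#' \donttest{
#' ep <- simulate_scenario("S1", seed = 1)
#' seq1 <- analyze_episode(ep)
#' median(seq1$breaths$pip)
#' }
analyze_episode <- function(x, weight = NULL, pip_target = NULL, ...) {
  rec <- if (inherits(x, "ppv_episode")) x$record else x
  stopifnot(inherits(rec, "waveform_record"))
  md <- rec$metadata
  weight <- weight %||% md$profile$weight %||% 3.14
  pip_target <- pip_target %||% md$settings$set_pip %||% 30
  episode_id <- if (inherits(x, "ppv_episode")) x$episode_id else NULL
  recipient <- md$profile$recipient %||% NA_character_
  assemble_sequence(rec, weight = weight, pip_target = pip_target,
                    episode_id = episode_id, recipient = recipient, ...)
}

#' @export
print.ventilation_sequence <- function(x, ...) {
  cat(sprintf("<ventilation_sequence> %s (%s): %d inflations, %.1f s PPV, %d pause(s), %d obstruction window(s)\n",
              x$episode_id %||% "?", x$recipient %||% "?",
              nrow(x$breaths), x$total_ppv_time, nrow(x$pauses),
              nrow(x$obstruction_events)))
  invisible(x)
}
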