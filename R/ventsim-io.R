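#' Write a simulated episode to disk
#'
#' Writes the waveform as CSV (`<id>.csv` with columns
#' `time_s,pressure_mbar,flow_ml_min`), a sidecar metadata JSON
#' (`<id>_meta.json`: recipient, weight, scenario, settings, seed) and, when
#' present, the ground-truth per-breath log (`<id>_truth.csv`).
#'
#' @param episode A `ppv_episode`.
#' @param dir Output directory (created if needed).
#' @param id Episode id; defaults to `episode$episode_id`.
#' @return Invisibly, the path of the waveform CSV.
#' @export
write_episode <- function(episode, dir, id = NULL) {
  stopifnot(inherits(episode, "ppv_episode"))
  id <- id %||% episode$episode_id %||% "episode"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- episode$record
  wf <- data.frame(time_s = rec$time, pressure_mbar = rec$pressure,
                   flow_ml_min = rec$flow)
  csv <- file.path(dir, paste0(id, ".csv"))
  write.csv(wf, csv, row.names = FALSE)
  meta <- list(
    episode_id = id,
    recipient = episode$profile$recipient,
    weight_kg = episode$profile$weight,
    scenario = if (!is.null(episode$scenario)) episode$scenario$scenario_id,
    settings = unclass(episode$settings),
    quality = episode$quality,
    seed = episode$seed,
    success_time_s = episode$success_time,
    truth_file = if (!is.null(rec$truth)) paste0(id, "_truth.csv")
  )
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(rec$truth)) {
    write.csv(rec$truth, file.path(dir, paste0(id, "_truth.csv")),
              row.names = FALSE)
  }
  invisible(csv)
}

#' Read an episode written by [write_episode()]
#'
#' @param dir Directory holding the files.
#' @param id Episode id (basename without extension).
#' @return A `ppv_episode` (without heart-rate series).
#' @export
read_episode <- function(dir, id) {
  wf <- read.csv(file.path(dir, paste0(id, ".csv")))
  meta_path <- file.path(dir, paste0(id, "_meta.json"))
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  truth <- NULL
  if (!is.null(meta$truth_file) &&
      file.exists(file.path(dir, meta$truth_file))) {
    truth <- read.csv(file.path(dir, meta$truth_file))
  }
  s <- meta$settings
  settings <- if (!is.null(s)) {
    resuscitator_settings(s$set_pip, s$set_peep, s$gas_flow,
                          s$inflation_rate, s$inspiratory_fraction)
  } else resuscitator_settings()
  recipient <- meta$recipient %||% "manikin"
  profile <- subject_profile(recipient, weight = meta$weight_kg)
  record <- waveform_record(wf$time_s, wf$pressure_mbar, wf$flow_ml_min,
                            metadata = list(settings = settings,
                                            profile = profile,
                                            seed = meta$seed),
                            truth = truth)
  structure(list(record = record,
                 success_time = meta$success_time_s %||% NA_real_,
                 heart_rate = NULL,
                 scenario = if (!is.null(meta$scenario)) scenario_spec(meta$scenario),
                 profile = profile, settings = settings,
                 quality = meta$quality %||% NA_character_,
                 seed = meta$seed, episode_id = meta$episode_id %||% id),
            class = "ppv_episode")
}
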