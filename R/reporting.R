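# End-to-end orchestration: simulate -> analyze -> pair -> stats, emitting a
# reproduction report (tables, trend curves, figures, manifest) under a run
# directory. Figures are artifacts only; every asserted number traces to a
# CSV.

#' Default run configuration
#'
#' @param seed Master seed for the run.
#' @param n_providers Providers (and sequences per group), default 18.
#' @param out_dir Output directory.
#' @param n_boot Bootstrap samples for dynamical correlation (default 1000).
#' @param tolerance Pairing duration tolerance (default 0.15).
#' @param make_figures Write PNG figures (default `TRUE`).
#' @param ... Overrides stored verbatim in the config (e.g. `settings`,
#'   `control`, `flow_floor`, `min_rise`).
#' @return A named list of class `run_config`, fully JSON-serialisable
#'   (object-valued entries are unclassed on save).
#' @export
default_run_config <- function(seed = 1, n_providers = 18,
                               out_dir = file.path(tempdir(), "venticomp_run"),
                               n_boot = 1000, tolerance = 0.15,
                               make_figures = TRUE, ...) {
  structure(list(seed = seed, n_providers = n_providers, out_dir = out_dir,
                 n_boot = n_boot, tolerance = tolerance,
                 make_figures = make_figures, ...),
            class = "run_config")
}

analyze_study <- function(study, ...) {
  list(manikin = lapply(study$manikin, analyze_episode, ...),
       baby = lapply(study$baby_pool, analyze_episode, ...))
}

seq_breath_table <- function(seqs) {
  do.call(rbind, lapply(seqs, function(s) {
    if (!nrow(s$breaths)) return(NULL)
    cbind(episode_id = s$episode_id, recipient = s$recipient, s$breaths)
  }))
}

#' Run the full synthetic study end to end
#'
#' Simulates the study design (n providers x {S1, S4} manikin scenarios plus
#' a duration-matched pool of baby episodes), extracts per-inflation
#' parameters from every waveform, pairs and groups the sequences, and
#' computes the statistical comparison: per-group median/IQR, random-effects
#' panel contrasts (M vs B, short and long separately) with Newey-West
#' variance, LOESS trend curves, dynamical and Pearson correlations for the
#' PIP/eV_T/leak pairs per group, and the chi-square comparison of
#' obstruction occurrence. All tables are written as CSV/JSON under
#' `config$out_dir` together with a provenance manifest; the numeric results
#' are also returned.
#'
#' @param config A [default_run_config()] list.
#' @return Invisibly, a list with `groups`, `pairs`, `summary_table`,
#'   `panel_tests`, `correlations`, `trends`, `obstruction`, `counts`,
#'   `out_dir`.
#' @export
#' @examples
#' \donttest{
#' res <- run_full_study(default_run_config(seed = 1, n_providers = 3,
#'                                          n_boot = 50,
#'                                          make_figures = FALSE))
#' res$counts
#' }
run_full_study <- function(config = default_run_config()) {
  stopifnot(is.list(config), !is.null(config$seed))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(fmt, ...) message(sprintf(paste0("[venticomp] ", fmt), ...))

  stage("simulate: %d providers (seed %s)", config$n_providers,
        format(config$seed))
  study <- tryCatch(
    simulate_study(n_providers = config$n_providers, seed = config$seed,
                   settings = config$settings %||% resuscitator_settings(),
                   control = config$control %||% sim_control()),
    error = function(e) stop("stage simulate: ", conditionMessage(e),
                             call. = FALSE))

  stage("analyze: %d episodes", length(study$manikin) + length(study$baby_pool))
  seqs <- tryCatch(
    analyze_study(study, min_rise = config$min_rise %||% 5,
                  flow_floor = config$flow_floor %||% 1),
    error = function(e) stop("stage analyze: ", conditionMessage(e),
                             call. = FALSE))

  stage("pair: tolerance %.2f", config$tolerance)
  pairs <- tryCatch(
    pair_by_duration(seqs$manikin, seqs$baby, tolerance = config$tolerance),
    error = function(e) stop("stage pair: ", conditionMessage(e),
                             call. = FALSE))
  groups <- assign_groups(pairs, seqs$manikin, seqs$baby)
  counts <- lengths(groups)
  stage("groups: %s", paste(sprintf("%s=%d", names(counts), counts),
                            collapse = " "))

  panel <- build_panel_dataset(groups)
  stage("stats: %d panel rows, %d bootstrap samples", nrow(panel),
        config$n_boot)

  summary_table <- summarize_median_iqr(panel)

  params <- c("PIP", "PEEP", "eV_T", "leak")
  panel_tests <- do.call(rbind, lapply(c("S", "L"), function(cl) {
    do.call(rbind, lapply(params, function(p) {
      sub <- panel[panel$duration_class == cl & panel$parameter == p, ]
      fit <- fit_random_effects_panel(sub)
      data.frame(duration_class = cl, parameter = p,
                 contrast = fit$contrast,
                 estimate = fit$coefficients[["group"]],
                 hac_se = fit$se[["group"]],
                 p_value = fit$p_value[["group"]],
                 method = fit$method)
    }))
  }))

  pair_defs <- list(c("PIP", "eV_T"), c("PIP", "leak"), c("leak", "eV_T"))
  correlations <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- panel[panel$group_label == g, ]
    do.call(rbind, lapply(seq_along(pair_defs), function(k) {
      pd <- pair_defs[[k]]
      # bootstrap needs >= 5 subjects; below that keep the point estimate
      dc <- if (length(unique(sub$subject_id)) >= 5L) {
        bootstrap_dyncorr(sub, pd[1L], pd[2L], n_boot = config$n_boot,
                          seed = derive_seed(config$seed, 900 + k))
      } else {
        dynamical_correlation(sub, pd[1L], pd[2L])
      }
      data.frame(group = g, pair = paste(pd, collapse = "-"),
                 dyn_rho = dc$rho, ci_low = dc$ci_low, ci_high = dc$ci_high,
                 p_value = dc$p_value,
                 pearson_r = pearson_r(sub, parameter_x = pd[1L],
                                       parameter_y = pd[2L]))
    }))
  }))

  trends <- list()
  for (g in names(groups)) {
    for (p in params) {
      tr <- tryCatch(loess_trend(panel[panel$group_label == g, ], p,
                                 min_subjects = config$min_subjects %||% 5L),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        trends[[paste(g, p, sep = "_")]] <- cbind(group = g, parameter = p, tr)
      }
    }
  }

  n_obs_m <- sum(vapply(c(groups$MS, groups$ML),
                        function(s) nrow(s$obstruction_events) > 0, logical(1)))
  n_obs_b <- sum(vapply(c(groups$BS, groups$BL),
                        function(s) nrow(s$obstruction_events) > 0, logical(1)))
  n_m <- length(groups$MS) + length(groups$ML)
  n_b <- length(groups$BS) + length(groups$BL)
  obstruction <- c(list(n_obstructed_manikin = n_obs_m, n_manikin = n_m,
                        n_obstructed_baby = n_obs_b, n_baby = n_b),
                   chi_square_obstruction(n_obs_m, n_m, n_obs_b, n_b))

  # ---- artifacts -----------------------------------------------------------
  write.csv(seq_breath_table(c(seqs$manikin, seqs$baby)),
            file.path(out_dir, "breaths.csv"), row.names = FALSE)
  write.csv(as.data.frame(pairs), file.path(out_dir, "pairs.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(groups, function(g) vapply(g, `[[`, character(1), "episode_id")),
    file.path(out_dir, "groups.json"), auto_unbox = FALSE)
  write.csv(summary_table, file.path(out_dir, "table1_median_iqr.csv"),
            row.names = FALSE)
  write.csv(correlations, file.path(out_dir, "table2_correlations.csv"),
            row.names = FALSE)
  write.csv(panel_tests, file.path(out_dir, "panel_tests.csv"),
            row.names = FALSE)
  if (length(trends)) {
    write.csv(do.call(rbind, trends), file.path(out_dir, "trend_curves.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(obstruction[c("n_obstructed_manikin", "n_manikin",
                                     "n_obstructed_baby", "n_baby",
                                     "statistic", "df", "p_value")],
                       file.path(out_dir, "obstruction.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(config$make_figures)) {
    try(write_report_figures(panel, trends, out_dir), silent = TRUE)
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg_serial <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(cfg_serial, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "venticomp",
    package_version = as.character(utils::packageVersion("venticomp")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    counts = as.list(counts),
    total_inflations = nrow(panel[panel$parameter == "PIP", ]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("done: %s", out_dir)

  invisible(list(groups = groups, pairs = pairs,
                 summary_table = summary_table, panel_tests = panel_tests,
                 correlations = correlations, trends = trends,
                 obstruction = obstruction, counts = counts, panel = panel,
                 out_dir = out_dir))
}

# boxplots, trend plots and scatter plots in the style of the group
# comparison figures
write_report_figures <- function(panel, trends, out_dir) {
  panel$group_label <- factor(panel$group_label,
                              levels = c("MS", "BS", "ML", "BL"))
  bp <- ggplot2::ggplot(panel,
                        ggplot2::aes(x = .data$group_label, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Ventilatory parameters by group") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "boxplots.png"), bp,
                  width = 7, height = 5, dpi = 120)

  if (length(trends)) {
    tr <- do.call(rbind, trends)
    tp <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$breath_index,
                                           y = .data$smoothed_mean,
                                           colour = .data$group)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = .data$smoothed_mean - .data$standard_error,
        ymax = .data$smoothed_mean + .data$standard_error,
        fill = .data$group), alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "inflation number", y = "smoothed mean (se)",
                    title = "LOESS trend curves (span 0.5)") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, "trends.png"), tp,
                    width = 7, height = 5, dpi = 120)
  }

  wide <- merge(panel[panel$parameter == "leak",
                      c("subject_id", "breath_index", "group", "value")],
                panel[panel$parameter == "eV_T",
                      c("subject_id", "breath_index", "value")],
                by = c("subject_id", "breath_index"))
  names(wide)[4:5] <- c("leak", "eV_T")
  sp <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$leak, y = .data$eV_T)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "leak (%)", y = "eV_T (mL/kg)",
                  title = "Leak vs expired tidal volume") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "scatter_leak_evt.png"), sp,
                  width = 7, height = 4, dpi = 120)
  invisible(NULL)
}
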