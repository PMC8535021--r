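# Study design: each simulated (manikin) episode is paired with a clinical
# (baby) episode of similar total PPV duration, allocated consecutively from
# the pool, then split into the four analysis groups MS/BS/ML/BL.

#' Pair manikin episodes with pool episodes by PPV duration
#'
#' Greedy consecutive allocation: manikin episodes are processed in order and
#' each takes the first not-yet-used pool episode whose total PPV duration is
#' within `tolerance` (relative to the manikin duration). Pairing is
#' deterministic given input order and each pool episode is used at most
#' once; an unpairable episode is an explicit error naming the orphan.
#'
#' @param manikin_sequences List of `ventilation_sequence` (manikin).
#' @param baby_pool List of `ventilation_sequence` (pool, in allocation
#'   order).
#' @param tolerance Maximum relative duration difference (default 0.15).
#' @return Data frame of class `episode_pairs`: `manikin_id`, `baby_id`,
#'   `manikin_duration`, `baby_duration`, `relative_difference`,
#'   `baby_index` (position in the pool).
#' @export
#' @examples
#' # |33 - 30| / 30 = 0.10 <= 0.15, so a 33 s pool episode pairs with a
#' # 30 s manikin episode; a 36 s one (0.20) would not.
pair_by_duration <- function(manikin_sequences, baby_pool, tolerance = 0.15) {
  m_dur <- vapply(manikin_sequences, function(s) s$total_ppv_time, numeric(1))
  b_dur <- vapply(baby_pool, function(s) s$total_ppv_time, numeric(1))
  used <- rep(FALSE, length(baby_pool))
  out <- vector("list", length(manikin_sequences))
  orphans <- character()
  for (i in seq_along(manikin_sequences)) {
    rel <- abs(b_dur - m_dur[i]) / m_dur[i]
    j <- which(!used & rel <= tolerance)[1L]
    if (is.na(j)) {
      orphans <- c(orphans,
                   manikin_sequences[[i]]$episode_id %||% as.character(i))
      next
    }
    used[j] <- TRUE
    out[[i]] <- data.frame(
      manikin_id = manikin_sequences[[i]]$episode_id %||% as.character(i),
      baby_id = baby_pool[[j]]$episode_id %||% as.character(j),
      manikin_duration = m_dur[i], baby_duration = b_dur[j],
      relative_difference = rel[j], baby_index = j)
  }
  if (length(orphans)) {
    stop("unpairable manikin episode(s): ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) {
    pairs <- data.frame(manikin_id = character(), baby_id = character(),
                        manikin_duration = numeric(),
                        baby_duration = numeric(),
                        relative_difference = numeric(),
                        baby_index = integer())
  }
  stopifnot(all(pairs$relative_difference <= tolerance + 1e-12))
  class(pairs) <- c("episode_pairs", class(pairs))
  pairs
}

#' Assemble the four analysis groups
#'
#' Splits the paired episodes into MS, BS, ML, BL: recipient (manikin M vs
#' baby B) crossed with duration class, where the class of a pair is set by
#' the manikin member's scenario (S1 - short, about 30 s; S4 - long, about
#' 90 s), not by its realised duration.
#'
#' @param pairs Output of [pair_by_duration()].
#' @param manikin_sequences,baby_pool The sequence lists the pairs refer to.
#' @param scenario_of Optional named character vector mapping manikin
#'   episode ids to scenario ids; by default the scenario is parsed from ids
#'   of the form `"M01-S1"`.
#' @return An object of class `study_groups`: list with elements `MS`, `BS`,
#'   `ML`, `BL`, each a list of `ventilation_sequence` with
#'   `duration_class` filled in.
#' @export
assign_groups <- function(pairs, manikin_sequences, baby_pool,
                          scenario_of = NULL) {
  groups <- list(MS = list(), BS = list(), ML = list(), BL = list())
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(structure(groups, class = "study_groups"))
  }
  m_ids <- vapply(manikin_sequences, function(s) s$episode_id %||% "",
                  character(1))
  for (k in seq_len(nrow(pairs))) {
    mid <- pairs$manikin_id[k]
    sc <- if (!is.null(scenario_of)) {
      scenario_of[[mid]]
    } else {
      sub(".*-(S[0-9])$", "\\1", mid)
    }
    cls <- if (identical(sc, "S1")) "S" else if (identical(sc, "S4")) "L" else {
      stop("cannot determine duration class for ", mid, call. = FALSE)
    }
    mseq <- manikin_sequences[[match(mid, m_ids)]]
    bseq <- baby_pool[[pairs$baby_index[k]]]
    mseq$duration_class <- cls
    bseq$duration_class <- cls
    gm <- paste0("M", cls)
    gb <- paste0("B", cls)
    groups[[gm]][[length(groups[[gm]]) + 1L]] <- mseq
    groups[[gb]][[length(groups[[gb]]) + 1L]] <- bseq
  }
  structure(groups, class = "study_groups")
}

#' @export
print.study_groups <- function(x, ...) {
  cat("<study_groups>",
      paste(sprintf("%s: %d", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format panel dataset from study groups
#'
#' One row per (sequence, inflation, parameter), suitable for panel
#' regression, LOESS trends and dynamical correlation. Inflations with a
#' flagged missing/undefined leak are excluded from the leak parameter only.
#'
#' @param groups A `study_groups` object.
#' @param parameters Parameters to include.
#' @return Data frame with `subject_id`, `breath_index`, `parameter`,
#'   `value`, `group` (M/B), `duration_class` (S/L), `group_label`.
#' @export
build_panel_dataset <- function(groups,
                                parameters = c("PIP", "PEEP", "eV_T", "leak")) {
  stopifnot(inherits(groups, "study_groups"))
  cols <- c(PIP = "pip", PEEP = "peep", eV_T = "ev_t", leak = "leak_pct")
  out <- list()
  for (g in names(groups)) {
    for (s in groups[[g]]) {
      b <- s$breaths
      if (!nrow(b)) next
      for (p in parameters) {
        v <- b[[cols[[p]]]]
        keep <- !is.na(v)
        if (p == "leak") keep <- keep & b$leak_flag != "undefined"
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.frame(
          subject_id = s$episode_id, breath_index = b$index[keep],
          parameter = p, value = v[keep],
          group = substr(g, 1, 1), duration_class = substr(g, 2, 2),
          group_label = g)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(), breath_index = integer(),
                      parameter = character(), value = numeric(),
                      group = character(), duration_class = character(),
                      group_label = character()))
  }
  do.call(rbind, out)
}
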