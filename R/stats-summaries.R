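#' Median and IQR of a parameter per group
#'
#' Pools all per-breath values of each group and reports the median and
#' interquartile range, the summary used for the per-group parameter table
#' and boxplots.
#'
#' @param panel Long-format panel data frame (see [build_panel_dataset()]).
#' @param parameter Parameter to summarise (`NULL`: all).
#' @param by Grouping column (default `"group_label"`).
#' @return Data frame with `group`, `parameter`, `median`, `iqr`, `q1`,
#'   `q3`, `n`.
#' @export
#' @examples
#' d <- data.frame(subject_id = "a", breath_index = 1:5, parameter = "PIP",
#'                 value = 1:5, group_label = "MS")
#' summarize_median_iqr(d)  # median 3, IQR 2
summarize_median_iqr <- function(panel, parameter = NULL,
                                 by = "group_label") {
  if (!is.null(parameter)) {
    panel <- panel[panel$parameter %in% parameter, , drop = FALSE]
  }
  panel <- panel[is.finite(panel$value), , drop = FALSE]
  if (!nrow(panel)) stop("no values to summarise", call. = FALSE)
  sp <- split(panel, list(panel[[by]], panel$parameter), drop = TRUE)
  out <- lapply(sp, function(d) {
    qs <- quantile(d$value, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = d[[by]][1L], parameter = d$parameter[1L],
               median = qs[2L], iqr = qs[3L] - qs[1L],
               q1 = qs[1L], q3 = qs[3L], n = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$parameter, res$group), ]
}

#' LOESS trend curve over breath index
#'
#' Smoothed mean trajectory of a parameter against breath index (local
#' linear fits with tricube weights, span 0.5 by default), restricted to
#' breath indices contributed by at least `min_subjects` of the group's
#' subjects; the pointwise standard error comes from the local weighted
#' residual variance.
#'
#' @param panel Long-format panel data frame for a single group.
#' @param parameter Parameter to smooth.
#' @param span LOESS span (default 0.5).
#' @param min_subjects Minimum subjects contributing at a breath index for
#'   it to enter the trend (default 5).
#' @return Data frame of class `trend_curve`: `breath_index`,
#'   `smoothed_mean`, `standard_error`, `n_subjects_at_index`.
#' @export
loess_trend <- function(panel, parameter = NULL, span = 0.5,
                        min_subjects = 5L) {
  if (!is.null(parameter) && "parameter" %in% names(panel)) {
    panel <- panel[panel$parameter == parameter, , drop = FALSE]
  }
  panel <- panel[is.finite(panel$value), , drop = FALSE]
  n_at <- tapply(panel$subject_id, panel$breath_index,
                 function(s) length(unique(s)))
  keep_idx <- as.integer(names(n_at))[n_at >= min_subjects]
  panel <- panel[panel$breath_index %in% keep_idx, , drop = FALSE]
  if (length(unique(panel$breath_index)) < 3L) {
    stop("fewer than 3 breath indices retained after the min-subjects rule",
         call. = FALSE)
  }
  fit <- loess(value ~ breath_index, data = panel, span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- sort(unique(panel$breath_index))
  pr <- predict(fit, newdata = data.frame(breath_index = grid), se = TRUE)
  out <- data.frame(breath_index = grid, smoothed_mean = as.numeric(pr$fit),
                    standard_error = as.numeric(pr$se.fit),
                    n_subjects_at_index = as.integer(n_at[as.character(grid)]))
  class(out) <- c("trend_curve", class(out))
  out
}

#' Pearson correlation on pooled breath-level values
#'
#' Product-moment correlation on pooled per-breath (x, y) pairs. Repeated-
#' measures autocorrelation biases this quantity - it is reported to allow
#' comparison with the literature, not as the primary inference, which is
#' the dynamical correlation.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values are
#'   dropped), or `x` a panel data frame with `parameter_x`/`parameter_y`.
#' @param parameter_x,parameter_y Parameter names when `x` is a panel; the
#'   values are matched within subject by breath index.
#' @return The correlation coefficient.
#' @export
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)  # 1
pearson_r <- function(x, y = NULL, parameter_x = NULL, parameter_y = NULL) {
  if (is.data.frame(x)) {
    dx <- x[x$parameter == parameter_x, c("subject_id", "breath_index", "value")]
    dy <- x[x$parameter == parameter_y, c("subject_id", "breath_index", "value")]
    m <- merge(dx, dy, by = c("subject_id", "breath_index"))
    x <- m$value.x
    y <- m$value.y
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance", call. = FALSE)
  cor(x, y)
}

#' Chi-square test of obstruction occurrence
#'
#' Pearson chi-square (no continuity correction by default) on the 2x2 table
#' of sequences with/without upper-airway obstruction in the combined
#' manikin versus combined baby groups.
#'
#' @param n_obstructed_manikin,n_manikin Obstructed and total manikin
#'   sequences.
#' @param n_obstructed_baby,n_baby Same for baby sequences.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
#' @examples
#' chi_square_obstruction(4, 18, 7, 18)$statistic
chi_square_obstruction <- function(n_obstructed_manikin, n_manikin,
                                   n_obstructed_baby, n_baby,
                                   correct = FALSE) {
  counts <- c(n_obstructed_manikin, n_manikin - n_obstructed_manikin,
              n_obstructed_baby, n_baby - n_obstructed_baby)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tab <- matrix(counts, nrow = 2L, byrow = TRUE,
                dimnames = list(c("manikin", "baby"),
                                c("obstructed", "clear")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in the 2x2 table", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = as.numeric(ht$statistic), df = as.numeric(ht$parameter),
       p_value = ht$p.value, table = tab)
}
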