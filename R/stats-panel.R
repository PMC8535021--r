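# One-way random-effects panel model with HAC (Newey-West) inference, used
# to compare a ventilatory parameter between manikin and baby sequences over
# breath index, separately for short and long sequences.

#' Newey-West HAC variance matrix
#'
#' Heteroscedasticity- and autocorrelation-consistent covariance of OLS
#' coefficients using Bartlett-kernel weights `w_j = 1 - j/(lag + 1)`.
#' Autocovariance terms are accumulated within subjects only, so serial
#' correlation along each ventilation sequence is captured without coupling
#' distinct subjects. At `lag = 0` the estimator reduces to White's
#' heteroscedasticity-only covariance.
#'
#' @param X Regressor matrix (n x k), including the intercept column.
#' @param residuals Length-n residual vector, ordered by time within
#'   subject.
#' @param subject Length-n subject identifier (default: one single series).
#' @param lag Maximum lag `L >= 0`; must be shorter than every subject's
#'   series.
#' @return A k x k covariance matrix (positive semi-definite by
#'   construction).
#' @export
#' @examples
#' X <- cbind(1, c(1, 2, 3, 4))
#' e <- c(0.5, -1, 0.25, 0.75)
#' newey_west_vcov(X, e, lag = 0)  # equals White's estimator
newey_west_vcov <- function(X, residuals, subject = NULL, lag = 0L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  residuals <- as.vector(residuals)
  if (length(residuals) != n) stop("residual length mismatch", call. = FALSE)
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  subject <- subject %||% rep(1L, n)
  h <- X * residuals  # score contributions
  S <- matrix(0, k, k)
  for (id in unique(subject)) {
    hi <- h[subject == id, , drop = FALSE]
    Ti <- nrow(hi)
    if (lag >= Ti) stop("lag must be smaller than the series length", call. = FALSE)
    S <- S + crossprod(hi)
    if (lag > 0) {
      for (j in seq_len(lag)) {
        w <- 1 - j / (lag + 1)
        G <- crossprod(hi[1:(Ti - j), , drop = FALSE],
                       hi[(1 + j):Ti, , drop = FALSE])
        S <- S + w * (G + t(G))
      }
    }
  }
  bread <- solve(crossprod(X))
  bread %*% S %*% bread
}

# standard plug-in bandwidth: floor(4 * (T/100)^(2/9))
default_nw_lag <- function(T_len) max(0L, floor(4 * (T_len / 100)^(2 / 9)))

#' One-way random-effects panel model with Newey-West inference
#'
#' Fits `value_it = alpha + beta * group_i + u_i + e_it` by feasible GLS with
#' Swamy-Arora variance components: the idiosyncratic variance comes from the
#' within (subject-demeaned) residuals, the subject-level variance from the
#' between regression, and the data are quasi-demeaned by
#' `theta_i = 1 - sqrt(s2_e / (T_i * s2_u + s2_e))` before OLS. The
#' group-contrast variance uses the Newey-West HAC estimator on the
#' quasi-demeaned residuals to absorb remaining serial correlation and
#' heteroscedasticity; the two-sided p-value uses a t reference with
#' `n_subjects - 2` degrees of freedom. If the estimated subject-level
#' variance is not positive the fit degenerates to pooled OLS (with a
#' warning), which is also the exact limit of the transformation.
#'
#' @param panel Long-format panel data frame (see [build_panel_dataset()]):
#'   columns `subject_id`, `breath_index`, `value`, `group`, and optionally
#'   `parameter`.
#' @param parameter If given, the panel is filtered to this parameter first.
#' @param lag Newey-West lag; default `floor(4 * (T/100)^(2/9))` with `T`
#'   the median sequence length.
#' @return List of class `panel_fit`: `coefficients` (intercept and group
#'   contrast), `se` (HAC), `statistic`, `p_value`, `df`, `sigma2_e`,
#'   `sigma2_u`, `theta` (per subject), `lag`, `method`.
#' @export
fit_random_effects_panel <- function(panel, parameter = NULL, lag = NULL) {
  if (!is.null(parameter) && "parameter" %in% names(panel)) {
    panel <- panel[panel$parameter == parameter, , drop = FALSE]
  }
  panel <- panel[is.finite(panel$value), , drop = FALSE]
  ids <- unique(panel$subject_id)
  if (length(ids) < 4L) stop("need at least 2 subjects per arm", call. = FALSE)
  grp_of <- vapply(ids, function(id) {
    as.character(panel$group[panel$subject_id == id][1L])
  }, character(1))
  if (length(unique(grp_of)) != 2L) {
    stop("group must take exactly two values", call. = FALSE)
  }
  lev <- sort(unique(grp_of))
  panel <- panel[order(panel$subject_id, panel$breath_index), , drop = FALSE]
  y <- panel$value
  g <- as.numeric(panel$group == lev[2L])
  sub <- panel$subject_id

  T_i <- table(sub)[as.character(sub)]  # expanded per-row lengths
  Ti_u <- tapply(panel$breath_index, sub, length)
  ybar_i <- tapply(y, sub, mean)
  ybar <- ybar_i[as.character(sub)]

  n_sub <- length(ids)
  N <- length(y)
  # within: only time-invariant regressors, so within residuals are y - ybar_i
  s2_e <- sum((y - ybar)^2) / (N - n_sub)
  # between regression of subject means on (1, group)
  gi <- as.numeric(grp_of[match(names(ybar_i), ids)] == lev[2L])
  Xb <- cbind(1, gi)
  bfit <- lm.fit(Xb, as.numeric(ybar_i))
  s2_between <- sum(bfit$residuals^2) / (n_sub - 2L)
  s2_u <- s2_between - s2_e * mean(1 / Ti_u)

  method <- "Swamy-Arora FGLS"
  if (!is.finite(s2_u) || s2_u <= 0) {
    warning("degenerate subject-level variance component; falling back to pooled OLS")
    s2_u <- 0
    method <- "pooled OLS"
  }
  theta_i <- 1 - sqrt(s2_e / (Ti_u * s2_u + s2_e))
  theta <- theta_i[as.character(sub)]

  ys <- as.vector(y - theta * ybar)
  Xs <- cbind(intercept = 1 - theta,
              group = g - theta * g)  # g is time-invariant per subject
  fit <- lm.fit(Xs, ys)
  beta <- coef(fit)
  res <- fit$residuals
  if (is.null(lag)) lag <- default_nw_lag(median(Ti_u))
  lag <- min(lag, min(Ti_u) - 1L)
  V <- newey_west_vcov(Xs, res, subject = sub, lag = lag)
  se <- sqrt(diag(V))
  tstat <- beta / se
  df <- n_sub - 2L
  p <- 2 * pt(-abs(tstat), df)
  structure(list(coefficients = setNames(beta, c("intercept", "group")),
                 se = setNames(se, c("intercept", "group")),
                 statistic = setNames(tstat, c("intercept", "group")),
                 p_value = setNames(p, c("intercept", "group")),
                 df = df, sigma2_e = s2_e, sigma2_u = s2_u,
                 theta = theta_i, lag = lag, method = method,
                 contrast = paste(lev[2L], "vs", lev[1L]),
                 n_subjects = n_sub, n_obs = N),
            class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  cat(sprintf("<panel_fit> %s (%s), %d subjects / %d obs, NW lag %d\n",
              x$contrast, x$method, x$n_subjects, x$n_obs, x$lag))
  cat(sprintf("  group contrast: %.4g (HAC se %.4g), t = %.3f, p = %.4g\n",
              x$coefficients["group"], x$se["group"],
              x$statistic["group"], x$p_value["group"]))
  invisible(x)
}

#' Augmented Dickey-Fuller stationarity screen
#'
#' Optional diagnostic: per-subject ADF regression
#' `diff(y)_t = a + rho * y_(t-1) + sum(gamma_j diff(y)_(t-j))`, with the t
#' statistic on `rho` compared against the 5 percent constant-case critical
#' value (-2.86). The screen only warns (it is a model-use justification, not
#' a gate) and is a coarse tabulated-critical-value check, not a full
#' response-surface test.
#'
#' @param series Numeric series (one subject).
#' @param lags Number of lagged differences (default 1).
#' @param critical Critical value for the 5 percent level (default -2.86).
#' @param warn Emit a warning when the screen fails.
#' @return List with `statistic`, `stationary` (logical), `lags`.
#' @export
adf_screen <- function(series, lags = 1L, critical = -2.86, warn = TRUE) {
  series <- series[is.finite(series)]
  n <- length(series)
  if (n < lags + 5L) {
    return(list(statistic = NA_real_, stationary = NA, lags = lags))
  }
  dy <- diff(series)
  ylag <- series[-n]
  m <- length(dy)
  X <- cbind(1, ylag[(lags + 1):m])
  if (lags > 0) {
    for (j in seq_len(lags)) X <- cbind(X, dy[(lags + 1 - j):(m - j)])
  }
  yy <- dy[(lags + 1):m]
  fit <- lm.fit(X, yy)
  s2 <- sum(fit$residuals^2) / (length(yy) - ncol(X))
  XtXinv <- solve(crossprod(X))
  tstat <- coef(fit)[2L] / sqrt(s2 * XtXinv[2L, 2L])
  stat_ok <- tstat < critical
  if (warn && !stat_ok) {
    warning("ADF screen does not reject a unit root for this series")
  }
  list(statistic = as.numeric(tstat), stationary = stat_ok, lags = lags)
}
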