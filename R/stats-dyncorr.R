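# Dynamical correlation for multivariate longitudinal data: per subject, two
# repeated-measures curves are centred (within subject, and against the
# cross-subject mean trend), standardised to unit L2 norm, and their inner
# product taken; the population estimate is the mean over subjects. Inference
# is by bootstrap resampling of subjects.

# panel (long) -> subjects x index matrix on the shared index grid
panel_pair_matrices <- function(panel, parameter_x, parameter_y) {
  px <- panel[panel$parameter == parameter_x & is.finite(panel$value), ]
  py <- panel[panel$parameter == parameter_y & is.finite(panel$value), ]
  ids <- intersect(unique(px$subject_id), unique(py$subject_id))
  if (!length(ids)) stop("no subjects with both curves", call. = FALSE)
  # truncation to shared indices: keep the index range every subject covers
  max_common <- min(vapply(ids, function(id) {
    min(max(px$breath_index[px$subject_id == id]),
        max(py$breath_index[py$subject_id == id]))
  }, numeric(1)))
  grid <- seq_len(max_common)
  fetch <- function(d, id) {
    di <- d[d$subject_id == id, ]
    v <- di$value[match(grid, di$breath_index)]
    if (anyNA(v)) {  # interior gaps: linear interpolation on the grid
      v <- approx(di$breath_index, di$value, xout = grid, rule = 2)$y
    }
    v
  }
  X <- t(vapply(ids, function(id) fetch(px, id), numeric(length(grid))))
  Y <- t(vapply(ids, function(id) fetch(py, id), numeric(length(grid))))
  rownames(X) <- rownames(Y) <- ids
  list(X = X, Y = Y, grid = grid, ids = ids)
}

dyncorr_from_matrices <- function(X, Y, warn = TRUE) {
  stopifnot(all(dim(X) == dim(Y)))
  if (ncol(X) < 3L) stop("need at least 3 shared indices", call. = FALSE)
  # standardise each subject curve (centre by its time average, unit L2
  # norm) before removing the cross-subject mean trend, so the estimate is
  # invariant to per-subject positive-slope affine rescaling
  cx <- X - rowMeans(X)
  cy <- Y - rowMeans(Y)
  nx <- sqrt(rowSums(cx^2))
  ny <- sqrt(rowSums(cy^2))
  ok <- nx > 1e-12 & ny > 1e-12
  if (!all(ok) && warn) {
    warning(sum(!ok), " subject(s) with a zero-variance curve excluded")
  }
  if (!any(ok)) return(list(rho = NA_real_, rho_i = numeric()))
  wx <- cx[ok, , drop = FALSE] / nx[ok]
  wy <- cy[ok, , drop = FALSE] / ny[ok]
  ux <- sweep(wx, 2L, colMeans(wx))
  uy <- sweep(wy, 2L, colMeans(wy))
  nux <- sqrt(rowSums(ux^2))
  nuy <- sqrt(rowSums(uy^2))
  ok2 <- nux > 1e-12 & nuy > 1e-12
  if (!all(ok2) && warn) {
    warning(sum(!ok2), " subject(s) coincide with the mean trend; excluded")
  }
  if (!any(ok2)) return(list(rho = NA_real_, rho_i = numeric()))
  rho_i <- rowSums(ux[ok2, , drop = FALSE] * uy[ok2, , drop = FALSE]) /
    (nux[ok2] * nuy[ok2])
  list(rho = mean(rho_i), rho_i = rho_i)
}

#' Dynamical correlation between two longitudinal parameters
#'
#' Point estimate of the dynamical correlation between two per-breath
#' parameter trajectories observed on the same subjects. Each subject's
#' curves are truncated to the index range shared by all subjects, centred by
#' their time average and scaled to unit L2 norm; the cross-subject mean
#' trend of the standardised curves is then removed, the curves renormalised,
#' and multiplied; the estimate is the mean of the per-subject inner
#' products. The sign reflects co-movement of the trajectory shapes (slopes
#' of the trends), not of pooled values, and the estimate is invariant to
#' positive-slope affine rescaling of each subject's curves.
#'
#' @param panel Long-format panel data frame with columns `subject_id`,
#'   `breath_index`, `parameter`, `value`.
#' @param parameter_x,parameter_y The two parameters to correlate.
#' @return List of class `dyncorr_result`: `rho`, per-subject `rho_i`,
#'   `pair`, `n_subjects`, `n_indices`; `ci_low`, `ci_high`, `p_value` and
#'   `n_bootstrap` are `NA` until filled by [bootstrap_dyncorr()].
#' @export
#' @examples
#' toy <- expand.grid(subject_id = c("a", "b", "c"), breath_index = 1:5)
#' toy$parameter <- "PIP"; toy$value <- rnorm(nrow(toy))
#' toy2 <- toy; toy2$parameter <- "eV_T"  # identical curves
#' dynamical_correlation(rbind(toy, toy2), "PIP", "eV_T")$rho  # 1
dynamical_correlation <- function(panel, parameter_x, parameter_y) {
  mats <- panel_pair_matrices(panel, parameter_x, parameter_y)
  dc <- dyncorr_from_matrices(mats$X, mats$Y)
  structure(list(rho = dc$rho, rho_i = dc$rho_i,
                 ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, n_bootstrap = NA_integer_,
                 pair = c(parameter_x, parameter_y),
                 n_subjects = length(dc$rho_i),
                 n_indices = length(mats$grid)),
            class = "dyncorr_result")
}

#' Bootstrap inference for the dynamical correlation
#'
#' Resamples subjects with replacement `n_boot` times (the cross-subject
#' mean trend is recomputed within each resample), reports the percentile
#' 95 percent confidence interval and a two-sided bootstrap p-value for
#' `rho = 0`: twice the proportion of resampled estimates with sign opposite
#' to the point estimate, floored at `1/n_boot` and capped at 1.
#'
#' @param panel,parameter_x,parameter_y As in [dynamical_correlation()].
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return A `dyncorr_result` with `ci_low`, `ci_high`, `p_value` and
#'   `n_bootstrap` filled in.
#' @export
bootstrap_dyncorr <- function(panel, parameter_x, parameter_y,
                              n_boot = 1000, seed = 1, conf_level = 0.95) {
  mats <- panel_pair_matrices(panel, parameter_x, parameter_y)
  n <- nrow(mats$X)
  if (n < 5L) stop("need at least 5 subjects for the bootstrap", call. = FALSE)
  point <- dyncorr_from_matrices(mats$X, mats$Y)
  set.seed(seed)
  rho_star <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    dyncorr_from_matrices(mats$X[idx, , drop = FALSE],
                          mats$Y[idx, , drop = FALSE], warn = FALSE)$rho
  }, numeric(1))
  rho_star <- rho_star[is.finite(rho_star)]
  alpha <- 1 - conf_level
  ci <- as.numeric(quantile(rho_star, c(alpha / 2, 1 - alpha / 2),
                            names = FALSE))
  opp <- if (point$rho >= 0) mean(rho_star <= 0) else mean(rho_star >= 0)
  p <- min(1, max(2 * opp, 1 / length(rho_star)))
  structure(list(rho = point$rho, rho_i = point$rho_i,
                 ci_low = min(ci[1L], point$rho),
                 ci_high = max(ci[2L], point$rho),
                 p_value = p, n_bootstrap = length(rho_star),
                 pair = c(parameter_x, parameter_y),
                 n_subjects = n, n_indices = length(mats$grid)),
            class = "dyncorr_result")
}

#' @export
print.dyncorr_result <- function(x, ...) {
  cat(sprintf("<dyncorr> %s ~ %s: rho = %.3f", x$pair[1L], x$pair[2L], x$rho))
  if (is.finite(x$ci_low)) {
    cat(sprintf(" (95%% CI %.3f; %.3f), p = %.3f [%d bootstrap samples]",
                x$ci_low, x$ci_high, x$p_value, x$n_bootstrap))
  }
  cat(sprintf(", %d subjects\n", x$n_subjects))
  invisible(x)
}
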