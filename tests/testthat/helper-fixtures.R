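# shared fixtures: noise-free controls, null-panel generators, toy panels

ctl_quiet <- function(...) {
  sim_control(pressure_noise_sd = 0, flow_noise_sd = 0, ...)
}

# balanced two-arm panel: subject intercept + (optionally AR(1)) noise
make_null_panel <- function(n_per_arm = 18, T_len = 25, delta = 0,
                            phi = 0, sd_u = 1, sd_e = 1) {
  subs <- paste0("s", seq_len(2 * n_per_arm))
  grp <- rep(c("M", "B"), each = n_per_arm)
  do.call(rbind, lapply(seq_along(subs), function(i) {
    e <- if (phi > 0) {
      as.numeric(stats::arima.sim(list(ar = phi), T_len, sd = sd_e))
    } else {
      rnorm(T_len, 0, sd_e)
    }
    data.frame(subject_id = subs[i], breath_index = seq_len(T_len),
               value = sd_u * rnorm(1) + (grp[i] == "B") * delta + e,
               group = grp[i])
  }))
}

# long-format two-parameter panel from subject x index matrices
panel_from_matrices <- function(X, Y, px = "PIP", py = "eV_T") {
  ids <- paste0("s", seq_len(nrow(X)))
  long <- function(M, p) {
    do.call(rbind, lapply(seq_len(nrow(M)), function(i) {
      data.frame(subject_id = ids[i], breath_index = seq_len(ncol(M)),
                 parameter = p, value = M[i, ])
    }))
  }
  rbind(long(X, px), long(Y, py))
}

# brute-force oracle: loop-based dynamical correlation written directly from
# the definition (standardise, remove mean trend, renormalise, inner
# product), independent of the package's vectorised path
brute_force_dyncorr <- function(X, Y) {
  n <- nrow(X); m <- ncol(X)
  wx <- X; wy <- Y
  for (i in 1:n) {
    a <- X[i, ] - mean(X[i, ])
    b <- Y[i, ] - mean(Y[i, ])
    wx[i, ] <- a / sqrt(sum(a^2))
    wy[i, ] <- b / sqrt(sum(b^2))
  }
  for (j in 1:m) {
    wx[, j] <- wx[, j] - sum(wx[, j]) / n
    wy[, j] <- wy[, j] - sum(wy[, j]) / n
  }
  rho_i <- numeric(n)
  for (i in 1:n) {
    rho_i[i] <- sum(wx[i, ] * wy[i, ]) /
      (sqrt(sum(wx[i, ]^2)) * sqrt(sum(wy[i, ]^2)))
  }
  mean(rho_i)
}

# episode suite with known obstruction injections, for detector scoring
make_obstruction_suite <- function(n_episodes = 30, seed = 101,
                                   control = sim_control()) {
  out <- vector("list", n_episodes)
  for (i in seq_len(n_episodes)) {
    ep <- simulate_scenario("S1", seed = seed + i, control = control)
    n <- nrow(ep$record$truth)
    injected <- i %% 2L == 0L
    win <- NULL
    if (injected) {
      set.seed(seed * 1000 + i)
      len <- sample(3:5, 1)
      start <- sample(5:(n - len - 3L), 1)
      ep <- inject_obstruction(ep, start, len)
      win <- c(start, start + len - 1L)
    }
    out[[i]] <- list(episode = ep, injected = injected, window = win)
  }
  out
}
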