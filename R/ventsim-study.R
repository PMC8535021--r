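#' Simulate the full study design
#'
#' Emulates the study's data collection: each of `n_providers` providers
#' performs one short (S1, 30 s optimal PPV) and one long (S4, 90 s) manikin
#' scenario, and a pool of real-newborn episodes is generated such that every
#' manikin episode has at least one pool episode of similar PPV duration
#' (well within the +/-15 percent pairing tolerance). Upper-airway
#' obstructions are injected per sequence with the study's observed
#' per-sequence rates (manikin 4/36, baby 7/36). Every episode carries a
#' ground-truth log (injected leak fractions, compliance trajectory,
#' obstruction flags) for parameter-recovery testing.
#'
#' @param n_providers Number of providers (default 18).
#' @param seed Integer seed; identical (arguments, seed) give identical
#'   output.
#' @param settings A [resuscitator_settings()] (per-provider inflation rates
#'   are jittered around its `inflation_rate`).
#' @param control A [sim_control()].
#' @param manikin_quality PPV quality for the manikin scenarios.
#' @param obstruction_prob_manikin,obstruction_prob_baby Per-sequence
#'   probability of an injected obstruction.
#' @param baby_duration_jitter Half-width of the relative duration difference
#'   between a baby episode and the manikin episode it shadows (default
#'   0.06, comfortably inside the 0.15 pairing tolerance).
#' @return An object of class `ppv_study`: list with `manikin` (2 x
#'   n_providers episodes, S1 then S4 per provider), `baby_pool` (same count,
#'   shuffled), and `seed`.
#' @export
#' @examples
#' \donttest{
#' st <- simulate_study(n_providers = 2, seed = 1)
#' length(st$manikin)  # 4
#' }
simulate_study <- function(n_providers = 18, seed = 1,
                           settings = resuscitator_settings(),
                           control = sim_control(),
                           manikin_quality = "optimal",
                           obstruction_prob_manikin = 4 / 36,
                           obstruction_prob_baby = 7 / 36,
                           baby_duration_jitter = 0.06) {
  if (n_providers < 1) stop("n_providers must be >= 1", call. = FALSE)
  manikin <- list()
  babies <- list()
  k <- 0L
  for (p in seq_len(n_providers)) {
    set.seed(derive_seed(seed, p * 100))
    rate <- clamp(rnorm(1, settings$inflation_rate, 2),
                  settings$inflation_rate - 8, settings$inflation_rate + 8)
    m_leak_mean <- clamp(0.35 + rnorm(1, 0, 0.05), 0.05, 0.7)
    b_leak_mean <- clamp(0.50 + rnorm(1, 0, 0.05), 0.1, 0.8)
    baby_weights <- clamp(rnorm(2, 3.5, 0.45), 2.5, 4.8)
    set_p <- settings
    set_p$inflation_rate <- rate

    for (sc in c("S1", "S4")) {
      k <- k + 1L
      ep <- simulate_scenario(scenario_spec(sc),
                              profile = subject_profile("manikin"),
                              settings = set_p, quality = manikin_quality,
                              seed = derive_seed(seed, k * 10 + 1),
                              leak = mask_leak_model(m_leak_mean, 0.25, -0.002),
                              control = control)
      ep$episode_id <- sprintf("M%02d-%s", p, sc)
      m_dur <- diff(range(ep$record$time))

      j <- if (sc == "S1") 1L else 2L
      bp <- subject_profile("baby", weight = baby_weights[j])
      set.seed(derive_seed(seed, k * 10 + 2))
      target <- m_dur * (1 + runif(1, -baby_duration_jitter,
                                   baby_duration_jitter))
      bep <- simulate_baby_episode(target, settings = set_p, profile = bp,
                                   seed = derive_seed(seed, k * 10 + 3),
                                   leak = mask_leak_model(b_leak_mean, 0.28,
                                                          -0.002),
                                   control = control)
      bep$episode_id <- sprintf("Bp%02d-%s", p, sc)  # relabelled after shuffle

      set.seed(derive_seed(seed, k * 10 + 4))
      ep <- maybe_inject_obstruction(ep, obstruction_prob_manikin)
      bep <- maybe_inject_obstruction(bep, obstruction_prob_baby)

      manikin[[length(manikin) + 1L]] <- ep
      babies[[length(babies) + 1L]] <- bep
    }
  }
  # the clinical pool arrives in its own (chronological) order
  set.seed(derive_seed(seed, 7))
  babies <- babies[sample(seq_along(babies))]
  for (i in seq_along(babies)) {
    babies[[i]]$episode_id <- sprintf("B%02d", i)
  }
  structure(list(manikin = manikin, baby_pool = babies,
                 n_providers = n_providers, seed = seed),
            class = "ppv_study")
}

# draw one Bernoulli obstruction and, if it fires, pick a legal window:
# after the valve has opened (manikin S4), clear of episode start and of the
# baby end-transition fade
maybe_inject_obstruction <- function(ep, prob, len_range = 3:5) {
  if (runif(1) >= prob) return(ep)
  truth <- ep$record$truth
  n <- nrow(truth)
  len <- sample(len_range, 1L)
  first_ok <- if (any(!truth$valve_open)) max(which(!truth$valve_open)) + 3L else 5L
  last_ok <- n - len - 3L
  if (last_ok < first_ok) return(ep)
  start <- if (last_ok == first_ok) first_ok else sample(first_ok:last_ok, 1L)
  inject_obstruction(ep, start, len)
}

#' @export
print.ppv_study <- function(x, ...) {
  cat(sprintf("<ppv_study> %d providers: %d manikin episodes, %d baby-pool episodes (seed %s)\n",
              x$n_providers, length(x$manikin), length(x$baby_pool),
              format(x$seed)))
  invisible(x)
}
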