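# small shared helpers; no exported surface here

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# trapezoidal integral of y over a uniform grid with step dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * sum((y[-1L] + y[-n]) / 2)
}

stop_if_not_finite <- function(...) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    if (!all(is.finite(args[[i]]))) {
      stop(sprintf("non-finite value in '%s'", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# deterministic child seed from a base seed and an index; stays well below 2^31
derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 1e6) * 1009 + as.numeric(k) * 9973) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
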