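# Independent oracles used across tests.

# Brute-force evaluation of the harmonic-tolerant interval loss over the
# full grid, with the documented selection rule re-implemented in plain
# loops; deliberately shares no code with estimate_m_prime().
brute_force_m_prime <- function(p, m_min = 15, m_max = 40, step = 0.01,
                                scales = c(2, 1, 0.5), tie_tol = 1e-9,
                                alias_guard = 20) {
  k <- floor((m_max - m_min) / step + 1e-9)
  g <- round(m_min + step * (0:k), 10)
  L <- vapply(g, function(m) {
    best <- rep(Inf, length(p))
    for (a in scales) best <- pmin(best, (a * p - m)^2)
    sum(best)
  }, numeric(1))
  lmin <- min(L)
  imin <- which.min(L)
  n_g <- length(g)
  is_min <- logical(n_g)
  for (i in seq_len(n_g)) {
    left_ok <- i == 1L || L[i] <= L[i - 1L]
    right_ok <- i == n_g || L[i] <= L[i + 1L]
    is_min[i] <- left_ok && right_ok
  }
  related <- logical(n_g)
  for (a in scales[scales != 1]) {
    related <- related | abs(g / (a * g[imin]) - 1) < 0.1
  }
  cand <- which((is_min & related & L <= alias_guard * lmin + tie_tol) |
                  seq_len(n_g) == imin |
                  (is_min & L <= lmin + tie_tol))
  count_unit <- function(m) {
    n1 <- 0L
    for (pk in p) {
      errs <- (scales * pk - m)^2
      if (any(scales[errs <= min(errs) + 1e-12] == 1)) n1 <- n1 + 1L
    }
    n1
  }
  if (length(cand) > 1L) {
    n1 <- vapply(cand, function(i) count_unit(g[i]), integer(1))
    cand <- cand[n1 == max(n1)]
    if (length(cand) > 1L) cand <- cand[L[cand] <= min(L[cand]) + tie_tol]
    if (length(cand) > 1L) {
      d <- abs(g[cand] - stats::median(p))
      cand <- cand[d <= min(d) + 1e-12]
    }
  }
  list(m_prime = g[cand[1]], loss = L[cand[1]])
}

# Analytic magnitude response of the bilinear-designed Butterworth
# band-pass (prototype order `order`), from the prewarped continuous
# response; single-pass amplitude gain.
analytic_butter_gain <- function(f, low, high, order, fs) {
  W <- tan(pi * f / fs)
  Wl <- tan(pi * low / fs)
  Wh <- tan(pi * high / fs)
  x <- (W^2 - Wl * Wh) / ((Wh - Wl) * W)
  1 / sqrt(1 + x^(2 * order))
}

# Noise model without motion transients: the controlled condition for
# parameter-recovery experiments (sensor noise, drift and heart-rate
# variability stay on; no artifact-inducing events).
quiet_noise <- function() noise_model(spike_rate = 0)
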