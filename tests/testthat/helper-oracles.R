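# Independent brute-force oracles used across the suite.

# Order-statistic quantile by direct enumeration: the smallest k-th value
# whose rank satisfies k >= level * m (k >= 1). Kept independent of
# empirical_quantile's internals.
oracle_quantile <- function(values, level) {
  m <- length(values)
  k <- which(seq_len(m) >= level * m - 1e-9)[1]
  if (is.na(k)) k <- m
  k <- max(1L, k)
  sort(values)[k]
}

# Exhaustive nearest-neighbour retrieval by scanning every candidate.
oracle_retrieve <- function(metrics, bound) {
  best <- 1L
  for (j in seq_along(metrics)) {
    if (abs(metrics[j] - bound) < abs(metrics[best] - bound)) best <- j
  }
  best
}

# Build a calibration record list whose ns = 2 ensembles realise given
# (s_lo, s_hi) score pairs at alpha_lo = alpha_hi = 0.25 and truth 0:
# Q_0.25 of two values is the min and Q_0.75 the max, so the ensemble
# {s_lo, -s_hi} yields exactly those scores (requires s_lo + s_hi <= 0).
records_from_scores <- function(s_lo, s_hi) {
  stopifnot(all(s_lo + s_hi <= 0))
  list(ensembles = mapply(function(a, b) c(a, -b), s_lo, s_hi,
                          SIMPLIFY = FALSE),
       truths = rep(0, length(s_lo)))
}

# A metric_cp fit with prescribed adjustments, for exercising the
# prediction formula in isolation.
fit_with_adjustments <- function(q_lo, q_hi, alpha_lo, alpha_hi) {
  structure(list(q_lo = q_lo, q_hi = q_hi,
                 alpha_hat_lo = NA_real_, alpha_hat_hi = NA_real_,
                 n = NA_integer_, alpha_lo = alpha_lo, alpha_hi = alpha_hi,
                 scores = NULL, quantile_convention = "test", call = NULL),
            class = "metric_cp")
}
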