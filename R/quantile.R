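#' Empirical quantile (lower order-statistic convention)
#'
#' Returns the \eqn{\alpha}-th empirical quantile of a finite sample as the
#' \eqn{k}-th smallest value with \eqn{k = \max(1, \lceil \alpha m \rceil)}
#' for \eqn{m} values: the lower empirical quantile, with no interpolation.
#' Level 0 gives the minimum and level 1 the maximum. Every quantile the
#' package computes -- ensemble quantiles, non-conformity score quantiles,
#' pixel-wise quantiles -- goes through this one convention, so conformal
#' calibration and prediction are exactly index-based.
#'
#' A fuzz of `1e-9` is subtracted before taking the ceiling so that products
#' that are integers in exact arithmetic (e.g. `(1 - 9/187) * 187 = 178`)
#' are not pushed to the next order statistic by floating-point round-up,
#' in the same spirit as the fuzz in [stats::quantile()].
#'
#' @param values numeric vector of finite sample values (non-empty).
#' @param level quantile level in \[0, 1\].
#' @return the selected order statistic, a length-1 numeric.
#' @examples
#' empirical_quantile(1:10, 0.1)  # 1
#' empirical_quantile(1:10, 0.9)  # 9
#' empirical_quantile(c(3, 1, 2), 1)  # 3
#' @seealso [adjusted_levels()], [metric_cp()]
#' @export
empirical_quantile <- function(values, level) {
  if (length(values) == 0L) {
    stop("empty sample set", call. = FALSE)
  }
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("'values' must be a finite numeric vector", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 0 || level > 1) {
    stop("'level' must be a single number in [0, 1]", call. = FALSE)
  }
  m <- length(values)
  k <- max(1L, as.integer(ceiling(level * m - 1e-9)))
  sort.int(values, method = "quick")[k]
}

# Row-wise version of empirical_quantile for a pixels-x-samples matrix:
# returns the k-th order statistic of every row at the given level.
# Used by the pixel-wise baselines; one sort per row, same index rule.
row_empirical_quantile <- function(m, level) {
  ns <- ncol(m)
  k <- max(1L, as.integer(ceiling(level * ns - 1e-9)))
  apply(m, 1L, function(r) sort.int(r, method = "quick")[k])
}

#' Finite-sample adjusted mis-coverage rates
#'
#' Maps a nominal one-sided mis-coverage rate \eqn{\alpha} and the
#' calibration-set size \eqn{n} to the finite-sample adjusted rate
#' \eqn{\hat\alpha = \lfloor \alpha (n + 1) \rfloor / n}. The calibrated
#' quantile adjustments are the \eqn{(1 - \hat\alpha)}-th empirical
#' quantiles of the non-conformity scores; this discrete correction is what
#' yields the marginal coverage guarantee under exchangeability.
#'
#' When \eqn{\lfloor \alpha (n + 1) \rfloor = 0} the adjusted rate is 0 and
#' the score quantile degenerates to the sample maximum (the most
#' conservative choice); a warning is emitted that `n` is too small for the
#' requested level. A fuzz of `1e-9` is added before the floor to protect
#' integer-valued products (e.g. `0.7 * 10`) from floating-point round-down.
#'
#' @param n number of calibration subjects (>= 1).
#' @param alpha_lo,alpha_hi lower and upper nominal mis-coverage rates,
#'   each in \[0, 1) with `alpha_lo + alpha_hi < 1`.
#' @return named numeric vector `c(alpha_hat_lo = , alpha_hat_hi = )`.
#' @examples
#' adjusted_levels(596, 0.05, 0.05)  # both 29/596
#' @export
adjusted_levels <- function(n, alpha_lo, alpha_hi) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  check_rates(alpha_lo, alpha_hi)
  hat <- function(alpha) floor(alpha * (n + 1) + 1e-9) / n
  out <- c(alpha_hat_lo = hat(alpha_lo), alpha_hat_hi = hat(alpha_hi))
  small <- c(alpha_lo, alpha_hi) > 0 & out == 0
  if (any(small)) {
    warning(sprintf(
      "calibration set of n = %d is too small for level(s) %s; using the most conservative adjustment (score maximum)",
      n, paste(format(c(alpha_lo, alpha_hi)[small]), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

check_rates <- function(alpha_lo, alpha_hi) {
  ok <- function(a) is.numeric(a) && length(a) == 1L && !is.na(a) &&
    a >= 0 && a < 1
  if (!ok(alpha_lo) || !ok(alpha_hi)) {
    stop("mis-coverage rates must be single numbers in [0, 1)", call. = FALSE)
  }
  if (alpha_lo + alpha_hi >= 1) {
    stop("alpha_lo + alpha_hi must be < 1", call. = FALSE)
  }
  invisible(TRUE)
}
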