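#' Prediction intervals on a scalar metric
#'
#' A `prediction_interval` is a data frame with columns `lower` and `upper`
#' (one row per subject) and an optional `subject_id` column. Endpoints may
#' cross (`upper < lower`) after conformal adjustment; the interval length
#' is then reported as 0 by [interval_length()] and every ensemble member is
#' an outlier under [partition_ensemble()]. Endpoints are not clamped to the
#' metric's natural domain unless a clamp is requested explicitly at
#' prediction time.
#'
#' @param lower,upper numeric vectors of finite interval endpoints.
#' @param subject_id optional identifiers, recycled against the endpoints.
#' @return an object of class `prediction_interval` (a data frame).
#' @examples
#' prediction_interval(2, 5)
#' interval_length(prediction_interval(5, 2))  # clamped to 0
#' @export
prediction_interval <- function(lower, upper, subject_id = NULL) {
  if (length(lower) != length(upper)) {
    stop("'lower' and 'upper' must have equal length", call. = FALSE)
  }
  if (!is.numeric(lower) || !is.numeric(upper) ||
      !all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("interval endpoints must be finite numerics", call. = FALSE)
  }
  out <- data.frame(lower = as.numeric(lower), upper = as.numeric(upper))
  if (!is.null(subject_id)) {
    out <- cbind(subject_id = as.character(subject_id), out)
  }
  class(out) <- c("prediction_interval", "data.frame")
  out
}

# Coerce a user-supplied interval (length-2 numeric, list(lower, upper), or
# prediction_interval) to a one-row prediction_interval.
as_single_interval <- function(interval) {
  if (inherits(interval, "prediction_interval")) {
    if (nrow(interval) != 1L) {
      stop("expected a single prediction interval (one row)", call. = FALSE)
    }
    return(interval)
  }
  if (is.list(interval) && all(c("lower", "upper") %in% names(interval))) {
    return(prediction_interval(interval$lower, interval$upper))
  }
  if (is.numeric(interval) && length(interval) == 2L) {
    return(prediction_interval(interval[[1L]], interval[[2L]]))
  }
  stop("cannot interpret 'interval' as a prediction interval", call. = FALSE)
}

#' @export
print.prediction_interval <- function(x, digits = 4, ...) {
  cat(sprintf("Prediction interval(s) on the metric (%d subject%s)\n",
              nrow(x), if (nrow(x) == 1L) "" else "s"))
  y <- as.data.frame(x)
  y$length <- interval_length(x)
  print(format(y, digits = digits), ...)
  invisible(x)
}

#' Interval length with clamping at zero
#'
#' The length of a prediction interval is `upper - lower`, reported as 0
#' when the difference is negative (crossed endpoints), so lengths are
#' always comparable across methods.
#'
#' @param interval a [prediction_interval()] (any number of rows), a
#'   length-2 numeric `c(lower, upper)`, or a list with `lower`/`upper`.
#' @return numeric vector of non-negative lengths, one per row.
#' @export
interval_length <- function(interval) {
  if (!inherits(interval, "prediction_interval")) {
    interval <- as_single_interval(interval)
  }
  pmax(0, interval$upper - interval$lower)
}

#' Empirical coverage of prediction intervals
#'
#' Fraction of ground-truth metric values falling inside their subject's
#' closed interval \eqn{[L, U]}. Membership at an endpoint counts as
#' covered; a crossed interval (`upper < lower`) covers nothing.
#'
#' @param intervals a [prediction_interval()] with one row per subject.
#' @param truths numeric vector of ground-truth metric values, same length.
#' @return the covered fraction, in \[0, 1\].
#' @export
coverage <- function(intervals, truths) {
  if (!inherits(intervals, "prediction_interval")) {
    intervals <- as_single_interval(intervals)
  }
  if (length(truths) != nrow(intervals) || length(truths) < 1L) {
    stop("'truths' must align one-to-one with the intervals", call. = FALSE)
  }
  mean(truths >= intervals$lower & truths <= intervals$upper)
}
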