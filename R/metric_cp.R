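#' Non-conformity scores for one calibration subject
#'
#' For a subject with predicted-metric ensemble \eqn{\hat Y_i} and
#' ground-truth metric \eqn{Y_i}, the lower and upper non-conformity scores
#' are the signed gaps between the ensemble's one-sided sample quantiles and
#' the truth:
#' \deqn{s_{i,lo} = Q_{\alpha_{lo}}(\hat Y_i) - Y_i, \qquad
#'       s_{i,hi} = Y_i - Q_{1-\alpha_{hi}}(\hat Y_i).}
#' A positive lower score means the ensemble's lower quantile overshoots the
#' truth (the raw interval would miss from below); negative scores mean the
#' ensemble is already conservative on that side. Scores are used as-is, so
#' calibrated adjustments may be negative and tighten the interval.
#'
#' @param samples numeric vector, the subject's predicted metric ensemble.
#' @param truth the subject's ground-truth metric (finite scalar).
#' @param alpha_lo,alpha_hi one-sided mis-coverage rates in \[0, 1).
#' @return named numeric vector `c(s_lo = , s_hi = )`.
#' @examples
#' nonconformity_scores(1:10, truth = 5, 0.1, 0.1)  # both -4
#' @export
nonconformity_scores <- function(samples, truth, alpha_lo, alpha_hi) {
  check_rates(alpha_lo, alpha_hi)
  if (!is.numeric(truth) || length(truth) != 1L || !is.finite(truth)) {
    stop("'truth' must be a single finite number", call. = FALSE)
  }
  c(s_lo = empirical_quantile(samples, alpha_lo) - truth,
    s_hi = truth - empirical_quantile(samples, 1 - alpha_hi))
}

#' Calibrate metric-guided conformal prediction bounds
#'
#' Fits the split conformal calibration for a scalar image-derived metric:
#' given a calibration set of per-subject predicted-metric ensembles with
#' known ground truth, computes the lower/upper non-conformity scores of
#' every subject ([nonconformity_scores()]), the finite-sample adjusted
#' mis-coverage rates ([adjusted_levels()]), and the quantile adjustments
#' \deqn{q_{lo} = Q_{1-\hat\alpha_{lo}}(\{s_{i,lo}\}), \qquad
#'       q_{hi} = Q_{1-\hat\alpha_{hi}}(\{s_{i,hi}\}).}
#' [predict.metric_cp()] then turns a new subject's ensemble into the
#' prediction interval
#' \eqn{[Q_{\alpha_{lo}}(\hat Y) - q_{lo},\; Q_{1-\alpha_{hi}}(\hat Y) + q_{hi}]},
#' which under exchangeability of calibration and test subjects contains
#' the true metric with probability at least about
#' \eqn{1 - \alpha_{lo} - \alpha_{hi}} marginally.
#'
#' The two sides are calibrated independently from their own one-sided
#' score sets. The calibration data may be given as a `metric_pool` (see
#' [generate_metric_pool()]), as a list of numeric ensembles plus a vector
#' of truths, or as a long-format data frame (columns `subject_id`,
#' `metric_value`, optionally `sample_id`) plus a truth table (columns
#' `subject_id`, `truth_value`).
#'
#' @param x calibration ensembles: a `metric_pool`, a list of numeric
#'   vectors, or a long-format data frame.
#' @param truth ground-truth metric values: numeric vector aligned with the
#'   list, or a data frame `subject_id`/`truth_value` for the data-frame
#'   interface. Ignored when `x` is a `metric_pool`.
#' @param alpha_lo,alpha_hi lower/upper mis-coverage rates in \[0, 1) with
#'   `alpha_lo + alpha_hi < 1`. The nominal two-sided coverage target is
#'   `1 - alpha_lo - alpha_hi`.
#' @return an object of class `metric_cp`: a list with the adjustments
#'   `q_lo`, `q_hi`, the adjusted levels `alpha_hat_lo`, `alpha_hat_hi`,
#'   the calibration size `n`, the nominal rates, the per-subject score
#'   table `scores`, and the quantile-convention tag.
#' @examples
#' pool <- generate_metric_pool(n_subjects = 30, ns = 20, seed = 1)
#' fit <- metric_cp(pool, alpha_lo = 0.1, alpha_hi = 0.1)
#' coef(fit)
#' predict(fit, newdata = pool$ensembles[[1]])
#' @seealso [predict.metric_cp()], [metric_baseline_interval()],
#'   [run_split_experiment()]
#' @export
metric_cp <- function(x, truth = NULL, alpha_lo = 0.05, alpha_hi = 0.05) {
  check_rates(alpha_lo, alpha_hi)
  cal <- as_calibration_set(x, truth)
  n <- length(cal$ensembles)
  if (n < 1L) stop("empty calibration set", call. = FALSE)
  sc <- vapply(
    seq_len(n),
    function(i) nonconformity_scores(cal$ensembles[[i]], cal$truths[[i]],
                                     alpha_lo, alpha_hi),
    numeric(2)
  )
  hat <- adjusted_levels(n, alpha_lo, alpha_hi)
  fit <- structure(list(
    q_lo = empirical_quantile(sc["s_lo", ], 1 - hat[["alpha_hat_lo"]]),
    q_hi = empirical_quantile(sc["s_hi", ], 1 - hat[["alpha_hat_hi"]]),
    alpha_hat_lo = hat[["alpha_hat_lo"]],
    alpha_hat_hi = hat[["alpha_hat_hi"]],
    n = n,
    alpha_lo = alpha_lo,
    alpha_hi = alpha_hi,
    scores = data.frame(subject_id = cal$ids,
                        s_lo = sc["s_lo", ], s_hi = sc["s_hi", ],
                        row.names = NULL),
    quantile_convention = quantile_convention_tag(),
    call = match.call()
  ), class = "metric_cp")
  fit
}

quantile_convention_tag <- function() "lower-empirical/ceil(level*m)"

# Normalise the calibration inputs to list(ensembles, truths, ids).
as_calibration_set <- function(x, truth = NULL) {
  if (inherits(x, "metric_pool")) {
    if (!is.null(truth)) {
      stop("a metric_pool already carries its truths; pass the rates by name (alpha_lo = , alpha_hi = )",
           call. = FALSE)
    }
    return(list(ensembles = x$ensembles, truths = x$truths, ids = x$ids))
  }
  if (is.data.frame(x)) {
    if (!all(c("subject_id", "metric_value") %in% names(x))) {
      stop("long-format calibration data needs columns 'subject_id' and 'metric_value'",
           call. = FALSE)
    }
    if (is.data.frame(truth)) {
      if (!all(c("subject_id", "truth_value") %in% names(truth))) {
        stop("truth table needs columns 'subject_id' and 'truth_value'",
             call. = FALSE)
      }
      truths <- stats::setNames(truth$truth_value, truth$subject_id)
    } else if (is.numeric(truth) && !is.null(names(truth))) {
      truths <- truth
    } else {
      stop("with a long-format 'x', 'truth' must be a truth table or a named numeric vector",
           call. = FALSE)
    }
    ids <- names(truths)
    missing_ids <- setdiff(ids, unique(as.character(x$subject_id)))
    if (length(missing_ids)) {
      stop(sprintf("subject(s) %s in truth table missing from samples",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
    }
    if ("sample_id" %in% names(x)) x <- x[order(x$subject_id, x$sample_id), ]
    ens <- lapply(ids, function(id) x$metric_value[x$subject_id == id])
    return(list(ensembles = ens, truths = unname(truths), ids = ids))
  }
  if (is.list(x)) {
    if (!is.numeric(truth) || length(truth) != length(x)) {
      stop("'truth' must be a numeric vector with one value per ensemble",
           call. = FALSE)
    }
    ids <- names(x)
    if (is.null(ids)) ids <- as.character(seq_along(x))
    return(list(ensembles = unname(x), truths = unname(truth), ids = ids))
  }
  if (is.numeric(x)) {
    return(as_calibration_set(list(x), truth))
  }
  stop("cannot interpret calibration input", call. = FALSE)
}

#' Predict a conformal interval for new metric ensembles
#'
#' Applies the calibrated quantile adjustments to one or more test
#' ensembles: each interval is
#' \eqn{[Q_{\alpha_{lo}}(\hat Y) - q_{lo},\; Q_{1-\alpha_{hi}}(\hat Y) + q_{hi}]}
#' with the rates stored in the fit. With a single-sample ensemble
#' \eqn{\{y\}} this reduces to \eqn{[y - q_{lo}, y + q_{hi}]}. Endpoints
#' are not clamped to the metric's domain by default; pass e.g.
#' `domain = c(0, Inf)` to clamp a physically non-negative metric.
#'
#' @param object a fitted [metric_cp()] object.
#' @param newdata a numeric ensemble, a list of numeric ensembles, a
#'   `metric_pool`, or a long-format data frame with `subject_id` and
#'   `metric_value` columns.
#' @param domain optional length-2 numeric; endpoints are clamped into
#'   `[domain[1], domain[2]]` after adjustment.
#' @param ... unused.
#' @return a [prediction_interval()] with one row per test ensemble.
#' @export
predict.metric_cp <- function(object, newdata, domain = NULL, ...) {
  ens <- as_ensemble_list(newdata)
  lo <- vapply(ens$ensembles, empirical_quantile, numeric(1),
               level = object$alpha_lo)
  hi <- vapply(ens$ensembles, empirical_quantile, numeric(1),
               level = 1 - object$alpha_hi)
  lower <- lo - object$q_lo
  upper <- hi + object$q_hi
  if (!is.null(domain)) {
    stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] <= domain[2])
    lower <- pmin(pmax(lower, domain[1]), domain[2])
    upper <- pmin(pmax(upper, domain[1]), domain[2])
  }
  prediction_interval(lower, upper, subject_id = ens$ids)
}

# Normalise test inputs to list(ensembles, ids); a bare numeric vector is a
# single ensemble.
as_ensemble_list <- function(newdata) {
  if (inherits(newdata, "metric_pool")) {
    return(list(ensembles = newdata$ensembles, ids = newdata$ids))
  }
  if (is.numeric(newdata)) {
    if (length(newdata) < 1L) stop("empty sample set", call. = FALSE)
    return(list(ensembles = list(newdata), ids = NULL))
  }
  if (is.data.frame(newdata)) {
    if (!all(c("subject_id", "metric_value") %in% names(newdata))) {
      stop("long-format data needs columns 'subject_id' and 'metric_value'",
           call. = FALSE)
    }
    if ("sample_id" %in% names(newdata)) {
      newdata <- newdata[order(newdata$subject_id, newdata$sample_id), ]
    }
    ids <- unique(as.character(newdata$subject_id))
    ens <- lapply(ids, function(id) {
      newdata$metric_value[newdata$subject_id == id]
    })
    return(list(ensembles = ens, ids = ids))
  }
  if (is.list(newdata)) {
    if (length(newdata) < 1L) stop("empty sample set", call. = FALSE)
    return(list(ensembles = newdata, ids = names(newdata)))
  }
  stop("cannot interpret 'newdata' as metric ensembles", call. = FALSE)
}

#' @export
print.metric_cp <- function(x, digits = 4, ...) {
  cat("Metric-guided split conformal calibration\n")
  cat(sprintf("  calibration subjects: n = %d\n", x$n))
  cat(sprintf("  rates: alpha_lo = %g, alpha_hi = %g (nominal coverage %g)\n",
              x$alpha_lo, x$alpha_hi, 1 - x$alpha_lo - x$alpha_hi))
  cat(sprintf("  adjusted levels: alpha_hat_lo = %s, alpha_hat_hi = %s\n",
              format(x$alpha_hat_lo, digits = digits),
              format(x$alpha_hat_hi, digits = digits)))
  cat(sprintf("  quantile adjustments: q_lo = %s, q_hi = %s\n",
              format(x$q_lo, digits = digits),
              format(x$q_hi, digits = digits)))
  invisible(x)
}

#' @export
coef.metric_cp <- function(object, ...) {
  c(q_lo = object$q_lo, q_hi = object$q_hi)
}

#' Residuals of a conformal calibration fit
#'
#' Returns the per-subject non-conformity scores, the calibration-set
#' "residuals" of the fit: a matrix with columns `s_lo` and `s_hi`.
#'
#' @param object a fitted [metric_cp()] object.
#' @param ... unused.
#' @export
residuals.metric_cp <- function(object, ...) {
  if (is.null(object$scores)) {
    stop("this fit carries no per-subject scores (loaded from an adjustment file?)",
         call. = FALSE)
  }
  m <- as.matrix(object$scores[, c("s_lo", "s_hi")])
  rownames(m) <- object$scores$subject_id
  m
}

#' @export
summary.metric_cp <- function(object, ...) {
  structure(list(fit = object,
                 score_summary = if (!is.null(object$scores))
                   summary(object$scores[, c("s_lo", "s_hi")])),
            class = "summary.metric_cp")
}

#' @export
print.summary.metric_cp <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$score_summary)) {
    cat("\nNon-conformity score distribution:\n")
    print(x$score_summary)
  }
  invisible(x)
}

#' Plot the non-conformity score distributions
#'
#' Histograms of the lower and upper non-conformity scores with the
#' calibrated adjustments `q_lo` and `q_hi` marked; a quick visual check of
#' how miscalibrated the reconstruction ensembles are on each side.
#'
#' @param x a fitted [metric_cp()] object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.metric_cp <- function(x, ...) {
  sc <- residuals(x)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::hist(sc[, "s_lo"], main = "Lower scores", xlab = "s_lo", ...)
  graphics::abline(v = x$q_lo, col = 2, lwd = 2)
  graphics::hist(sc[, "s_hi"], main = "Upper scores", xlab = "s_hi", ...)
  graphics::abline(v = x$q_hi, col = 2, lwd = 2)
  invisible(x)
}
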