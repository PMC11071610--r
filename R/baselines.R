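#' Uncalibrated metric-quantile interval (Metric baseline)
#'
#' The naive interval \eqn{[Q_{\alpha_{lo}}(\hat Y),\; Q_{1-\alpha_{hi}}(\hat Y)]}
#' taken directly from a test subject's sampled metrics, with no conformal
#' adjustment. Identical to [predict.metric_cp()] with `q_lo = q_hi = 0`;
#' it under-covers whenever the reconstruction ensemble is biased or
#' under-dispersed relative to the truth.
#'
#' @param x a numeric ensemble, list of ensembles, `metric_pool`, or
#'   long-format data frame (as in [predict.metric_cp()]).
#' @param alpha_lo,alpha_hi one-sided mis-coverage rates.
#' @return a [prediction_interval()], one row per ensemble.
#' @examples
#' metric_baseline_interval(1:10, 0.1, 0.1)  # [1, 9]
#' @export
metric_baseline_interval <- function(x, alpha_lo = 0.05, alpha_hi = 0.05) {
  check_rates(alpha_lo, alpha_hi)
  ens <- as_ensemble_list(x)
  lo <- vapply(ens$ensembles, empirical_quantile, numeric(1), level = alpha_lo)
  hi <- vapply(ens$ensembles, empirical_quantile, numeric(1),
               level = 1 - alpha_hi)
  prediction_interval(lo, hi, subject_id = ens$ids)
}

#' Pixel-wise quantile bounds (Pixel baseline)
#'
#' Computes, independently at every pixel, the \eqn{\alpha_{lo}}-th and
#' \eqn{(1-\alpha_{hi})}-th empirical quantiles of intensity across the
#' sampled reconstructions, yielding a lower and an upper bound image.
#' Purely intensity-based: the metric function is never consulted.
#'
#' @param images list of identically shaped arrays or an array stack with
#'   samples on the last axis.
#' @param alpha_lo,alpha_hi one-sided mis-coverage rates.
#' @return an object of class `pixel_bounds`: list with arrays `lower` and
#'   `upper` of the common image shape.
#' @export
pixel_baseline_bounds <- function(images, alpha_lo = 0.05, alpha_hi = 0.05) {
  check_rates(alpha_lo, alpha_hi)
  images <- as_image_list(images)
  shp <- dim(images[[1]]) %||% length(images[[1]])
  m <- vapply(images, as.numeric, numeric(prod(shp)))
  m <- matrix(m, nrow = prod(shp))
  structure(list(
    lower = array(row_empirical_quantile(m, alpha_lo), dim = shp),
    upper = array(row_empirical_quantile(m, 1 - alpha_hi), dim = shp)
  ), class = "pixel_bounds")
}

#' @export
print.pixel_bounds <- function(x, ...) {
  cat(sprintf("Pixel-wise bound pair, image shape %s\n",
              paste(dim(x$lower), collapse = "x")))
  cat(sprintf("  lower in [%s, %s]; upper in [%s, %s]\n",
              format(min(x$lower)), format(max(x$lower)),
              format(min(x$upper)), format(max(x$upper))))
  if (!is.null(x$q_lo)) cat("  conformal per-pixel adjustments attached\n")
  invisible(x)
}

#' Conformalised pixel-wise bounds (Pixel CP baseline)
#'
#' Treats every pixel as an independent scalar metric and runs the same
#' split conformal machinery as [metric_cp()] at each one: per-pixel
#' ensemble quantiles, per-pixel non-conformity scores against the
#' ground-truth image, per-pixel quantile adjustments at the finite-sample
#' adjusted levels, then adjusted bounds for the test ensemble. On 1x1
#' images this reduces exactly to the scalar calibration.
#'
#' @param cal_images list over calibration subjects; each element a list of
#'   arrays or an array stack (samples on the last axis).
#' @param cal_truth_images list of ground-truth images, shapes matching.
#' @param test_images the test subject's ensemble (list or stack).
#' @param alpha_lo,alpha_hi one-sided mis-coverage rates.
#' @return a `pixel_bounds` object with extra arrays `q_lo` and `q_hi`
#'   holding the per-pixel adjustments.
#' @export
pixel_cp_bounds <- function(cal_images, cal_truth_images, test_images,
                            alpha_lo = 0.05, alpha_hi = 0.05) {
  check_rates(alpha_lo, alpha_hi)
  n <- length(cal_images)
  if (n < 1L || length(cal_truth_images) != n) {
    stop("need one truth image per calibration subject", call. = FALSE)
  }
  test_images <- as_image_list(test_images)
  shp <- dim(test_images[[1]]) %||% length(test_images[[1]])
  npix <- prod(shp)

  flat <- function(imgs) {
    imgs <- as_image_list(imgs)
    matrix(vapply(imgs, as.numeric, numeric(npix)), nrow = npix)
  }
  s_lo <- matrix(NA_real_, nrow = npix, ncol = n)
  s_hi <- matrix(NA_real_, nrow = npix, ncol = n)
  for (i in seq_len(n)) {
    mi <- flat(cal_images[[i]])
    ti <- as.numeric(cal_truth_images[[i]])
    if (length(ti) != npix) stop("image shape mismatch", call. = FALSE)
    s_lo[, i] <- row_empirical_quantile(mi, alpha_lo) - ti
    s_hi[, i] <- ti - row_empirical_quantile(mi, 1 - alpha_hi)
  }
  hat <- adjusted_levels(n, alpha_lo, alpha_hi)
  q_lo <- row_empirical_quantile(s_lo, 1 - hat[["alpha_hat_lo"]])
  q_hi <- row_empirical_quantile(s_hi, 1 - hat[["alpha_hat_hi"]])

  mt <- flat(test_images)
  structure(list(
    lower = array(row_empirical_quantile(mt, alpha_lo) - q_lo, dim = shp),
    upper = array(row_empirical_quantile(mt, 1 - alpha_hi) + q_hi, dim = shp),
    q_lo = array(q_lo, dim = shp),
    q_hi = array(q_hi, dim = shp)
  ), class = "pixel_bounds")
}

#' Score a pixel-bound pair on a scalar metric
#'
#' Maps a pixel-space bound pair to a metric-space interval so pixel
#' methods can be evaluated on metric coverage: applies the metric to both
#' bound images and orders the two values. The min/max ordering matters
#' because a metric need not be monotone in pixel intensity -- the
#' lower-bound image can carry the larger metric value (e.g. windowed fat
#' counts), and adjusted pixel bounds can cross.
#'
#' @param bounds a `pixel_bounds` pair.
#' @param metric a [metric_function()] or plain function `image -> scalar`.
#' @param ... extra arguments for a plain-function `metric`.
#' @return a one-row [prediction_interval()].
#' @export
metric_interval_from_pixel_bounds <- function(bounds, metric, ...) {
  if (!inherits(bounds, "pixel_bounds")) {
    stop("'bounds' must be a pixel_bounds object", call. = FALSE)
  }
  vals <- apply_metric(list(bounds$lower, bounds$upper), metric, ...)
  prediction_interval(min(vals), max(vals))
}
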