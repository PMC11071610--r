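#' A subject's reconstruction ensemble
#'
#' Bundles the `ns` sampled reconstructions of one subject with their
#' metric values, aligned index-for-index, for bound-image retrieval and
#' inlier/outlier partitioning. Images may be omitted (`images = NULL`)
#' when only metric-space retrieval is needed.
#'
#' @param images list of identically shaped numeric arrays, an array stack
#'   with samples on the last axis, or `NULL`.
#' @param metrics numeric vector of per-image metric values.
#' @param subject_id optional identifier.
#' @return an object of class `reconstruction_ensemble`.
#' @export
reconstruction_ensemble <- function(images = NULL, metrics, subject_id = NULL) {
  if (!is.numeric(metrics) || length(metrics) < 1L || !all(is.finite(metrics))) {
    stop("'metrics' must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (!is.null(images)) {
    images <- as_image_list(images)
    if (length(images) != length(metrics)) {
      stop("'images' and 'metrics' must have equal length", call. = FALSE)
    }
  }
  structure(list(images = images, metrics = as.numeric(metrics),
                 subject_id = subject_id),
            class = "reconstruction_ensemble")
}

#' @export
print.reconstruction_ensemble <- function(x, ...) {
  cat(sprintf("Reconstruction ensemble%s: ns = %d samples%s\n",
              if (is.null(x$subject_id)) "" else
                sprintf(" for subject '%s'", x$subject_id),
              length(x$metrics),
              if (is.null(x$images)) " (metrics only)" else
                sprintf(", image shape %s",
                        paste(dim(x$images[[1]]) %||% length(x$images[[1]]),
                              collapse = "x"))))
  cat("  metric range: [", format(min(x$metrics)), ", ",
      format(max(x$metrics)), "]\n", sep = "")
  invisible(x)
}

ensemble_metrics <- function(ens) {
  if (inherits(ens, "reconstruction_ensemble")) return(ens$metrics)
  if (is.numeric(ens)) {
    if (length(ens) < 1L) stop("empty ensemble", call. = FALSE)
    return(ens)
  }
  stop("expected a reconstruction_ensemble or a numeric metric vector",
       call. = FALSE)
}

#' Retrieve the nearest-neighbour bound reconstructions
#'
#' Maps a metric prediction interval back into image space: the lower
#' (upper) bound reconstruction is the ensemble member whose metric value
#' is closest in absolute distance to the interval's lower (upper)
#' endpoint, by exhaustive search. Ties are broken toward the smallest
#' index, deterministically.
#'
#' @param ens a [reconstruction_ensemble()] or a numeric vector of the
#'   ensemble's metric values.
#' @param interval a single prediction interval ([prediction_interval()],
#'   `c(lower, upper)`, or a list with `lower`/`upper`).
#' @return named integer vector `c(lower_index = , upper_index = )`.
#' @examples
#' retrieve_bound_images(c(1, 5, 9), c(4.4, 9.6))  # 2, 3
#' @export
retrieve_bound_images <- function(ens, interval) {
  m <- ensemble_metrics(ens)
  interval <- as_single_interval(interval)
  c(lower_index = which.min(abs(m - interval$lower)),
    upper_index = which.min(abs(m - interval$upper)))
}

#' Partition an ensemble into inliers and outliers
#'
#' An ensemble member is an inlier when its metric lies in the closed
#' prediction interval \eqn{[L, U]} (endpoints included) and an outlier
#' otherwise; the two index sets always partition `1:ns`. If the interval
#' is empty (`U < L`, which calibrated endpoints can produce), every member
#' is an outlier and a warning is emitted.
#'
#' Outliers are reconstructions that may look plausible as images but whose
#' metric value is statistically unlikely given the calibrated bounds --
#' the ensemble members worth flagging for review.
#'
#' @inheritParams retrieve_bound_images
#' @return list with integer vectors `inliers` and `outliers`.
#' @examples
#' partition_ensemble(c(1, 5, 9), c(2, 8))  # inliers 2, outliers 1 3
#' @export
partition_ensemble <- function(ens, interval) {
  m <- ensemble_metrics(ens)
  interval <- as_single_interval(interval)
  if (interval$upper < interval$lower) {
    warning("empty prediction interval (upper < lower): all samples are outliers",
            call. = FALSE)
  }
  inside <- m >= interval$lower & m <= interval$upper
  list(inliers = which(inside), outliers = which(!inside))
}

#' Full metric-space retrieval report for one subject
#'
#' Combines bound-image retrieval and the inlier/outlier partition into a
#' single report: indices and metric values of the reconstructions nearest
#' the interval endpoints, plus the index sets.
#'
#' @inheritParams retrieve_bound_images
#' @return an object of class `retrieval_report`.
#' @export
retrieval_report <- function(ens, interval) {
  m <- ensemble_metrics(ens)
  interval <- as_single_interval(interval)
  idx <- retrieve_bound_images(m, interval)
  part <- partition_ensemble(m, interval)
  structure(list(
    interval = interval,
    lower_index = unname(idx[["lower_index"]]),
    upper_index = unname(idx[["upper_index"]]),
    lower_metric = m[[idx[["lower_index"]]]],
    upper_metric = m[[idx[["upper_index"]]]],
    inliers = part$inliers,
    outliers = part$outliers,
    ns = length(m)
  ), class = "retrieval_report")
}

#' @export
print.retrieval_report <- function(x, digits = 4, ...) {
  cat("Metric-space retrieval report\n")
  cat(sprintf("  interval: [%s, %s] (length %s)\n",
              format(x$interval$lower, digits = digits),
              format(x$interval$upper, digits = digits),
              format(interval_length(x$interval), digits = digits)))
  cat(sprintf("  lower-bound image: index %d (metric %s)\n",
              x$lower_index, format(x$lower_metric, digits = digits)))
  cat(sprintf("  upper-bound image: index %d (metric %s)\n",
              x$upper_index, format(x$upper_metric, digits = digits)))
  cat(sprintf("  inliers: %d / %d; outliers: %s\n",
              length(x$inliers), x$ns,
              if (length(x$outliers)) paste(x$outliers, collapse = ", ")
              else "none"))
  invisible(x)
}
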