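#' Normalised interval length
#'
#' A method's mean interval length divided by the reference (calibrated
#' metric) method's mean interval length, removing arbitrary scaling
#' differences across metrics. The reference normalises to 1 by
#' construction.
#'
#' @param method_mean the method's mean interval length (>= 0).
#' @param reference_mean the reference method's mean interval length (> 0).
#' @return `method_mean / reference_mean`.
#' @export
normalized_length <- function(method_mean, reference_mean) {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      is.na(reference_mean) || reference_mean <= 0) {
    stop("degenerate reference", call. = FALSE)
  }
  method_mean / reference_mean
}

#' Repeated random-split coverage experiment
#'
#' Evaluates calibration methods by repeated random calibration/testing
#' splits of an exchangeable subject pool: for each split, the calibration
#' part fits the conformal adjustments, every method produces a prediction
#' interval for each test subject, and test coverage and interval lengths
#' are recorded. Results are averaged across splits (arithmetic mean), and
#' each method's mean interval length is normalised by the calibrated
#' metric method's.
#'
#' Methods:
#' \describe{
#'   \item{`metric_cp`}{the calibrated interval of [metric_cp()] /
#'     [predict.metric_cp()] (the reference method, always computed).}
#'   \item{`metric`}{the uncalibrated [metric_baseline_interval()].}
#'   \item{`pixel`}{[pixel_baseline_bounds()] scored on the metric via
#'     [metric_interval_from_pixel_bounds()]; needs a pool with images.}
#'   \item{`pixel_cp`}{[pixel_cp_bounds()] scored the same way; needs a
#'     pool with images and truth images.}
#' }
#'
#' Splits draw `floor(cal_fraction * N)` calibration subjects uniformly at
#' random without replacement; the remainder are test subjects. Per-subject
#' ensemble quantiles and non-conformity scores are computed once and
#' reused across splits (ensembles are fixed per subject; only the split
#' assignment is re-randomised). The whole experiment is a deterministic
#' function of the pool, settings and `seed`.
#'
#' @param pool a [metric_pool()]; for the pixel methods it must carry
#'   `images`, `truth_images` and a `metric`.
#' @param methods character subset of
#'   `c("metric_cp", "metric", "pixel", "pixel_cp")`.
#' @param alpha_lo,alpha_hi one-sided mis-coverage rates.
#' @param n_splits number of random splits.
#' @param cal_fraction fraction of subjects used for calibration, in (0, 1).
#' @param seed RNG seed for the split draws.
#' @param verbose emit progress messages every 100 splits?
#' @return a data frame of class `cp_evaluation` with one row per method:
#'   `method`, `coverage`, `mean_interval_length`,
#'   `normalized_interval_length`, `n_splits`, `seed`. Per-split coverages
#'   and mean lengths are attached as attribute `"per_split"`.
#' @examples
#' pool <- generate_metric_pool(n_subjects = 40, ns = 30, seed = 2)
#' run_split_experiment(pool, methods = c("metric_cp", "metric"),
#'                      n_splits = 20, seed = 3)
#' @export
run_split_experiment <- function(pool,
                                 methods = c("metric_cp", "metric"),
                                 alpha_lo = 0.05, alpha_hi = 0.05,
                                 n_splits = 500, cal_fraction = 0.75,
                                 seed = 1, verbose = FALSE) {
  stopifnot(inherits(pool, "metric_pool"))
  check_rates(alpha_lo, alpha_hi)
  methods <- match.arg(methods,
                       c("metric_cp", "metric", "pixel", "pixel_cp"),
                       several.ok = TRUE)
  if (!is.numeric(cal_fraction) || cal_fraction <= 0 || cal_fraction >= 1) {
    stop("'cal_fraction' must be in (0, 1)", call. = FALSE)
  }
  N <- length(pool$ensembles)
  n_cal <- floor(cal_fraction * N)
  if (N < 4L || n_cal < 1L || N - n_cal < 1L) {
    stop("pool too small for the requested calibration fraction",
         call. = FALSE)
  }
  pixel_methods <- intersect(methods, c("pixel", "pixel_cp"))
  if (length(pixel_methods)) {
    if (is.null(pool$images) || is.null(pool$metric)) {
      stop("pixel methods need a pool with images and a metric function",
           call. = FALSE)
    }
    if ("pixel_cp" %in% methods && is.null(pool$truth_images)) {
      stop("'pixel_cp' needs ground-truth images in the pool", call. = FALSE)
    }
  }
  all_methods <- union("metric_cp", methods)

  # Per-subject quantities that do not depend on the split.
  base_lo <- vapply(pool$ensembles, empirical_quantile, numeric(1),
                    level = alpha_lo)
  base_hi <- vapply(pool$ensembles, empirical_quantile, numeric(1),
                    level = 1 - alpha_hi)
  s_lo <- base_lo - pool$truths
  s_hi <- pool$truths - base_hi

  px <- if (length(pixel_methods)) {
    precompute_pixel_state(pool, alpha_lo, alpha_hi,
                           need_cp = "pixel_cp" %in% methods)
  }

  cov_mat <- matrix(NA_real_, n_splits, length(all_methods),
                    dimnames = list(NULL, all_methods))
  len_mat <- cov_mat

  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      cal <- sample.int(N, n_cal)
      test <- setdiff(seq_len(N), cal)
      truths_test <- pool$truths[test]

      hat <- suppressWarnings(adjusted_levels(n_cal, alpha_lo, alpha_hi))
      q_lo <- empirical_quantile(s_lo[cal], 1 - hat[["alpha_hat_lo"]])
      q_hi <- empirical_quantile(s_hi[cal], 1 - hat[["alpha_hat_hi"]])

      for (m in all_methods) {
        iv <- switch(m,
          metric_cp = prediction_interval(base_lo[test] - q_lo,
                                          base_hi[test] + q_hi),
          metric = prediction_interval(base_lo[test], base_hi[test]),
          pixel = prediction_interval(px$pixel_lower[test],
                                      px$pixel_upper[test]),
          pixel_cp = pixel_cp_split_intervals(px, cal, test,
                                              alpha_lo, alpha_hi)
        )
        cov_mat[s, m] <- coverage(iv, truths_test)
        len_mat[s, m] <- mean(interval_length(iv))
      }
      if (verbose && s %% 100L == 0L) {
        message(sprintf("split %d / %d", s, n_splits))
      }
    }
  })

  ref_len <- mean(len_mat[, "metric_cp"])
  out <- data.frame(
    method = all_methods,
    coverage = colMeans(cov_mat),
    mean_interval_length = colMeans(len_mat),
    # undefined when the reference interval is degenerate (length 0)
    normalized_interval_length = if (ref_len > 0) vapply(
      colMeans(len_mat), normalized_length, numeric(1),
      reference_mean = ref_len) else NA_real_,
    n_splits = n_splits,
    seed = seed,
    row.names = NULL
  )
  attr(out, "per_split") <- list(coverage = cov_mat, mean_length = len_mat)
  class(out) <- c("cp_evaluation", "data.frame")
  out
}

# Flattened per-subject pixel quantiles and scores, computed once.
precompute_pixel_state <- function(pool, alpha_lo, alpha_hi, need_cp) {
  N <- length(pool$ensembles)
  shp <- dim(as_image_list(pool$images[[1]])[[1]])
  npix <- prod(shp)
  plo <- matrix(NA_real_, npix, N)
  phi <- matrix(NA_real_, npix, N)
  for (i in seq_len(N)) {
    imgs <- as_image_list(pool$images[[i]])
    m <- matrix(vapply(imgs, as.numeric, numeric(npix)), nrow = npix)
    plo[, i] <- row_empirical_quantile(m, alpha_lo)
    phi[, i] <- row_empirical_quantile(m, 1 - alpha_hi)
  }
  st <- list(shp = shp, metric = pool$metric, plo = plo, phi = phi)
  # Pixel baseline: per-subject metric interval from that subject's own
  # pixel-quantile bound pair (split-independent).
  bl <- numeric(N)
  bu <- numeric(N)
  for (i in seq_len(N)) {
    b <- structure(list(lower = array(plo[, i], dim = shp),
                        upper = array(phi[, i], dim = shp)),
                   class = "pixel_bounds")
    iv <- metric_interval_from_pixel_bounds(b, pool$metric)
    bl[i] <- iv$lower
    bu[i] <- iv$upper
  }
  st$pixel_lower <- bl
  st$pixel_upper <- bu
  if (need_cp) {
    tr <- matrix(vapply(pool$truth_images, as.numeric, numeric(npix)),
                 nrow = npix)
    st$s_lo <- plo - tr
    st$s_hi <- tr - phi
  }
  st
}

pixel_cp_split_intervals <- function(px, cal, test, alpha_lo, alpha_hi) {
  hat <- suppressWarnings(adjusted_levels(length(cal), alpha_lo, alpha_hi))
  q_lo <- row_empirical_quantile(px$s_lo[, cal, drop = FALSE],
                                 1 - hat[["alpha_hat_lo"]])
  q_hi <- row_empirical_quantile(px$s_hi[, cal, drop = FALSE],
                                 1 - hat[["alpha_hat_hi"]])
  lower <- numeric(length(test))
  upper <- numeric(length(test))
  for (k in seq_along(test)) {
    i <- test[k]
    b <- structure(list(lower = array(px$plo[, i] - q_lo, dim = px$shp),
                        upper = array(px$phi[, i] + q_hi, dim = px$shp)),
                   class = "pixel_bounds")
    iv <- metric_interval_from_pixel_bounds(b, px$metric)
    lower[k] <- iv$lower
    upper[k] <- iv$upper
  }
  prediction_interval(lower, upper)
}

#' @export
print.cp_evaluation <- function(x, digits = 4, ...) {
  cat(sprintf("Random-split evaluation: %d splits, seed %d\n",
              x$n_splits[1], x$seed[1]))
  print(format(as.data.frame(x)[, c("method", "coverage",
                                    "mean_interval_length",
                                    "normalized_interval_length")],
               digits = digits), row.names = FALSE, ...)
  invisible(x)
}
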