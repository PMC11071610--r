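# Run code under a given RNG seed without disturbing the caller's RNG
# state. All stochastic routines in the package route through this, so
# generation is a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a pool of calibration/test subjects
#'
#' A `metric_pool` holds exchangeable subjects for calibration and
#' evaluation: per-subject predicted-metric ensembles, ground-truth metric
#' values, and (optionally) the image ensembles and truth images behind
#' them, for the pixel-space baselines.
#'
#' @param ensembles list of numeric vectors, one ensemble per subject.
#' @param truths numeric vector of ground-truth metrics, one per subject.
#' @param ids optional subject identifiers (default `"s1"`, `"s2"`, ...).
#' @param images optional list of per-subject image ensembles (each a list
#'   of arrays or an array stack).
#' @param truth_images optional list of per-subject ground-truth images.
#' @param metric optional [metric_function()] linking images to metrics.
#' @return an object of class `metric_pool`.
#' @export
metric_pool <- function(ensembles, truths, ids = NULL, images = NULL,
                        truth_images = NULL, metric = NULL) {
  if (!is.list(ensembles) || length(ensembles) < 1L) {
    stop("'ensembles' must be a non-empty list", call. = FALSE)
  }
  if (length(truths) != length(ensembles) || !all(is.finite(truths))) {
    stop("'truths' must be finite, one per ensemble", call. = FALSE)
  }
  ok <- vapply(ensembles, function(e)
    is.numeric(e) && length(e) >= 1L && all(is.finite(e)), logical(1))
  if (!all(ok)) stop("every ensemble must be non-empty and finite", call. = FALSE)
  if (is.null(ids)) ids <- paste0("s", seq_along(ensembles))
  if (!is.null(images) && length(images) != length(ensembles)) {
    stop("'images' must have one ensemble per subject", call. = FALSE)
  }
  if (!is.null(truth_images) && length(truth_images) != length(ensembles)) {
    stop("'truth_images' must have one image per subject", call. = FALSE)
  }
  structure(list(ensembles = ensembles, truths = as.numeric(truths),
                 ids = as.character(ids), images = images,
                 truth_images = truth_images, metric = metric),
            class = "metric_pool")
}

#' @export
print.metric_pool <- function(x, ...) {
  ns <- lengths(x$ensembles)
  cat(sprintf("Metric pool: %d subjects, ns = %s samples each%s\n",
              length(x$ensembles),
              if (length(unique(ns)) == 1L) ns[1]
              else sprintf("%d-%d", min(ns), max(ns)),
              if (is.null(x$images)) "" else " (with images)"))
  cat(sprintf("  truth range: [%s, %s]\n",
              format(min(x$truths)), format(max(x$truths))))
  invisible(x)
}

#' Generate an exchangeable synthetic pool of metric ensembles
#'
#' Emulates the calibration data produced by a probabilistic reconstruction
#' pipeline: each subject has a latent ground-truth metric
#' \eqn{Y_i} drawn from the truth distribution, and an ensemble of `ns`
#' predicted metrics
#' \deqn{\hat Y_{i,j} = Y_i + \mathrm{bias} +
#'       \mathrm{dispersion\_factor} \cdot \varepsilon_{i,j}, \quad
#'       \varepsilon_{i,j} \sim N(0, \mathrm{noise\_sd}^2),}
#' so `bias` models a systematically shifted reconstruction algorithm and
#' `dispersion_factor` a mis-stated spread. With probability
#' `outlier_rate` a sample is additionally displaced by
#' `+/- outlier_scale * noise_sd` (random sign), emulating hallucinated
#' reconstructions with extreme metric values. Subjects are i.i.d., hence
#' exchangeable between calibration and test roles.
#'
#' Defaults describe a deliberately miscalibrated pipeline (bias 1.5 times
#' the noise SD, spread inflated 1.5x) around a truth distribution
#' N(100, 15^2), with `ns = 100` samples per subject.
#'
#' @param n_subjects number of subjects.
#' @param ns samples per subject (>= 1).
#' @param truth_mean,truth_sd mean and SD of the truth distribution.
#' @param truth_distribution `"normal"` or `"t"` (scaled Student t with
#'   `df` degrees of freedom, for heavy-tailed truths).
#' @param df degrees of freedom for the t option.
#' @param bias additive offset of predictions vs truth (metric units).
#' @param noise_sd SD of the per-sample prediction noise (>= 0).
#' @param dispersion_factor multiplier on the noise SD (1 = well
#'   calibrated spread).
#' @param outlier_rate probability a sample is an outlier, in \[0, 1).
#' @param outlier_scale outlier displacement in units of `noise_sd`.
#' @param seed RNG seed; the pool is a pure function of the arguments.
#' @return a [metric_pool()].
#' @examples
#' pool <- generate_metric_pool(n_subjects = 20, ns = 50, seed = 7)
#' pool
#' @export
generate_metric_pool <- function(n_subjects = 250, ns = 100,
                                 truth_mean = 100, truth_sd = 15,
                                 truth_distribution = c("normal", "t"),
                                 df = 3,
                                 bias = 7.5, noise_sd = 5,
                                 dispersion_factor = 1.5,
                                 outlier_rate = 0, outlier_scale = 4,
                                 seed = 1) {
  truth_distribution <- match.arg(truth_distribution)
  stopifnot(n_subjects >= 1, ns >= 1, noise_sd >= 0, dispersion_factor >= 0,
            outlier_rate >= 0, outlier_rate < 1, truth_sd >= 0)
  with_seed(seed, {
    truths <- switch(truth_distribution,
      normal = stats::rnorm(n_subjects, truth_mean, truth_sd),
      t = truth_mean + truth_sd * stats::rt(n_subjects, df = df)
    )
    ensembles <- lapply(truths, function(y) {
      s <- y + bias + dispersion_factor * stats::rnorm(ns, 0, noise_sd)
      if (outlier_rate > 0) {
        flag <- stats::runif(ns) < outlier_rate
        if (any(flag)) {
          sign <- sample(c(-1, 1), sum(flag), replace = TRUE)
          s[flag] <- s[flag] + sign * outlier_scale * noise_sd
        }
      }
      s
    })
    metric_pool(ensembles, truths)
  })
}

#' Specification of a CT-like fat phantom
#'
#' Describes a square synthetic CT slice whose fat content is known by
#' construction: `fat_region_pixels` pixels take the value `fat_hu`
#' (default -100 HU, the centre of the adipose window) on a uniform
#' background (default 0 HU, i.e. water, outside the window), so
#' [fat_volume()] of the truth image is exactly
#' `fat_region_pixels * slice_thickness`.
#'
#' @param image_size pixels per side.
#' @param background_hu background attenuation (HU), outside the fat window.
#' @param fat_hu attenuation of fat pixels (HU), inside the window.
#' @param fat_region_pixels number of fat pixels (<= `image_size^2`).
#' @param slice_thickness slice thickness in mm.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64, background_hu = 0, fat_hu = -100,
                         fat_region_pixels = 800, slice_thickness = 3) {
  stopifnot(image_size >= 1, slice_thickness > 0, fat_region_pixels >= 0)
  if (fat_region_pixels > image_size^2) {
    stop("fat region exceeds image", call. = FALSE)
  }
  structure(list(image_size = image_size, background_hu = background_hu,
                 fat_hu = fat_hu, fat_region_pixels = fat_region_pixels,
                 slice_thickness = slice_thickness),
            class = "phantom_spec")
}

# Deterministic fill order for the fat blob: pixels sorted by distance
# from the image centre (ties by linear index), so any count k gives a
# roughly circular region nested across counts.
phantom_fill_order <- function(image_size) {
  ctr <- (image_size + 1) / 2
  g <- expand.grid(row = seq_len(image_size), col = seq_len(image_size))
  d <- (g$row - ctr)^2 + (g$col - ctr)^2
  order(d, seq_len(image_size^2))
}

phantom_image <- function(spec, n_fat, fill_order) {
  img <- matrix(spec$background_hu, spec$image_size, spec$image_size)
  n_fat <- max(0L, min(as.integer(n_fat), spec$image_size^2))
  if (n_fat > 0L) img[fill_order[seq_len(n_fat)]] <- spec$fat_hu
  img
}

#' Generate one subject's phantom reconstruction ensemble
#'
#' Builds a ground-truth phantom image from `spec` and `ns` "reconstructed"
#' phantoms whose fat-pixel counts follow the same bias/noise law as the
#' scalar generator: count_j = round(truth_count + bias +
#' dispersion_factor * N(0, noise_sd)), clamped into the image. The
#' returned ensemble carries [fat_volume()] metrics computed from the
#' actual images, so the full image pipeline can be exercised end-to-end.
#'
#' @param spec a [phantom_spec()].
#' @param ns reconstructions per subject.
#' @param bias additive bias on the fat-pixel count.
#' @param noise_sd SD of the count noise.
#' @param dispersion_factor multiplier on the noise SD.
#' @param seed RNG seed.
#' @return list with elements `ensemble` (a [reconstruction_ensemble()]
#'   whose metrics are fat volumes) and `truth_image`.
#' @export
generate_phantom_ensemble <- function(spec, ns = 20, bias = 60,
                                      noise_sd = 40, dispersion_factor = 1,
                                      seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"), ns >= 1, noise_sd >= 0)
  fill <- phantom_fill_order(spec$image_size)
  truth_image <- phantom_image(spec, spec$fat_region_pixels, fill)
  with_seed(seed, {
    counts <- round(spec$fat_region_pixels + bias +
                      dispersion_factor * stats::rnorm(ns, 0, noise_sd))
    counts <- pmax(0, pmin(counts, spec$image_size^2))
    images <- lapply(counts, function(k) phantom_image(spec, k, fill))
    metrics <- apply_metric(images, fat_volume,
                            slice_thickness = spec$slice_thickness)
    list(ensemble = reconstruction_ensemble(images, metrics),
         truth_image = truth_image)
  })
}

#' Generate a pool of phantom subjects for the image pipeline
#'
#' Draws per-subject truth fat-pixel counts (rounded normal, clamped into
#' the image), builds each subject's phantom reconstruction ensemble with
#' [generate_phantom_ensemble()], and computes the fat-volume metrics from
#' the images, yielding an exchangeable [metric_pool()] whose scalar law
#' matches [generate_metric_pool()] up to count rounding. Set
#' `keep_images = TRUE` to retain the image ensembles (needed by the
#' pixel-space baselines); by default images are dropped after the metric
#' is computed.
#'
#' @param n_subjects number of subjects.
#' @param image_size phantom side length in pixels.
#' @param count_mean,count_sd mean and SD of the truth fat-pixel count.
#' @param ns reconstructions per subject.
#' @param bias,noise_sd,dispersion_factor count perturbation law, as in
#'   [generate_phantom_ensemble()].
#' @param slice_thickness slice thickness in mm.
#' @param keep_images retain image ensembles and truth images in the pool?
#' @param seed RNG seed.
#' @return a [metric_pool()] whose metric is fat volume.
#' @export
generate_phantom_pool <- function(n_subjects = 100, image_size = 64,
                                  count_mean = 800, count_sd = 120,
                                  ns = 20, bias = 60, noise_sd = 40,
                                  dispersion_factor = 1,
                                  slice_thickness = 3,
                                  keep_images = FALSE, seed = 1) {
  stopifnot(n_subjects >= 1)
  with_seed(seed, {
    counts <- round(stats::rnorm(n_subjects, count_mean, count_sd))
    counts <- pmax(0, pmin(counts, image_size^2))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    ensembles <- vector("list", n_subjects)
    truths <- numeric(n_subjects)
    images <- if (keep_images) vector("list", n_subjects)
    truth_images <- if (keep_images) vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      spec <- phantom_spec(image_size = image_size,
                           fat_region_pixels = counts[i],
                           slice_thickness = slice_thickness)
      ph <- generate_phantom_ensemble(spec, ns = ns, bias = bias,
                                      noise_sd = noise_sd,
                                      dispersion_factor = dispersion_factor,
                                      seed = sub_seeds[i])
      ensembles[[i]] <- ph$ensemble$metrics
      truths[i] <- fat_volume(ph$truth_image,
                              slice_thickness = slice_thickness)
      if (keep_images) {
        images[[i]] <- ph$ensemble$images
        truth_images[[i]] <- ph$truth_image
      }
    }
    metric_pool(ensembles, truths, images = images,
                truth_images = truth_images,
                metric = metric_function("fat_volume", fat_volume,
                                         list(slice_thickness = slice_thickness)))
  })
}
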