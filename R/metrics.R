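#' Fat volume of a CT slice by Hounsfield-unit windowing
#'
#' Counts the pixels whose attenuation falls in the adipose-tissue window
#' (default the closed range \[-150, -50\] HU, endpoints inclusive) and
#' multiplies the count by the slice thickness and the pixel area. The
#' default `pixel_area = 1` reproduces the bare pixels-times-thickness
#' definition; pass the physical in-plane spacing (mm^2 per pixel) for a
#' volume in mm^3.
#'
#' @param image 2-D (or higher) numeric array of Hounsfield units, finite.
#' @param slice_thickness slice thickness in mm, > 0.
#' @param pixel_area in-plane area per pixel (mm^2), or 1 for the literal
#'   pixel-count definition.
#' @param hu_window closed HU window classifying a pixel as fat.
#' @return the fat volume, a length-1 numeric.
#' @examples
#' img <- matrix(-100, 10, 10)
#' fat_volume(img, slice_thickness = 3)  # 100 pixels * 3 = 300
#' @export
fat_volume <- function(image, slice_thickness = 1, pixel_area = 1,
                       hu_window = c(-150, -50)) {
  if (!is.numeric(image) || !all(is.finite(image))) {
    stop("'image' must be finite-valued", call. = FALSE)
  }
  if (!is.numeric(slice_thickness) || length(slice_thickness) != 1L ||
      is.na(slice_thickness) || slice_thickness <= 0) {
    stop("'slice_thickness' must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(hu_window), length(hu_window) == 2L,
            hu_window[1] <= hu_window[2])
  n_fat <- sum(image >= hu_window[1] & image <= hu_window[2])
  n_fat * slice_thickness * pixel_area
}

#' Volume of a region above an intensity threshold
#'
#' Toy structural metric standing in for radiotherapy-planning quantities
#' (organ volumes, dose-volume metrics): the count of pixels strictly above
#' `threshold`, times a voxel volume. Useful for exercising the pluggable
#' metric interface on synthetic images.
#'
#' @param image numeric array, finite.
#' @param threshold intensity threshold.
#' @param voxel_volume volume per voxel (default 1).
#' @export
region_volume_above <- function(image, threshold, voxel_volume = 1) {
  if (!is.numeric(image) || !all(is.finite(image))) {
    stop("'image' must be finite-valued", call. = FALSE)
  }
  sum(image > threshold) * voxel_volume
}

#' A named, parameterised scalar metric function
#'
#' Wraps a deterministic function `f(image) -> scalar` together with a name
#' and fixed parameters, so metrics can be configured (e.g. from the CLI)
#' and applied uniformly with [apply_metric()]. Identical image and
#' parameters must give an identical value.
#'
#' @param name short metric name (e.g. `"fat_volume"`).
#' @param fn function taking the image as first argument.
#' @param parameters named list of extra arguments fixed for this metric.
#' @return an object of class `metric_function`, itself callable.
#' @examples
#' m <- metric_function("fat_volume", fat_volume,
#'                      list(slice_thickness = 3))
#' m(matrix(-100, 4, 4))  # 48
#' @export
metric_function <- function(name, fn, parameters = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn),
            is.list(parameters))
  structure(
    function(image) do.call(fn, c(list(image), parameters)),
    name = name, parameters = parameters,
    class = c("metric_function", "function")
  )
}

#' @export
print.metric_function <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf("Metric function '%s'", attr(x, "name")))
  if (length(p)) {
    cat(" with parameters: ",
        paste(names(p), vapply(p, format, character(1)), sep = " = ",
              collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# Look a metric up by name (for the CLI config surface).
resolve_metric <- function(name, parameters = list()) {
  fn <- switch(name,
    fat_volume = fat_volume,
    region_volume_above = region_volume_above,
    stop(sprintf("unknown metric '%s'", name), call. = FALSE)
  )
  metric_function(name, fn, parameters)
}

#' Apply a scalar metric over an ensemble of images
#'
#' Vectorises a metric function over the sampled reconstructions of one
#' subject, preserving order, so the result is the subject's predicted
#' metric ensemble.
#'
#' @param images a list of numeric arrays with identical shapes, or a
#'   single array whose last axis indexes the samples.
#' @param metric a [metric_function()] or a plain function `image -> scalar`.
#' @param ... extra arguments passed to a plain-function `metric`.
#' @return numeric vector of metric values aligned with the image order.
#' @examples
#' imgs <- list(matrix(0, 2, 2), matrix(-100, 2, 2))
#' apply_metric(imgs, fat_volume, slice_thickness = 2)  # 0 8
#' @export
apply_metric <- function(images, metric, ...) {
  images <- as_image_list(images)
  f <- if (inherits(metric, "metric_function")) {
    function(img) metric(img)
  } else {
    function(img) metric(img, ...)
  }
  vapply(images, f, numeric(1))
}

# Normalise image input to a list of arrays and check identical shapes.
as_image_list <- function(images) {
  if (is.array(images) && !is.list(images)) {
    nd <- length(dim(images))
    if (nd < 2L) stop("image stack must have at least 2 dimensions", call. = FALSE)
    if (nd == 2L) return(list(images))
    images <- lapply(seq_len(dim(images)[nd]), function(j) {
      slice_last_axis(images, j)
    })
    return(images)
  }
  if (!is.list(images) || length(images) < 1L) {
    stop("'images' must be a non-empty list of arrays or an array stack",
         call. = FALSE)
  }
  shapes <- lapply(images, function(im) dim(im) %||% length(im))
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]]))) {
    stop("image shape mismatch within ensemble", call. = FALSE)
  }
  images
}

# Extract sample j from an array whose trailing axis indexes samples.
slice_last_axis <- function(arr, j) {
  nd <- length(dim(arr))
  idx <- c(rep(list(quote(expr = )), nd - 1L), list(j))
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  array(out, dim = dim(arr)[-nd])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
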