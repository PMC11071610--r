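#' Read a long-format metric samples table
#'
#' Reads a CSV with exactly the columns `subject_id`, `sample_id`,
#' `metric_value` (in that order; header validated strictly) holding one
#' predicted metric value per sampled reconstruction. Non-numeric metric
#' values are reported with their row number.
#'
#' @param path path to the CSV file.
#' @return a data frame with the three columns.
#' @export
read_metric_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  expected <- c("subject_id", "sample_id", "metric_value")
  if (!identical(names(df), expected)) {
    stop(sprintf("'%s': expected columns %s, found %s", path,
                 paste(expected, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$metric_value))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    stop(sprintf("'%s': non-numeric or non-finite metric_value at row %d ('%s')",
                 path, bad[1] + 1L, df$metric_value[bad[1]]), call. = FALSE)
  }
  df$metric_value <- vals
  # numeric sample ids sort numerically, not lexicographically
  sid <- suppressWarnings(as.numeric(df$sample_id))
  if (!anyNA(sid)) df$sample_id <- sid
  df
}

#' Read a ground-truth metric table
#'
#' Reads a CSV with exactly the columns `subject_id`, `truth_value`.
#'
#' @param path path to the CSV file.
#' @return a data frame with the two columns.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  expected <- c("subject_id", "truth_value")
  if (!identical(names(df), expected)) {
    stop(sprintf("'%s': expected columns %s, found %s", path,
                 paste(expected, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df$truth_value))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    stop(sprintf("'%s': non-numeric or non-finite truth_value at row %d ('%s')",
                 path, bad[1] + 1L, df$truth_value[bad[1]]), call. = FALSE)
  }
  df$truth_value <- vals
  df
}

#' Write a calibration fit to a JSON adjustment file
#'
#' Serialises the calibrated quantile adjustments, adjusted levels,
#' nominal rates, calibration size and quantile-convention tag, plus an
#' MD5 content hash of the calibration samples table when its path is
#' supplied, so downstream predictions can detect a changed calibration
#' set.
#'
#' @param fit a fitted [metric_cp()] object.
#' @param path output path for the JSON file.
#' @param calibration_table optional path of the calibration samples CSV;
#'   its MD5 hash is recorded.
#' @return `path`, invisibly.
#' @export
write_adjustments <- function(fit, path, calibration_table = NULL) {
  stopifnot(inherits(fit, "metric_cp"))
  obj <- list(
    q_lo = fit$q_lo, q_hi = fit$q_hi,
    alpha_hat_lo = fit$alpha_hat_lo, alpha_hat_hi = fit$alpha_hat_hi,
    n = fit$n, alpha_lo = fit$alpha_lo, alpha_hi = fit$alpha_hi,
    quantile_convention = fit$quantile_convention,
    calibration_hash = if (!is.null(calibration_table))
      unname(tools::md5sum(calibration_table)) else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a JSON adjustment file back into a fit object
#'
#' Reconstructs a `metric_cp` object (without per-subject scores) from a
#' file written by [write_adjustments()], usable directly with
#' [predict.metric_cp()]. If `calibration_table` is supplied and the file
#' records a hash, a mismatch raises a warning that the calibration inputs
#' have changed.
#'
#' @param path path to the adjustment JSON file.
#' @param calibration_table optional path of the calibration samples CSV
#'   to verify against the recorded hash.
#' @return an object of class `metric_cp`.
#' @export
read_adjustments <- function(path, calibration_table = NULL) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  needed <- c("q_lo", "q_hi", "alpha_hat_lo", "alpha_hat_hi", "n",
              "alpha_lo", "alpha_hi")
  if (!is.list(obj) || !all(needed %in% names(obj))) {
    stop(sprintf("'%s' is not a valid adjustment file", path), call. = FALSE)
  }
  if (!is.null(calibration_table) && !is.null(obj$calibration_hash)) {
    h <- unname(tools::md5sum(calibration_table))
    if (!identical(h, obj$calibration_hash)) {
      warning("calibration table hash mismatch: adjustments were calibrated on different inputs",
              call. = FALSE)
    }
  }
  structure(list(
    q_lo = obj$q_lo, q_hi = obj$q_hi,
    alpha_hat_lo = obj$alpha_hat_lo, alpha_hat_hi = obj$alpha_hat_hi,
    n = obj$n, alpha_lo = obj$alpha_lo, alpha_hi = obj$alpha_hi,
    scores = NULL,
    quantile_convention = obj$quantile_convention %||% quantile_convention_tag(),
    call = NULL
  ), class = "metric_cp")
}

#' Read an image ensemble stack from NIfTI
#'
#' Reads a NIfTI file holding one subject's sampled reconstructions
#' stacked on the trailing axis and returns them as a list of arrays.
#'
#' @param path path to a NIfTI file (`.nii` or `.nii.gz`).
#' @return list of image arrays, one per sample.
#' @export
read_image_stack <- function(path) {
  img <- RNifti::readNifti(path)
  as_image_list(array(as.vector(img), dim = dim(img)))
}

#' Write an image ensemble stack to NIfTI
#'
#' Stacks identically shaped images on a new trailing axis and writes them
#' as one NIfTI volume.
#'
#' @param images list of arrays or a single array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(images, path) {
  images <- as_image_list(images)
  shp <- dim(images[[1]]) %||% length(images[[1]])
  arr <- array(unlist(images), dim = c(shp, length(images)))
  RNifti::writeNifti(arr, path)
  invisible(path)
}

#' Write a retrieval report to JSON
#'
#' Serialises a [retrieval_report()] (interval, bound-image indices and
#' metrics, inlier/outlier index sets) to a JSON file.
#'
#' @param report a `retrieval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_retrieval_report <- function(report, path) {
  stopifnot(inherits(report, "retrieval_report"))
  obj <- list(
    interval = list(lower = report$interval$lower,
                    upper = report$interval$upper,
                    length = interval_length(report$interval)),
    lower_index = report$lower_index,
    upper_index = report$upper_index,
    lower_metric = report$lower_metric,
    upper_metric = report$upper_metric,
    inliers = report$inliers,
    outliers = report$outliers,
    ns = report$ns
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a metric pool as CLI-ready CSV tables
#'
#' Emits the long-format samples table (`subject_id`, `sample_id`,
#' `metric_value`) and the truth table (`subject_id`, `truth_value`) for a
#' [metric_pool()].
#'
#' @param pool a `metric_pool`.
#' @param samples_path,truths_path output CSV paths.
#' @return invisibly, a list with the two paths.
#' @export
write_pool_csv <- function(pool, samples_path, truths_path) {
  stopifnot(inherits(pool, "metric_pool"))
  ns <- lengths(pool$ensembles)
  samples <- data.frame(
    subject_id = rep(pool$ids, ns),
    sample_id = unlist(lapply(ns, seq_len)),
    metric_value = unlist(pool$ensembles)
  )
  utils::write.csv(samples, samples_path, row.names = FALSE, quote = FALSE)
  truths <- data.frame(subject_id = pool$ids, truth_value = pool$truths)
  utils::write.csv(truths, truths_path, row.names = FALSE, quote = FALSE)
  invisible(list(samples = samples_path, truths = truths_path))
}

#' Read a metric pool from CLI CSV tables
#'
#' Inverse of [write_pool_csv()]: joins a samples table and a truth table
#' into a [metric_pool()], erroring if a truth-table subject has no
#' samples.
#'
#' @param samples_path,truths_path input CSV paths.
#' @return a `metric_pool`.
#' @export
read_pool_csv <- function(samples_path, truths_path) {
  samples <- read_metric_samples(samples_path)
  truths <- read_truth_table(truths_path)
  cal <- as_calibration_set(samples,
                            stats::setNames(truths$truth_value,
                                            truths$subject_id))
  metric_pool(cal$ensembles, cal$truths, ids = cal$ids)
}
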