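test_that("non-conformity scores follow the signed-gap formulas", {
  # degenerate ensemble equal to truth
  expect_equal(unname(nonconformity_scores(rep(4, 7), 4, 0.2, 0.3)), c(0, 0))
  # hand evaluation under the quantile convention
  expect_equal(unname(nonconformity_scores(1:10, 5, 0.1, 0.1)), c(-4, -4))
  # truth below all samples forces a positive lower score
  sc <- nonconformity_scores(c(10, 11, 12), 0, 0.05, 0.05)
  expect_equal(sc[["s_lo"]], 10)
  expect_true(sc[["s_lo"]] > 0)
})

test_that("calibration reproduces hand-computed adjustments", {
  # every ensemble equal to its truth -> zero adjustments
  fit0 <- metric_cp(list(rep(2, 5), rep(9, 5), rep(4, 5)), c(2, 9, 4),
                    alpha_lo = 0.25, alpha_hi = 0.25)
  expect_equal(unname(coef(fit0)), c(0, 0))

  # hand-set realisable score pairs at alpha = 0.25 and n = 3:
  # lower scores {-1, 0, 2}, upper scores {-2, -1, -3};
  # alpha_hat = floor(0.25*4)/3 = 1/3, so q = 2nd smallest score
  rec <- records_from_scores(c(-1, 0, 2), c(-2, -1, -3))
  fit <- metric_cp(rec$ensembles, rec$truths, 0.25, 0.25)
  expect_equal(residuals(fit)[, "s_lo"], c(-1, 0, 2), ignore_attr = TRUE)
  expect_equal(residuals(fit)[, "s_hi"], c(-2, -1, -3), ignore_attr = TRUE)
  expect_equal(fit$alpha_hat_lo, 1 / 3)
  expect_equal(unname(coef(fit)), c(0, -2))

  # with a rate too small for n = 3 the adjustment is the score maximum
  expect_warning(fit_max <- metric_cp(rec$ensembles, rec$truths, 0.05, 0.05),
                 "too small")
  expect_equal(unname(coef(fit_max)), c(2, -1))
})

test_that("calibration is invariant to joint shifts of samples and truths", {
  set.seed(7)
  ens <- replicate(12, rnorm(15, 50, 4), simplify = FALSE)
  tr <- rnorm(12, 50, 4)
  fit <- metric_cp(ens, tr, 0.1, 0.1)
  shifted <- metric_cp(lapply(ens, `+`, 13.7), tr + 13.7, 0.1, 0.1)
  expect_equal(coef(shifted), coef(fit))
})

test_that("empty or malformed calibration sets error", {
  expect_error(metric_cp(list(), numeric(0)), "empty calibration set")
  expect_error(metric_cp(list(1:3), c(1, 2)), "one value per ensemble")
  expect_error(metric_cp(list(1:3), 1, alpha_lo = 0.5, alpha_hi = 0.5),
               "< 1")
})

test_that("prediction applies the adjusted quantile formula", {
  fit <- fit_with_adjustments(0.5, 2, 0.1, 0.1)
  iv <- predict(fit, newdata = 1:10)
  expect_equal(c(iv$lower, iv$upper), c(0.5, 11))

  # identity adjustments reduce to the raw sample quantiles
  fit0 <- fit_with_adjustments(0, 0, 0.1, 0.1)
  iv0 <- predict(fit0, newdata = 1:10)
  base <- metric_baseline_interval(1:10, 0.1, 0.1)
  expect_equal(c(iv0$lower, iv0$upper), c(base$lower, base$upper))

  # single-sample ensemble reduces to [y - q_lo, y + q_hi]
  iv1 <- predict(fit, newdata = 42)
  expect_equal(c(iv1$lower, iv1$upper), c(42 - 0.5, 42 + 2))

  expect_error(predict(fit, newdata = numeric(0)), "empty sample set")
})

test_that("optional domain clamp restricts endpoints", {
  fit <- fit_with_adjustments(10, 0, 0.1, 0.1)
  iv <- predict(fit, newdata = c(1, 2, 3), domain = c(0, Inf))
  expect_gte(iv$lower, 0)
})

test_that("intervals are translation equivariant", {
  set.seed(11)
  ens <- replicate(20, rnorm(25, 100, 8), simplify = FALSE)
  tr <- rnorm(20, 100, 8)
  test_ens <- rnorm(25, 100, 8)
  b <- 31.4

  fit <- metric_cp(ens, tr, 0.1, 0.1)
  iv <- predict(fit, newdata = test_ens)

  # shifting all predictions (calibration + test), truths fixed:
  # the adjustments absorb the shift and the interval is unchanged
  fit_pred <- metric_cp(lapply(ens, `+`, b), tr, 0.1, 0.1)
  iv_pred <- predict(fit_pred, newdata = test_ens + b)
  expect_equal(c(iv_pred$lower, iv_pred$upper), c(iv$lower, iv$upper))

  # shifting predictions and truths jointly shifts the interval by b
  fit_all <- metric_cp(lapply(ens, `+`, b), tr + b, 0.1, 0.1)
  iv_all <- predict(fit_all, newdata = test_ens + b)
  expect_equal(c(iv_all$lower, iv_all$upper), c(iv$lower + b, iv$upper + b))
})

test_that("decreasing a mis-coverage rate widens both interval components", {
  # the two ingredients of the interval are each weakly monotone in alpha:
  # (a) the base ensemble quantiles move outward ...
  set.seed(13)
  v <- rnorm(30, 10, 2)
  alphas <- c(0.2, 0.1, 0.05, 0.02)
  q_lo_base <- vapply(alphas, function(a) empirical_quantile(v, a),
                      numeric(1))
  q_hi_base <- vapply(alphas, function(a) empirical_quantile(v, 1 - a),
                      numeric(1))
  expect_true(all(diff(q_lo_base) <= 1e-12))
  expect_true(all(diff(q_hi_base) >= -1e-12))

  # ... and (b) for a FIXED score set the calibrated adjustment grows as
  # alpha shrinks (the adjusted level 1 - alpha_hat is nondecreasing)
  scores <- rnorm(40)
  n <- length(scores)
  q_adj <- vapply(alphas, function(a) {
    hat <- suppressWarnings(adjusted_levels(n, a, a))
    empirical_quantile(scores, 1 - hat[["alpha_hat_lo"]])
  }, numeric(1))
  expect_true(all(diff(q_adj) >= -1e-12))

  # the composed endpoint is NOT pointwise monotone (the score set itself
  # depends on alpha); the guarantee that shrinking alpha buys is higher
  # coverage, which the acceptance simulations check directly.
})

test_that("the packaged micro-example calibrates as computed by hand", {
  samples <- read_metric_samples(
    system.file("extdata", "calib_samples.csv", package = "metricCP"))
  truths <- read_truth_table(
    system.file("extdata", "calib_truths.csv", package = "metricCP"))
  fit <- metric_cp(samples, truths, alpha_lo = 0.25, alpha_hi = 0.25)
  # scores: A (2-3, 3-4), B (12-10, 10-14), C (22-27, 27-26);
  # alpha_hat = 1/3 so q = 2nd smallest of {-1,2,-5} and {-1,-4,1}
  expect_equal(fit$n, 3)
  expect_equal(unname(coef(fit)), c(-1, -1))
  test_df <- read_metric_samples(
    system.file("extdata", "test_samples.csv", package = "metricCP"))
  iv <- predict(fit, newdata = test_df)
  expect_equal(c(iv$lower, iv$upper), c(7, 7))
})

test_that("fit methods expose the calibration state", {
  pool <- generate_metric_pool(n_subjects = 15, ns = 10, seed = 3)
  fit <- metric_cp(pool, alpha_lo = 0.1, alpha_hi = 0.1)
  expect_s3_class(fit, "metric_cp")
  expect_named(coef(fit), c("q_lo", "q_hi"))
  expect_equal(dim(residuals(fit)), c(15L, 2L))
  expect_output(print(fit), "calibration subjects: n = 15")
  expect_output(print(summary(fit)), "score distribution")
})
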