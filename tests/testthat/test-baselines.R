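test_that("the uncalibrated metric baseline is the raw quantile interval", {
  iv <- metric_baseline_interval(1:10, 0.1, 0.1)
  expect_equal(c(iv$lower, iv$upper), c(1, 9))
  ivc <- metric_baseline_interval(rep(4.2, 6), 0.1, 0.1)
  expect_equal(c(ivc$lower, ivc$upper), c(4.2, 4.2))
  # definitional identity with zero-adjustment prediction
  fit0 <- fit_with_adjustments(0, 0, 0.1, 0.1)
  set.seed(4)
  e <- rnorm(17)
  expect_equal(unlist(metric_baseline_interval(e, 0.1, 0.1)[, c("lower", "upper")]),
               unlist(predict(fit0, newdata = e)[, c("lower", "upper")]))
  expect_error(metric_baseline_interval(numeric(0)), "empty")
})

test_that("pixel baseline equals the scalar quantile applied per pixel", {
  # two constant images: bounds are the two images themselves
  imgs <- list(matrix(0, 3, 3), matrix(100, 3, 3))
  b <- pixel_baseline_bounds(imgs, 0.1, 0.1)
  expect_equal(b$lower, matrix(0, 3, 3))
  expect_equal(b$upper, matrix(100, 3, 3))

  # single image: lower = upper = the image
  one <- matrix(rnorm(9), 3, 3)
  b1 <- pixel_baseline_bounds(list(one), 0.2, 0.2)
  expect_equal(b1$lower, one)
  expect_equal(b1$upper, one)

  # per-pixel brute force on a random stack
  set.seed(9)
  stack <- lapply(1:7, function(i) matrix(rnorm(12), 3, 4))
  bb <- pixel_baseline_bounds(stack, 0.15, 0.25)
  for (r in 1:3) {
    for (cc in 1:4) {
      px <- vapply(stack, function(im) im[r, cc], numeric(1))
      expect_equal(bb$lower[r, cc], empirical_quantile(px, 0.15))
      expect_equal(bb$upper[r, cc], empirical_quantile(px, 1 - 0.25))
    }
  }
  expect_error(pixel_baseline_bounds(list(matrix(0, 2, 2), matrix(0, 1, 1))),
               "shape mismatch")
})

test_that("pixel CP on 1x1 images reduces exactly to scalar calibration", {
  set.seed(10)
  n <- 12
  ns <- 9
  cal_scalar <- replicate(n, rnorm(ns, 5, 2), simplify = FALSE)
  truths <- rnorm(n, 5, 2)
  test_scalar <- rnorm(ns, 5, 2)

  to_imgs <- function(v) lapply(v, function(x) matrix(x, 1, 1))
  b <- pixel_cp_bounds(lapply(cal_scalar, to_imgs),
                       to_imgs(truths),
                       to_imgs(test_scalar),
                       alpha_lo = 0.1, alpha_hi = 0.1)
  fit <- metric_cp(cal_scalar, truths, 0.1, 0.1)
  iv <- predict(fit, newdata = test_scalar)
  expect_identical(as.numeric(b$lower), as.numeric(iv$lower))
  expect_identical(as.numeric(b$upper), as.numeric(iv$upper))
  expect_identical(as.numeric(b$q_lo), as.numeric(coef(fit)[["q_lo"]]))
  expect_identical(as.numeric(b$q_hi), as.numeric(coef(fit)[["q_hi"]]))
})

test_that("pixel CP with noiseless ensembles leaves quantile bounds alone", {
  truth_imgs <- lapply(1:6, function(i) matrix(rnorm(4), 2, 2))
  cal_imgs <- lapply(truth_imgs, function(tr) replicate(5, tr,
                                                        simplify = FALSE))
  test_imgs <- replicate(5, truth_imgs[[1]], simplify = FALSE)
  b <- pixel_cp_bounds(cal_imgs, truth_imgs, test_imgs, 0.2, 0.2)
  expect_equal(b$q_lo, matrix(0, 2, 2))
  expect_equal(b$q_hi, matrix(0, 2, 2))
  expect_equal(b$lower, truth_imgs[[1]])
  expect_equal(b$upper, truth_imgs[[1]])
})

test_that("per-pixel adjustments are non-positive when quantiles bracket truth", {
  set.seed(12)
  truth_imgs <- lapply(1:8, function(i) matrix(0, 2, 2))
  # ensembles symmetric and wide around the truth at every pixel
  cal_imgs <- lapply(truth_imgs, function(tr) {
    lapply(seq(-2, 2, length.out = 9), function(d) tr + d)
  })
  b <- pixel_cp_bounds(cal_imgs, truth_imgs, cal_imgs[[1]], 0.2, 0.2)
  expect_true(all(b$q_lo <= 0))
  expect_true(all(b$q_hi <= 0))
})

test_that("pixel bounds map to an ordered metric interval", {
  # lower = upper image: zero-length interval
  img <- matrix(rnorm(9), 3, 3)
  b_eq <- structure(list(lower = img, upper = img), class = "pixel_bounds")
  iv <- metric_interval_from_pixel_bounds(b_eq, fat_volume)
  expect_equal(interval_length(iv), 0)

  # counter-monotone metric: the pixel-wise lower image holds MORE fat
  # than the upper image, so f(lower) > f(upper) and min/max reorders
  b <- structure(list(lower = matrix(-100, 2, 2), upper = matrix(0, 2, 2)),
                 class = "pixel_bounds")
  iv2 <- metric_interval_from_pixel_bounds(b, fat_volume,
                                           slice_thickness = 3)
  expect_equal(c(iv2$lower, iv2$upper), c(0, 12))

  # monotone metric with ordered bounds keeps the natural order
  b3 <- structure(list(lower = matrix(1, 2, 2), upper = matrix(5, 2, 2)),
                  class = "pixel_bounds")
  iv3 <- metric_interval_from_pixel_bounds(b3, region_volume_above,
                                           threshold = 2)
  expect_equal(c(iv3$lower, iv3$upper), c(0, 4))
})
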