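test_that("metric pool generation is a pure function of the seed", {
  p1 <- generate_metric_pool(n_subjects = 15, ns = 8, seed = 60)
  p2 <- generate_metric_pool(n_subjects = 15, ns = 8, seed = 60)
  expect_identical(p1, p2)
  p3 <- generate_metric_pool(n_subjects = 15, ns = 8, seed = 61)
  expect_false(identical(p1$truths, p3$truths))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(generate_metric_pool(n_subjects = 3, ns = 2,
                                              seed = 99)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("zero bias and noise reproduce the truths exactly", {
  pool <- generate_metric_pool(n_subjects = 10, ns = 5, bias = 0,
                               noise_sd = 0, seed = 62)
  for (i in 1:10) {
    expect_equal(pool$ensembles[[i]], rep(pool$truths[i], 5))
  }
})

test_that("generator settings shape the sample law as declared", {
  pool <- generate_metric_pool(n_subjects = 200, ns = 40, bias = 7.5,
                               noise_sd = 5, dispersion_factor = 1.5,
                               seed = 63)
  dev <- unlist(Map(function(e, y) e - y, pool$ensembles, pool$truths))
  expect_lt(abs(mean(dev) - 7.5), 0.3)       # bias
  expect_lt(abs(sd(dev) - 7.5), 0.3)         # dispersion * noise_sd
  # outliers displace a fraction of samples by +/- scale * noise_sd
  po <- generate_metric_pool(n_subjects = 200, ns = 40, bias = 0,
                             noise_sd = 1, dispersion_factor = 1,
                             outlier_rate = 0.1, outlier_scale = 8,
                             seed = 64)
  devo <- unlist(Map(function(e, y) e - y, po$ensembles, po$truths))
  expect_gt(mean(abs(devo) > 4), 0.05)
  expect_lt(mean(abs(devo) > 4), 0.15)
  # heavy-tailed truths are available
  pt <- generate_metric_pool(n_subjects = 50, ns = 2,
                             truth_distribution = "t", df = 3, seed = 65)
  expect_true(all(is.finite(pt$truths)))
  expect_error(generate_metric_pool(outlier_rate = 1.2), "outlier_rate")
})

test_that("phantom truth images have exactly the specified fat volume", {
  spec <- phantom_spec(image_size = 16, fat_region_pixels = 100,
                       slice_thickness = 3)
  ph <- generate_phantom_ensemble(spec, ns = 4, bias = 0, noise_sd = 0,
                                  seed = 70)
  expect_equal(fat_volume(ph$truth_image, slice_thickness = 3), 300)
  # zero bias/noise: every reconstruction matches the truth metric
  expect_equal(ph$ensemble$metrics, rep(300, 4))
  # images all share the phantom shape
  expect_true(all(vapply(ph$ensemble$images,
                         function(im) identical(dim(im), c(16L, 16L)),
                         logical(1))))
  expect_error(phantom_spec(image_size = 4, fat_region_pixels = 17),
               "fat region exceeds image")
})

test_that("phantom fat pixels sit inside the HU window, background outside", {
  spec <- phantom_spec(image_size = 8, fat_region_pixels = 10)
  ph <- generate_phantom_ensemble(spec, ns = 1, bias = 0, noise_sd = 0,
                                  seed = 71)
  vals <- sort(unique(as.vector(ph$truth_image)))
  expect_equal(vals, c(-100, 0))
  expect_equal(sum(ph$truth_image == -100), 10)
})

test_that("the phantom pool's scalar law matches the scalar generator", {
  thick <- 3
  pool <- generate_phantom_pool(n_subjects = 60, image_size = 64,
                                count_mean = 800, count_sd = 120,
                                ns = 20, bias = 60, noise_sd = 40,
                                slice_thickness = thick, seed = 72)
  dev <- unlist(Map(function(e, y) e - y, pool$ensembles, pool$truths))
  # metric units are count * thickness: bias 60 * 3, sd 40 * 3
  expect_lt(abs(mean(dev) - 60 * thick), 15)
  expect_lt(abs(sd(dev) - 40 * thick), 15)
  # truths are thickness-scaled rounded normal counts
  expect_lt(abs(mean(pool$truths) - 800 * thick), 150)
})

test_that("subject exchangeability: permuting the pool leaves results in family", {
  pool <- generate_metric_pool(n_subjects = 60, ns = 30, seed = 73)
  set.seed(73)
  perm <- sample(60)
  pool_p <- metric_pool(pool$ensembles[perm], pool$truths[perm])
  r1 <- run_split_experiment(pool, methods = "metric_cp", n_splits = 100,
                             seed = 74)
  r2 <- run_split_experiment(pool_p, methods = "metric_cp", n_splits = 100,
                             seed = 74)
  expect_lt(abs(r1$coverage - r2$coverage), 0.05)
})
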