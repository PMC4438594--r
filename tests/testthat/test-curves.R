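test_that("param_curve validates its grid and values", {
  expect_s3_class(param_curve("bv_tv", c(0, 0.5, 1), c(1, 2, 3)), "param_curve")
  expect_error(param_curve("x", c(0, 0.5, 0.4, 1), 1:4))
  expect_error(param_curve("x", c(0.1, 0.5, 1), 1:3))
  expect_error(param_curve("x", c(0, 0.5, 1), c(1, NA, 3)))
})

test_that("resampling preserves endpoints and linear segments", {
  cv <- param_curve("bv_tv", c(0, 0.25, 1), c(10, 20, 5))
  rs <- resample_curve(cv, 101)
  expect_equal(rs$values[1], 10)
  expect_equal(rs$values[101], 5)
  expect_equal(rs$values[26], 20) # grid point 0.25
  # linear on [0.25, 1]: value at 0.625 is the midpoint of 20 and 5
  rs9 <- resample_curve(cv, 9) # grid 0, 0.125, ..., 1
  expect_equal(rs9$values[6], 12.5)
  expect_error(resample_curve(cv, 1), "n_points")
})

test_that("averaging requires one parameter and takes pointwise means", {
  a <- param_curve("fd", c(0, 1), c(2, 4))
  b <- param_curve("fd", c(0, 1), c(4, 6))
  avg <- average_curves(list(a, b), n_points = 5)
  expect_equal(avg$values, seq(3, 5, length.out = 5))
  expect_error(average_curves(list(a, param_curve("da", c(0, 1), c(1, 1)))),
               "different parameters")
})

test_that("difference curves subtract after resampling", {
  a <- param_curve("bv_tv", c(0, 0.5, 1), c(30, 40, 30))
  b <- param_curve("bv_tv", c(0, 1), c(20, 20))
  d <- difference_curve(a, b, n_points = 11)
  expect_equal(d$values[1], 10)
  expect_equal(d$values[6], 20)
  expect_equal(max(d$values), 20)
})

test_that("slice curves bridge missing slices linearly", {
  sl <- data.frame(slice_index = 1:5, normalized_height = (0:4) / 4,
                   bv_tv = c(10, NA, 30, NA, 50))
  cv <- slice_curves(sl, parameters = "bv_tv")$bv_tv
  expect_equal(cv$values, c(10, 20, 30, 40, 50))
})

test_that("region selection finds the strongest window and breaks ties caudally", {
  g <- seq(0, 1, length.out = 101)
  peaked <- param_curve("bv_tv", g, exp(-((g - 0.7) / 0.1)^2))
  sel <- select_region(list(peaked), fraction = 0.2, n_slices = 50)
  w <- sel$z_window
  expect_equal(w[2] - w[1] + 1, 10)
  # the window must cover the peak at normalized height 0.7
  expect_true(w[1] <= 36 && w[2] >= 34)
  expect_equal(sel$anchor, "interior")

  flat <- param_curve("bv_tv", c(0, 1), c(1, 1))
  sel2 <- select_region(list(flat), fraction = 0.4, n_slices = 50)
  expect_equal(sel2$z_window, c(1, 20))
  expect_equal(sel2$anchor, "caudal")
})

test_that("fixed caudal mode returns the caudal window directly", {
  g <- seq(0, 1, length.out = 11)
  cv <- param_curve("bv_tv", g, g) # increasing toward cranial
  sel <- select_region(list(cv), fraction = 0.4, n_slices = 100,
                       fixed_caudal = TRUE)
  expect_equal(sel$z_window, c(1, 40))
  expect_equal(sel$anchor, "caudal")
  expect_error(select_region(list(cv), fraction = 0, n_slices = 10),
               "fraction")
})

test_that("opposite-signed difference curves contribute on equal footing", {
  g <- seq(0, 1, length.out = 101)
  up <- param_curve("bv_tv", g, 30 * exp(-((g - 0.8) / 0.1)^2))
  dn <- param_curve("tb_sp", g, -0.1 * exp(-((g - 0.8) / 0.1)^2))
  sel <- select_region(list(up, dn), fraction = 0.2, n_slices = 60)
  # both curves peak near 0.8 despite opposite signs and scales
  expect_gt(sel$z_window[1], 30)
})
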