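test_that("gray_stack validates voxel values and size", {
  expect_s3_class(gray_stack(array(0L, c(2, 2, 2)), 0.018), "gray_stack")
  expect_error(gray_stack(array(-1, c(2, 2, 2)), 0.018), "0")
  expect_error(gray_stack(array(256, c(2, 2, 2)), 0.018), "255")
  expect_error(gray_stack(array(1, c(2, 2, 2, 2)), 0.018))
  expect_error(gray_stack(array(0, c(2, 2, 2)), -1))
  # a bare matrix is promoted to a single-slice stack
  expect_equal(dim(gray_stack(matrix(0L, 3, 4), 0.018)$voxels), c(3L, 4L, 1L))
})

test_that("natural filename sort orders numeric runs by value", {
  f <- c("slice_10.png", "slice_2.png", "slice_1.png")
  expect_equal(trabstiff:::natural_sort(f),
               c("slice_1.png", "slice_2.png", "slice_10.png"))
  g <- c("b2a10", "b2a2", "b10a1")
  expect_equal(trabstiff:::natural_sort(g), c("b2a2", "b2a10", "b10a1"))
})

test_that("PNG slice directory round-trips with sidecar metadata", {
  vox <- array(sample.int(256, 4 * 5 * 3, replace = TRUE) - 1L, c(4, 5, 3))
  st <- gray_stack(vox, 0.018)
  d <- tempfile("stack_png")
  write_stack(st, d, format = "png")
  back <- read_stack(d) # voxel size from metadata.txt
  expect_equal(back$voxels, vox)
  expect_equal(back$voxel_size, 0.018)
})

test_that("8-bit BMP slices round-trip exactly", {
  m <- matrix(sample.int(256, 7 * 9, replace = TRUE) - 1L, 7, 9)
  f <- tempfile(fileext = ".bmp")
  trabstiff:::write_bmp8(m, f)
  expect_equal(trabstiff:::read_bmp8(f), m)

  vox <- array(sample.int(256, 6 * 4 * 2, replace = TRUE) - 1L, c(6, 4, 2))
  d <- tempfile("stack_bmp")
  write_stack(gray_stack(vox, 0.01), d, format = "bmp")
  expect_equal(read_stack(d)$voxels, vox)
})

test_that("multi-page TIFF round-trips", {
  vox <- array(sample.int(256, 5 * 5 * 4, replace = TRUE) - 1L, c(5, 5, 4))
  f <- tempfile(fileext = ".tif")
  write_stack(gray_stack(vox, 0.018), f)
  back <- read_stack(f, voxel_size_mm = 0.018)
  expect_equal(back$voxels, vox)
})

test_that("inconsistent slice shapes are rejected", {
  d <- tempfile("bad_stack")
  dir.create(d)
  png::writePNG(matrix(0, 4, 4), file.path(d, "s_1.png"))
  png::writePNG(matrix(0, 5, 4), file.path(d, "s_2.png"))
  expect_error(read_stack(d, 0.018), "inconsistent slice shape")
})

test_that("missing voxel size without sidecar is an error", {
  d <- tempfile("nosidecar")
  dir.create(d)
  png::writePNG(matrix(0, 4, 4), file.path(d, "s_1.png"))
  expect_error(read_stack(d), "voxel_size_mm")
})
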