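vx <- 0.018

test_that("volume fraction and apparent density are plain averages", {
  mask <- array(FALSE, c(4, 4, 4))
  mask[1:2, , ] <- TRUE # half the voxels
  roi <- as_roi(mask, vx)
  expect_equal(bv_tv(roi), 50)
  dens <- density_stack(array(0.2, c(4, 4, 4)), vx)
  dens$voxels[mask] <- 0.8
  expect_equal(mean_bmd(dens, roi), 0.5)
})

test_that("local thickness matches slab and ball oracles", {
  slab <- array(FALSE, c(40, 40, 40))
  slab[, , 18:22] <- TRUE # 5 voxels thick
  expect_equal(local_thickness(as_roi(slab, vx)), 5 * vx)

  r <- 8
  ax <- seq_len(33) - 17
  ball <- array(outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= r^2, c(33, 33, 33))
  th <- local_thickness(as_roi(ball, vx))
  expect_lt(abs(th - 16 * vx), 0.1 * 16 * vx)

  empty <- as_roi(array(FALSE, c(4, 4, 4)), vx)
  expect_error(local_thickness(empty), "empty")
})

test_that("separation is thickness of the complementary phase", {
  # bone plates at slices 1, 5, 9 leave two marrow gaps exactly 3 voxels wide
  slab <- array(FALSE, c(20, 20, 9))
  slab[, , c(1, 5, 9)] <- TRUE
  roi <- as_roi(slab, vx)
  expect_equal(local_thickness(roi, "background"), 3 * vx)
})

test_that("box-counting dimension recovers cube, plane and sponge", {
  cube <- array(TRUE, c(64, 64, 64))
  expect_lt(abs(fractal_dimension(cube) - 3), 0.05)
  plane <- array(FALSE, c(64, 64, 64))
  plane[, , 32] <- TRUE
  expect_lt(abs(fractal_dimension(plane) - 2), 0.05)
  sponge <- trabstiff:::phantom_menger(3, 81)
  expect_lt(abs(fractal_dimension(sponge) - log(20) / log(3)), 0.1)
  expect_error(fractal_dimension(array(TRUE, c(3, 3, 3))), "smaller")
  expect_error(fractal_dimension(array(FALSE, c(64, 64, 64))), "empty")
})

test_that("exposed-face surface counting matches the brute-force oracle", {
  m <- porous_mask(c(7, 8, 6), fill = 0.45, seed = 5)
  expect_equal(trabstiff:::exposed_faces(m), brute_faces(m))
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(trabstiff:::exposed_faces(one), 6L)
})

test_that("pattern factor is positive for convex, negative for enclosed", {
  r <- 8
  ax <- seq_len(33) - 17
  ball <- array(outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= r^2, c(33, 33, 33))
  expect_gt(tb_pf(as_roi(ball, vx)), 0)

  hollow <- array(TRUE, c(30, 30, 30))
  hollow[8:23, 8:23, 8:23] <- FALSE
  expect_lt(tb_pf(as_roi(hollow, vx)), 0)

  full <- as_roi(array(TRUE, c(4, 4, 4)), vx)
  full$region <- array(TRUE, c(4, 4, 4))
  expect_error(tb_pf(full), "dilation changed no voxels")
})

test_that("Euler characteristic matches explicit cell enumeration", {
  ball <- trabstiff:::phantom_ball(4)
  torus <- trabstiff:::phantom_torus(5, 2)
  pretzel <- trabstiff:::phantom_pretzel(3, 3, 4)
  for (m in list(ball, torus, pretzel))
    expect_equal(trabstiff:::euler_characteristic(m), brute_euler(m))
  expect_equal(trabstiff:::euler_characteristic(ball), 1)
  expect_equal(trabstiff:::euler_characteristic(torus), 0)
  expect_equal(trabstiff:::euler_characteristic(pretzel), -1)
})

test_that("connectivity density is (1 - Euler) per volume", {
  torus <- trabstiff:::phantom_torus(5, 2)
  roi <- as_roi(torus, vx)
  tv <- sum(roi$region) * vx^3
  expect_equal(as.numeric(connectivity_density(roi)), (1 - 0) / tv)
  two <- array(FALSE, c(6, 6, 6))
  two[1:2, 1:2, 1:2] <- TRUE
  two[5:6, 5:6, 5:6] <- TRUE
  expect_warning(connectivity_density(as_roi(two, vx)), "2 components")
})

test_that("anisotropy separates aligned rods from isotropic porous media", {
  rods <- trabstiff:::phantom_rod_lattice(3, 8, c(48, 48, 48))
  da_rods <- as.numeric(degree_of_anisotropy(as_roi(rods, vx)))
  expect_gt(da_rods, 0.6)

  iso <- porous_mask(c(48, 48, 48), fill = 0.35, sigma = 2.5, seed = 42)
  da_iso <- as.numeric(degree_of_anisotropy(as_roi(iso, vx)))
  expect_lt(da_iso, 0.15)

  expect_error(degree_of_anisotropy(as_roi(array(FALSE, c(8, 8, 8)), vx)),
               "empty")
  expect_error(degree_of_anisotropy(as_roi(array(TRUE, c(8, 8, 8)), vx)),
               "solid")
})

test_that("anisotropy is deterministic for a fixed seed", {
  rods <- trabstiff:::phantom_rod_lattice(3, 8, c(32, 32, 32))
  roi <- as_roi(rods, vx)
  a <- degree_of_anisotropy(roi, seed = 7)
  b <- degree_of_anisotropy(roi, seed = 7)
  expect_identical(a, b)
})

test_that("analyze_3d bundles the parameter panel consistently", {
  mask <- porous_mask(c(24, 24, 24), fill = 0.4, seed = 9)
  roi <- as_roi(mask, vx)
  dens <- density_stack(array(0.1, dim(mask)), vx)
  dens$voxels[mask] <- 0.9
  m <- suppressWarnings(analyze_3d(roi, dens))
  expect_equal(m$bv_tv, bv_tv(roi))
  expect_equal(m$bmd, mean_bmd(dens, roi))
  expect_equal(m$tb_th, local_thickness(roi))
  expect_equal(m$tb_sp, local_thickness(roi, "background"))
  expect_equal(m$fd, fractal_dimension(roi))
  expect_equal(m$tb_pf, tb_pf(roi))
  expect_equal(m$da, as.numeric(degree_of_anisotropy(roi)))
  expect_equal(m$conn_dn, as.numeric(suppressWarnings(connectivity_density(roi))))
})

test_that("slice analysis is constant on an axially uniform phantom", {
  rods <- trabstiff:::phantom_rod_lattice(3, 8, c(24, 24, 10))
  roi <- as_roi(rods, vx)
  sl <- analyze_slices(roi)
  expect_equal(nrow(sl), 10)
  expect_equal(sl$normalized_height, (0:9) / 9)
  for (p in c("bv_tv", "tb_th", "tb_sp", "fd", "tb_pf", "da"))
    expect_equal(diff(range(sl[[p]])), 0)
})

test_that("an empty middle slice yields zero area fraction at that height", {
  mask <- porous_mask(c(16, 16, 7), fill = 0.5, seed = 2)
  mask[, , 4] <- FALSE
  sl <- analyze_slices(as_roi(mask, vx))
  expect_equal(sl$bv_tv[4], 0)
  expect_true(is.na(sl$tb_th[4]))
})

test_that("single-slice values equal the 2D operations run alone", {
  mask <- porous_mask(c(20, 20, 5), fill = 0.5, seed = 8)
  roi <- as_roi(mask, vx)
  sl <- analyze_slices(roi)
  k <- 3
  m2 <- mask[, , k]
  r2 <- matrix(TRUE, 20, 20)
  expect_equal(sl$bv_tv[k], 100 * sum(m2) / sum(r2))
  expect_equal(sl$tb_pf[k], trabstiff:::slice_tb_pf(m2, vx))
  expect_equal(sl$fd[k], trabstiff:::slice_fd(m2))
  expect_equal(sl$tb_th[k], trabstiff:::slice_thickness(m2) * vx)
})
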