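vx <- 0.018

test_that("deterministic fixtures hit their analytic oracles", {
  cyl <- make_phantom("solid_cylinder", diameter_vox = 40, height_vox = 10)
  expect_equal(bv_tv(cyl$roi), 100)
  expect_equal(as.numeric(connectivity_density(cyl$roi)) *
                 sum(cyl$roi$region) * vx^3, 0)

  rods <- trabstiff:::phantom_rod_lattice(3, 6, c(24, 24, 12))
  expect_equal(mean(rods), 0.25) # (3/6)^2 area fraction in a square region

  sponge <- trabstiff:::phantom_menger(3, 81)
  expect_equal(sum(sponge), 20^3 * 27) # 3 iterations leave solid 3^3 cells
  expect_error(trabstiff:::phantom_menger(3, 80), "power of 3")
})

test_that("fixture gray stacks segment back to the generating mask", {
  ph <- make_phantom("torus", R_vox = 6, r_vox = 2)
  seg <- segment_bone(ph$stack)
  expect_equal(seg, ph$roi$mask)
  expect_equal(ph$spec$kind, "torus")
})

test_that("gaussian phantoms land on the target volume fraction", {
  roi <- gaussian_trabecular(dims = c(40, 40, 30), target_bvtv = 35,
                             diameter_mm = 36 * vx, seed = 3)
  expect_lt(abs(bv_tv(roi) - 35), 0.2)
  expect_equal(attr(roi, "seed"), 3)
  roi2 <- gaussian_trabecular(dims = c(40, 40, 30), target_bvtv = 35,
                              diameter_mm = 36 * vx, seed = 3)
  expect_identical(roi$mask, roi2$mask)
})

test_that("the thinning transform erodes to an exact subset", {
  roi <- gaussian_trabecular(dims = c(40, 40, 30), target_bvtv = 35,
                             diameter_mm = 36 * vx, seed = 4)
  thin <- ovx_transform(roi, delta_bvtv = 12)
  expect_true(all(roi$mask[thin$mask])) # subset
  expect_lt(abs(bv_tv(thin) - (bv_tv(roi) - 12)), 0.05)
  expect_error(ovx_transform(roi, delta_bvtv = 50), "infeasible")
  expect_identical(ovx_transform(roi, 0), roi)
})

test_that("a foramen channel clears bone at mid-height", {
  roi <- gaussian_trabecular(dims = c(40, 40, 30), target_bvtv = 45,
                             diameter_mm = 36 * vx, seed = 5)
  bored <- add_foramen(roi, radius_mm = 0.1)
  sl0 <- analyze_slices(roi)
  sl1 <- analyze_slices(bored)
  mid <- 15
  expect_lt(sl1$bv_tv[mid], sl0$bv_tv[mid])
  expect_equal(sl1$bv_tv[1], sl0$bv_tv[1]) # ends untouched
  expect_error(add_foramen(roi, 0.4), "exceeds")
})

test_that("generated studies are deterministic with paired siblings", {
  st <- generate_study(n_per_group = 2, levels = c("L4", "L5"),
                       dims = c(24, 24, 20), diameter_mm = 20 * vx,
                       target_bvtv = 40, seed = 6)
  expect_length(st$specimens, 8)
  ids <- vapply(st$specimens, `[[`, "", "id")
  expect_setequal(unique(ids), c("sham_01", "sham_02", "ovx_01", "ovx_02"))
  # ovx sibling is a subset of its sham twin
  sham <- st$specimens[[1]]$roi
  ovx <- st$specimens[[2]]$roi
  expect_equal(st$specimens[[1]]$truth$seed, st$specimens[[2]]$truth$seed)
  expect_true(all(sham$mask[ovx$mask]))
  expect_lt(abs(bv_tv(sham) - bv_tv(ovx) - 12), 0.1)

  st2 <- generate_study(n_per_group = 2, levels = c("L4", "L5"),
                        dims = c(24, 24, 20), diameter_mm = 20 * vx,
                        target_bvtv = 40, seed = 6)
  expect_identical(st$specimens[[3]]$roi$mask, st2$specimens[[3]]$roi$mask)
})

test_that("trabecular scale controls the structure thickness", {
  fine <- gaussian_trabecular(dims = c(40, 40, 30), scale = 2,
                              target_bvtv = 40, diameter_mm = 36 * vx, seed = 7)
  coarse <- gaussian_trabecular(dims = c(40, 40, 30), scale = 4,
                                target_bvtv = 40, diameter_mm = 36 * vx, seed = 7)
  expect_lt(local_thickness(fine), local_thickness(coarse))
})
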