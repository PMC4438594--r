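vx <- 0.018
mat <- fe_material()

test_that("material defaults and validation", {
  expect_equal(mat$E, 24.5)
  expect_equal(mat$nu, 0.3)
  expect_error(fe_material(-1, 0.3))
  expect_error(fe_material(24.5, 0.5))
})

test_that("element stiffness is symmetric with exact rigid-body null space", {
  Ke <- hex8_stiffness(mat, vx)
  expect_equal(dim(Ke), c(24L, 24L))
  expect_equal(Ke, t(Ke))
  # translations
  for (ax in 1:3) {
    u <- rep(0, 24)
    u[seq(ax, 24, by = 3)] <- 1
    expect_lt(max(abs(Ke %*% u)), 1e-9 * max(abs(Ke)))
  }
  # infinitesimal rotation about z on the unit cube corner coordinates
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)) * vx
  u <- as.vector(t(cbind(-corners[, 2], corners[, 1], 0)))
  expect_lt(max(abs(Ke %*% u)), 1e-9 * max(abs(Ke)))
  # positive semidefinite with exactly 6 zero modes
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev[19:24])), 1e-9 * ev[1])
  expect_gt(ev[18], 0)
})

test_that("2-point Gauss quadrature is exact for the voxel element", {
  expect_equal(hex8_stiffness(mat, vx, n_gauss = 2),
               hex8_stiffness(mat, vx, n_gauss = 3), tolerance = 1e-12)
})

test_that("a single frictionless element reproduces the uniaxial closed form", {
  roi <- as_roi(array(TRUE, c(1, 1, 1)), vx)
  mesh <- build_mesh(roi)
  bcs <- boundary_conditions(mesh, strain = 0.05, mode = "frictionless")
  sol <- solve_fe(mesh, mat, bcs)
  si <- stiffness_index(sol, diameter_mm = vx)
  expect_equal(si$k, mat$E * 1000 * vx, tolerance = 1e-9)
  # uniform axial strain: all top nodes displace equally
  uz_top <- sol$displacements[mesh$top_nodes, 3]
  expect_equal(diff(range(uz_top)), 0, tolerance = 1e-12)
})

test_that("zero prescribed displacement gives zero response", {
  roi <- as_roi(array(TRUE, c(2, 2, 2)), vx)
  mesh <- build_mesh(roi)
  bcs <- boundary_conditions(mesh, strain = 0, mode = "bonded")
  sol <- solve_fe(mesh, mat, bcs)
  expect_equal(max(abs(sol$displacements)), 0)
  expect_equal(abs(axial_reaction(sol, "bottom")), 0)
})

test_that("iterative solves match a dense direct factorization", {
  m <- porous_mask(c(10, 10, 8), fill = 0.5, sigma = 1.2, seed = 7)
  mesh <- build_mesh(as_roi(m, vx))
  expect_lte(nrow(mesh$elements), 500)
  for (mode in c("bonded", "frictionless")) {
    bcs <- boundary_conditions(mesh, mode = mode)
    sol <- solve_fe(mesh, mat, bcs, tol = 1e-10)
    ref <- dense_solve(mesh, mat, bcs)
    uz_it <- sol$displacements[, 3]
    uz_ref <- ref$u[seq(3, length(ref$u), by = 3)]
    # axial displacements are unique in both modes
    expect_lt(sqrt(sum((uz_it - uz_ref)^2) / sum(uz_ref^2)), 1e-8)
    if (mode == "bonded") {
      u_it <- as.vector(t(sol$displacements))
      expect_lt(sqrt(sum((u_it - ref$u)^2) / sum(ref$u^2)), 1e-8)
    }
    kb_ref <- sum(ref$reactions[3 * mesh$bottom_nodes])
    expect_lt(abs(axial_reaction(sol, "bottom") - kb_ref) / abs(kb_ref), 1e-8)
  }
})

test_that("bottom and top axial forces balance on converged solves", {
  for (seed in c(1, 2)) {
    m <- porous_mask(c(12, 12, 10), fill = 0.45, sigma = 1.4, seed = seed)
    mesh <- build_mesh(as_roi(m, vx))
    bcs <- boundary_conditions(mesh, mode = "bonded")
    sol <- solve_fe(mesh, mat, bcs)
    rb <- axial_reaction(sol, "bottom")
    rt <- axial_reaction(sol, "top")
    expect_lt(abs(rb + rt) / abs(rb), 1e-6)
  }
})

test_that("the solve is linear in the prescribed displacement", {
  m <- porous_mask(c(8, 8, 8), fill = 0.5, sigma = 1.2, seed = 4)
  mesh <- build_mesh(as_roi(m, vx))
  b1 <- boundary_conditions(mesh, strain = 0.05, mode = "bonded")
  b2 <- boundary_conditions(mesh, strain = 0.10, mode = "bonded")
  s1 <- solve_fe(mesh, mat, b1, tol = 1e-10)
  s2 <- solve_fe(mesh, mat, b2, tol = 1e-10)
  f1 <- abs(axial_reaction(s1, "bottom"))
  f2 <- abs(axial_reaction(s2, "bottom"))
  expect_lt(abs(f2 - 2 * f1) / f2, 1e-8)
  k1 <- stiffness_index(s1, 8 * vx)
  k2 <- stiffness_index(s2, 8 * vx)
  expect_lt(abs(k1$k - k2$k) / k1$k, 1e-8)
  expect_lt(abs(k1$index - k2$index) / k1$index, 1e-8)
})

test_that("a fully fixed bottom is at least as stiff as a frictionless one", {
  m <- porous_mask(c(10, 10, 8), fill = 0.55, sigma = 1.3, seed = 11)
  mesh <- build_mesh(as_roi(m, vx))
  sp <- solve_fe(mesh, mat, boundary_conditions(mesh, mode = "bonded"))
  sf <- solve_fe(mesh, mat, boundary_conditions(mesh, mode = "frictionless"))
  kp <- stiffness_index(sp, 10 * vx)$k
  kf <- stiffness_index(sf, 10 * vx)$k
  expect_gte(kp, kf * (1 - 1e-9))
})

test_that("removing elements never increases stiffness", {
  m <- porous_mask(c(8, 8, 8), fill = 0.65, sigma = 1.2, seed = 3)
  roi <- as_roi(m, vx)
  mesh <- build_mesh(roi)
  k0 <- stiffness_index(solve_fe(mesh, mat,
                                 boundary_conditions(mesh, mode = "bonded"),
                                 tol = 1e-10), 8 * vx)$k
  idx <- which(m)
  removals <- trabstiff:::with_seed(99, sample(idx, 20))
  for (v in removals) {
    m2 <- m
    m2[v] <- FALSE
    mesh2 <- try(build_mesh(as_roi(m2, vx)), silent = TRUE)
    if (inherits(mesh2, "try-error")) next # removal may break the load path
    k1 <- stiffness_index(solve_fe(mesh2, mat,
                                   boundary_conditions(mesh2, mode = "bonded"),
                                   tol = 1e-10), 8 * vx)$k
    expect_lte(k1, k0 * (1 + 1e-8))
  }
})

test_that("meshing keeps exactly the spanning components", {
  m <- array(FALSE, c(6, 6, 5))
  m[1:2, 1:2, ] <- TRUE     # spanning column
  m[5:6, 5:6, 1:2] <- TRUE  # dangling stump
  m[4, 4, 3] <- TRUE        # floating voxel
  roi <- as_roi(m, vx)
  mesh <- build_mesh(roi)
  expect_equal(nrow(mesh$elements), 2 * 2 * 5)
  expect_equal(mesh$removed_fraction, (8 + 1) / sum(m))
  expect_error(build_mesh(as_roi(array(FALSE, c(4, 4, 4)), vx)))
})

test_that("ABAQUS export re-parses to the identical mesh", {
  m <- porous_mask(c(6, 6, 5), fill = 0.6, sigma = 1, seed = 5)
  mesh <- build_mesh(as_roi(m, vx))
  bcs <- boundary_conditions(mesh, mode = "bonded")
  f <- tempfile(fileext = ".inp")
  export_inp(mesh, mat, bcs, f)
  back <- read_inp(f)
  expect_equal(back$nodes, unname(mesh$nodes), tolerance = 1e-9)
  expect_equal(back$elements, unname(mesh$elements))
  expect_setequal(back$bottom_nodes, mesh$bottom_nodes)
  expect_setequal(back$top_nodes, mesh$top_nodes)
  expect_true(any(grepl("C3D8", readLines(f))))
})

test_that("stiffness index arithmetic matches the closed form", {
  # D = 2 mm, L = 1 mm, E = 24.5 GPa: k' = 24.5e3 * pi * 1 / 1
  sol <- structure(list(mesh = list(bottom_nodes = 1L, top_nodes = 2L,
                                    height = 1),
                        bcs = list(delta_d = 0.05),
                        material = fe_material(24.5, 0.3),
                        reactions = data.frame(node = 1L, dof = 3L,
                                               force = 77)),
                   class = "fe_solution")
  si <- stiffness_index(sol, diameter_mm = 2, height_mm = 1)
  expect_equal(si$k_prime, 24.5e3 * pi * 2^2 / 4, tolerance = 1e-12)
  expect_equal(si$k, 77 / 0.05)
})
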