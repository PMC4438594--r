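#' Linear elastic material
#'
#' @param E Young's modulus in GPa (default 24.5, a standard value for rat
#'   trabecular bone tissue).
#' @param nu Poisson's ratio (default 0.3).
#' @return object of class `fe_material`.
#' @export
fe_material <- function(E = 24.5, nu = 0.3) {
  stopifnot(E > 0, nu > -1, nu < 0.5)
  structure(list(E = E, nu = nu), class = "fe_material")
}

#' Canonical hex8 element stiffness matrix
#'
#' Trilinear 8-node hexahedron of edge `a` with isotropic elasticity,
#' integrated by Gauss quadrature (2x2x2 by default; the integrand is exact
#' at that order for a cube). DOFs are ordered (ux, uy, uz) per node, nodes
#' counterclockwise on the bottom face then the top face.
#'
#' @param material a [fe_material()].
#' @param edge_mm element edge length in mm.
#' @param n_gauss Gauss points per axis.
#' @return 24x24 symmetric stiffness matrix in N/mm.
#' @export
hex8_stiffness <- function(material, edge_mm, n_gauss = 2) {
  E <- material$E * 1000 # GPa -> N/mm^2
  nu <- material$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  # natural coordinates of the 8 nodes
  xi <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  eta <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  zeta <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  gp <- switch(as.character(n_gauss),
               "1" = list(x = 0, w = 2),
               "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
               "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                          w = c(5, 8, 5) / 9),
               stop("n_gauss must be 1, 2 or 3"))
  a <- edge_mm
  J <- a / 2 # d(x)/d(xi), cube element
  K <- matrix(0, 24, 24)
  for (i in seq_along(gp$x)) for (j in seq_along(gp$x)) for (k in seq_along(gp$x)) {
    g <- c(gp$x[i], gp$x[j], gp$x[k])
    w <- gp$w[i] * gp$w[j] * gp$w[k]
    dN <- cbind(xi * (1 + eta * g[2]) * (1 + zeta * g[3]),
                eta * (1 + xi * g[1]) * (1 + zeta * g[3]),
                zeta * (1 + xi * g[1]) * (1 + eta * g[2])) / 8
    dNx <- dN / J # derivatives w.r.t. physical coordinates
    B <- matrix(0, 6, 24)
    for (nd in 1:8) {
      c0 <- 3 * (nd - 1)
      B[1, c0 + 1] <- dNx[nd, 1]
      B[2, c0 + 2] <- dNx[nd, 2]
      B[3, c0 + 3] <- dNx[nd, 3]
      B[4, c0 + 1] <- dNx[nd, 2]; B[4, c0 + 2] <- dNx[nd, 1]
      B[5, c0 + 2] <- dNx[nd, 3]; B[5, c0 + 3] <- dNx[nd, 2]
      B[6, c0 + 1] <- dNx[nd, 3]; B[6, c0 + 3] <- dNx[nd, 1]
    }
    K <- K + w * J^3 * t(B) %*% D %*% B
  }
  (K + t(K)) / 2
}

#' Build a voxel hex8 mesh from a segmented ROI
#'
#' One cube element per bone voxel at the native voxel size; no resampling
#' or smoothing. Before meshing, the mask is filtered to the union of
#' face-connected (6-connectivity) components that span from the bottom to
#' the top slice of the ROI: components without a load path (including
#' voxels attached only through edges or corners) cannot transmit axial
#' force and would make the stiffness system singular.
#'
#' @param roi a `trab_roi` (or 3D logical mask plus `voxel_size_mm`).
#' @param voxel_size_mm voxel size for bare masks.
#' @return object of class `hex_mesh`: `nodes` (n x 3 mm coordinates),
#'   `elements` (m x 8 node ids, right-handed), `edge` (mm),
#'   `removed_fraction`, `n_slices`, `height` (mm) and node id vectors
#'   `bottom_nodes`, `top_nodes`.
#' @export
build_mesh <- function(roi, voxel_size_mm = NULL) {
  if (inherits(roi, "trab_roi")) {
    m <- roi_crop(roi)$mask
    h <- roi$voxel_size
  } else {
    m <- roi
    h <- voxel_size_mm
    if (is.null(h)) stop("voxel_size_mm required for a bare mask")
  }
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  keep <- array(spanning_components_cpp(as.logical(m), d), d)
  n_total <- sum(m)
  n_keep <- sum(keep)
  if (n_keep == 0)
    stop("no load path: no face-connected component spans bottom to top")
  idx <- which(keep, arr.ind = TRUE) # columns: row (x), col (y), slice (z)
  nxp <- d[1] + 1; nyp <- d[2] + 1
  lid <- function(i, j, k) # 0-based lattice id (numeric: no 32-bit overflow)
    as.numeric(i) + nxp * (as.numeric(j) + nyp * as.numeric(k))
  i0 <- idx[, 1] - 1L; j0 <- idx[, 2] - 1L; k0 <- idx[, 3] - 1L
  # hex8 node order: bottom face CCW (x,y), then top (+z)
  corners <- cbind(lid(i0,     j0,     k0),
                   lid(i0 + 1, j0,     k0),
                   lid(i0 + 1, j0 + 1, k0),
                   lid(i0,     j0 + 1, k0),
                   lid(i0,     j0,     k0 + 1),
                   lid(i0 + 1, j0,     k0 + 1),
                   lid(i0 + 1, j0 + 1, k0 + 1),
                   lid(i0,     j0 + 1, k0 + 1))
  ulat <- sort(unique(as.vector(corners)))
  elements <- matrix(match(corners, ulat), ncol = 8)
  kz <- ulat %/% (nxp * nyp)
  rem <- ulat %% (nxp * nyp)
  jy <- rem %/% nxp
  ix <- rem %% nxp
  nodes <- cbind(ix, jy, kz) * h
  structure(list(nodes = nodes, elements = elements, edge = h,
                 removed_fraction = 1 - n_keep / n_total,
                 n_slices = d[3], height = d[3] * h,
                 bottom_nodes = which(kz == 0L),
                 top_nodes = which(kz == d[3])),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d elements, %d nodes, edge %g mm, height %g mm (removed %.1f%%)\n",
              nrow(x$elements), nrow(x$nodes), x$edge, x$height,
              100 * x$removed_fraction))
  invisible(x)
}

#' Uniaxial compression boundary conditions
#'
#' A prescribed axial displacement of `strain x height` is applied to the
#' top face while the bottom face is fixed. In `"bonded"` mode the bottom
#' nodes are fixed in all three directions (fully bonded platen); in
#' `"frictionless"` mode only the axial component is constrained on both
#' faces, which makes the uniform uniaxial stress state an exact solution
#' (the analytic oracles k/k' = 1 for a solid cylinder and k/k' = area
#' fraction for parallel rods hold exactly in this mode).
#'
#' @param mesh a [build_mesh()] mesh.
#' @param strain prescribed apparent compressive strain (default 0.05).
#' @param mode `"bonded"` or `"frictionless"`.
#' @return object of class `fe_bcs` with the constrained DOF table,
#'   `delta_d` (mm, positive = shortening) and `strain`.
#' @export
boundary_conditions <- function(mesh, strain = 0.05, mode = c("bonded", "frictionless")) {
  mode <- match.arg(mode)
  if (!length(mesh$bottom_nodes) || !length(mesh$top_nodes))
    stop("mesh has no bottom or top face nodes")
  delta <- strain * mesh$height
  bot <- mesh$bottom_nodes
  top <- mesh$top_nodes
  if (mode == "bonded") {
    fixed_dofs <- c(3 * rep(bot, each = 3) - (2:0), 3 * top)
    fixed_vals <- c(rep(0, 3 * length(bot)), rep(-delta, length(top)))
  } else {
    fixed_dofs <- c(3 * bot, 3 * top)
    fixed_vals <- c(rep(0, length(bot)), rep(-delta, length(top)))
  }
  structure(list(mode = mode, fixed_dofs = as.integer(fixed_dofs),
                 fixed_vals = fixed_vals, delta_d = delta, strain = strain),
            class = "fe_bcs")
}

#' Solve the voxel FE compression problem
#'
#' Matrix-free Jacobi-preconditioned conjugate gradient on the
#' element-by-element operator (all elements share one canonical hex8
#' matrix). The iteration starts from the affine compression field (with
#' the Poisson lateral expansion in frictionless mode), which is the exact
#' solution for homogeneous structures. In frictionless mode, remaining
#' in-plane rigid modes have zero axial component, so the consistent
#' semi-definite system converges and reactions are unique.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param material a [fe_material()].
#' @param bcs a [boundary_conditions()] object.
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap.
#' @return object of class `fe_solution`: `displacements` (n x 3 mm),
#'   `reactions` (data.frame: node, dof, force N), `residual`, `iterations`,
#'   plus the mesh/bcs references.
#' @export
solve_fe <- function(mesh, material, bcs, tol = 1e-8, max_iter = 20000) {
  Ke <- hex8_stiffness(material, mesh$edge)
  n <- nrow(mesh$nodes)
  eps <- bcs$strain
  z <- mesh$nodes[, 3]
  x0 <- numeric(3 * n)
  x0[seq(3, 3 * n, by = 3)] <- -eps * z
  if (bcs$mode == "frictionless") {
    x0[seq(1, 3 * n, by = 3)] <- material$nu * eps * (mesh$nodes[, 1] - mean(mesh$nodes[, 1]))
    x0[seq(2, 3 * n, by = 3)] <- material$nu * eps * (mesh$nodes[, 2] - mean(mesh$nodes[, 2]))
  }
  res <- fe_solve_cg_cpp(mesh$elements, n, Ke, bcs$fixed_dofs, bcs$fixed_vals,
                         x0, tol, max_iter)
  if (res$relres > tol)
    stop(sprintf("CG did not converge: relative residual %.3g after %d iterations",
                 res$relres, res$iterations))
  disp <- matrix(res$displacements, ncol = 3, byrow = TRUE)
  reac <- data.frame(node = (bcs$fixed_dofs - 1L) %/% 3L + 1L,
                     dof = (bcs$fixed_dofs - 1L) %% 3L + 1L,
                     force = res$reactions)
  structure(list(displacements = disp, reactions = reac,
                 residual = res$relres, iterations = res$iterations,
                 mesh = mesh, bcs = bcs, material = material),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> %d iterations, residual %.2e, axial force %.4g N\n",
              x$iterations, x$residual, abs(axial_reaction(x, "bottom"))))
  invisible(x)
}

#' Summed axial reaction force on a loaded face
#'
#' Total z-direction reaction over the constrained nodes of the bottom or
#' top face, in N. On a converged solution the two faces balance:
#' `axial_reaction(sol, "bottom") == -axial_reaction(sol, "top")` to
#' solver precision (equilibrium).
#'
#' @param solution a [solve_fe()] solution.
#' @param face `"bottom"` or `"top"`.
#' @return signed axial force in N.
#' @export
axial_reaction <- function(solution, face = c("bottom", "top")) {
  face <- match.arg(face)
  nodes <- if (face == "bottom") solution$mesh$bottom_nodes else solution$mesh$top_nodes
  r <- solution$reactions
  sum(r$force[r$dof == 3 & r$node %in% nodes])
}

#' Normalized stiffness index k/k'
#'
#' k is the apparent axial stiffness: summed axial reaction on the fixed
#' bottom face divided by the prescribed displacement. k' is the theoretical
#' stiffness of the same cylinder were it solid: E A / L with the nominal
#' circle area A = pi D^2 / 4 of the ROI and L the analyzed segment height.
#' Their ratio is a dimensionless, size-independent stiffness index.
#'
#' @param solution a converged [solve_fe()] solution.
#' @param diameter_mm ROI cylinder diameter.
#' @param height_mm analyzed segment height (defaults to the mesh height).
#' @return object of class `stiffness_result` with `k`, `k_prime` (N/mm)
#'   and `index`.
#' @export
stiffness_index <- function(solution, diameter_mm, height_mm = NULL) {
  if (solution$bcs$delta_d == 0) stop("prescribed displacement is zero")
  if (is.null(height_mm)) height_mm <- solution$mesh$height
  k <- abs(axial_reaction(solution, "bottom")) / solution$bcs$delta_d
  A <- pi * diameter_mm^2 / 4
  k_prime <- solution$material$E * 1000 * A / height_mm
  structure(list(k = k, k_prime = k_prime, index = k / k_prime,
                 geometry = c(diameter_mm = diameter_mm, height_mm = height_mm)),
            class = "stiffness_result")
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("<stiffness_result> k = %.4g N/mm, k' = %.4g N/mm, k/k' = %.4f\n",
              x$k, x$k_prime, x$index))
  invisible(x)
}

#' Export a mesh and load case in ABAQUS input-file dialect
#'
#' Writes *NODE / *ELEMENT (TYPE=C3D8) / *MATERIAL / *BOUNDARY / *STEP
#' sections. [read_inp()] parses the node and element sections back,
#' reproducing the mesh connectivity exactly.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param material a [fe_material()].
#' @param bcs a [boundary_conditions()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_inp <- function(mesh, material, bcs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("*HEADING", "trabecular cylinder uniaxial compression", "*NODE")
  w(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
            mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  w("*ELEMENT, TYPE=C3D8, ELSET=BONE")
  w(sprintf("%d, %s", seq_len(nrow(mesh$elements)),
            apply(mesh$elements, 1, paste, collapse = ", ")))
  w("*NSET, NSET=BOTTOM")
  w(paste(mesh$bottom_nodes, collapse = ", "))
  w("*NSET, NSET=TOP")
  w(paste(mesh$top_nodes, collapse = ", "))
  w("*SOLID SECTION, ELSET=BONE, MATERIAL=BONE_TISSUE",
    "*MATERIAL, NAME=BONE_TISSUE", "*ELASTIC",
    sprintf("%.9g, %.9g", material$E * 1000, material$nu),
    "*STEP", "*STATIC", "*BOUNDARY")
  if (bcs$mode == "bonded") w("BOTTOM, 1, 3, 0.")
  else w("BOTTOM, 3, 3, 0.")
  w(sprintf("TOP, 3, 3, %.9g", -bcs$delta_d))
  w("*END STEP")
  invisible(path)
}

#' @rdname export_inp
#' @param path input file written by [export_inp()].
#' @return `read_inp`: list with `nodes` and `elements` matrices.
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\*", lines)
  section <- function(tag) {
    s <- grep(paste0("^\\*", tag), lines, ignore.case = TRUE)[1]
    if (is.na(s)) return(character())
    nxt <- starts[starts > s]
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    lines[(s + 1):end]
  }
  nd <- do.call(rbind, lapply(strsplit(section("NODE"), ","), as.numeric))
  el <- do.call(rbind, lapply(strsplit(section("ELEMENT"), ","), as.numeric))
  nodes <- nd[order(nd[, 1]), 2:4, drop = FALSE]
  elements <- el[order(el[, 1]), 2:9, drop = FALSE]
  storage.mode(elements) <- "integer"
  nset <- function(name) {
    txt <- section(paste0("NSET, NSET=", name))
    as.integer(unlist(strsplit(paste(txt, collapse = ","), ",")))
  }
  list(nodes = nodes, elements = elements,
       bottom_nodes = nset("BOTTOM"), top_nodes = nset("TOP"))
}
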