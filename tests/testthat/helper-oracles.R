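# Brute-force reference implementations used as oracles by the tests.
# Deliberately simple and slow: correctness is checked against these, never
# the other way around.

# rectangular ROI around a logical mask
as_roi <- function(mask, voxel_size_mm = 0.018) {
  trabstiff:::voxel_roi(mask, voxel_size_mm)
}

# exposed-face count by looping over voxels (6-neighbourhood)
brute_faces <- function(m) {
  d <- dim(m)
  n <- 0L
  at <- function(i, j, k) {
    if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) return(FALSE)
    m[i, j, k]
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- c(at(i - 1, j, k), at(i + 1, j, k), at(i, j - 1, k),
            at(i, j + 1, k), at(i, j, k - 1), at(i, j, k + 1))
    n <- n + sum(!nb)
  }
  n
}

# Euler characteristic by explicit cell enumeration of the cubical complex:
# vertices/edges/faces/cubes of the union of closed unit voxels
brute_euler <- function(m) {
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  key <- function(a) paste(a[, 1], a[, 2], a[, 3], a[, 4])
  cells <- new.env(hash = TRUE)
  add <- function(type, i, j, k) assign(paste(type, i, j, k), TRUE, cells)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    for (a in 0:1) for (b in 0:1) for (c in 0:1) add("V", i + a, j + b, k + c)
    for (b in 0:1) for (c in 0:1) add("Ex", i, j + b, k + c)
    for (a in 0:1) for (c in 0:1) add("Ey", i + a, j, k + c)
    for (a in 0:1) for (b in 0:1) add("Ez", i + a, j + b, k)
    for (a in 0:1) add("Fx", i + a, j, k)
    for (b in 0:1) add("Fy", i, j + b, k)
    for (c in 0:1) add("Fz", i, j, k + c)
    add("C", i, j, k)
  }
  nm <- ls(cells)
  nV <- sum(startsWith(nm, "V "))
  nE <- sum(startsWith(nm, "Ex ") | startsWith(nm, "Ey ") | startsWith(nm, "Ez "))
  nF <- sum(startsWith(nm, "Fx ") | startsWith(nm, "Fy ") | startsWith(nm, "Fz "))
  nC <- sum(startsWith(nm, "C "))
  nV - nE + nF - nC
}

# dense assembly of the global stiffness matrix from the element matrix
dense_assemble <- function(mesh, Ke) {
  n <- nrow(mesh$nodes)
  K <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(mesh$elements))) {
    nd <- mesh$elements[e, ]
    dofs <- as.vector(rbind(3 * nd - 2, 3 * nd - 1, 3 * nd))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

# direct Dirichlet solve; returns full displacement vector (dof-ordered)
dense_solve <- function(mesh, material, bcs) {
  Ke <- hex8_stiffness(material, mesh$edge)
  K <- dense_assemble(mesh, Ke)
  n <- nrow(mesh$nodes)
  u <- rep(0, 3 * n)
  fx <- bcs$fixed_dofs
  free <- setdiff(seq_len(3 * n), fx)
  u[fx] <- bcs$fixed_vals
  rhs <- -K[free, fx, drop = FALSE] %*% bcs$fixed_vals
  Kff <- K[free, free]
  u[free] <- if (bcs$mode == "frictionless") {
    # semidefinite block (in-plane rigid modes); minimum-norm solution
    as.vector(MASS::ginv(Kff) %*% rhs)
  } else {
    solve(Kff, rhs)
  }
  list(u = u, reactions = as.vector(K %*% u))
}

# exhaustive-permutation two-sided Mann-Whitney p (no ties)
perm_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  combs <- utils::combn(n1 + n2, n1)
  U <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lo <- mean(U <= u_obs)
  hi <- mean(U >= u_obs)
  min(1, 2 * min(lo, hi))
}

# small two-phase gray stack wrapper around a mask
mask_stack <- function(mask, voxel_size_mm = 0.018, bone = 200, marrow = 30) {
  g <- array(marrow, dim(mask))
  g[mask] <- bone
  gray_stack(g, voxel_size_mm)
}

# deterministic smoothed random porous mask
porous_mask <- function(dims, fill = 0.5, sigma = 1.5, seed = 1) {
  f <- trabstiff:::with_seed(seed, rnorm(prod(dims)))
  f <- trabstiff:::gauss_blur3d_cpp(f, as.integer(dims), sigma)
  array(f > stats::quantile(f, 1 - fill), dims)
}
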