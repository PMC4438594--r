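#' Bone volume fraction (BV/TV)
#'
#' @param roi a [extract_cylinder()] ROI.
#' @return percent of ROI voxels classified as bone.
#' @export
bv_tv <- function(roi) {
  stopifnot(inherits(roi, "trab_roi"))
  tv <- sum(roi$region)
  if (tv == 0) stop("empty ROI")
  100 * sum(roi$mask) / tv
}

#' Apparent bone mineral density of a ROI
#'
#' Mean calibrated density over every voxel of the cylindrical region (bone
#' and marrow alike): the apparent density that group-level vertebral BMD
#' tables report, well below the tissue mineral density of the bone phase.
#'
#' @param density a [density_stack()] (calibrated, same grid as the ROI).
#' @param roi a `trab_roi`.
#' @return mean density in g/cm^3.
#' @export
mean_bmd <- function(density, roi) {
  stopifnot(inherits(density, "density_stack"), inherits(roi, "trab_roi"))
  if (!identical(dim(density$voxels), dim(roi$region)))
    stop("density stack and ROI dimensions differ")
  if (sum(roi$region) == 0) stop("empty ROI")
  mean(density$voxels[roi$region])
}

#' Local thickness (Tb.Th / Tb.Sp)
#'
#' Mean trabecular thickness (foreground phase) or separation (background
#' phase) by the maximal-inscribed-sphere definition: each phase voxel is
#' assigned the diameter of the largest sphere fully contained in the phase
#' that covers it; the volume-weighted mean of that field is reported in mm.
#' The background phase is the marrow space inside the cylinder, so
#' `local_thickness(roi, "background")` equals the foreground thickness of
#' the complemented ROI by construction.
#'
#' @param roi a `trab_roi`.
#' @param phase `"foreground"` (bone, Tb.Th) or `"background"` (marrow, Tb.Sp).
#' @return mean local thickness in mm.
#' @export
local_thickness <- function(roi, phase = c("foreground", "background")) {
  phase <- match.arg(phase)
  cr <- roi_crop(roi)
  ph <- if (phase == "foreground") cr$mask else cr$region & !cr$mask
  if (!any(ph)) stop("empty ", phase, " phase")
  th <- local_thickness_cpp(as.logical(ph), dim(ph))
  mean(th[as.logical(ph)]) * roi$voxel_size
}

#' Box-counting fractal dimension
#'
#' Slope of log(occupied boxes) against log(1/box size), grid anchored at
#' the array corner. Box sizes are the integer divisors of the smallest grid
#' dimension N in `[2, floor(N/4)]`, so boxes tile the grid exactly and no
#' partial boundary boxes bias the counts; on power-of-two grids this is the
#' usual dyadic ladder 2, 4, 8, ... When fewer than two divisors exist
#' (e.g. prime N) the dyadic ladder is used as a fallback, and for grids too
#' thin to carry two box sizes below N/4 the cap is widened to N/2.
#'
#' @param x a `trab_roi` (3D), a 3D logical array, or a logical matrix (2D).
#' @return fractal dimension estimate.
#' @export
fractal_dimension <- function(x) {
  m <- if (inherits(x, "trab_roi")) roi_crop(x)$mask else x
  if (is.matrix(m)) dim(m) <- c(dim(m), 1L)
  if (!any(m)) stop("empty structure")
  d <- dim(m)
  dims_used <- d[d > 1]
  N <- min(dims_used)
  ladder <- function(smax) {
    if (smax < 2) return(integer(0))
    cand <- 2:smax
    s <- cand[N %% cand == 0]
    if (length(s) < 2) s <- 2^(1:30)[2^(1:30) <= smax]
    s
  }
  # preferred cap N/4; widen to N/2 for grids too thin to carry two sizes
  sizes <- ladder(floor(N / 4))
  if (length(sizes) < 2) sizes <- ladder(floor(N / 2))
  if (length(sizes) < 2)
    stop("structure smaller than the smallest box-size ladder")
  idx <- which(m, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    b <- ceiling(idx / s)
    nrow(unique(b))
  }, 0)
  fit <- lm(log(counts) ~ log(1 / sizes))
  unname(coef(fit)[2])
}

# exposed-face count of a 3D logical array (faces to FALSE or to the border)
exposed_faces <- function(m) {
  d <- dim(m)
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  core <- p[i, j, k, drop = FALSE]
  sum(core & !p[i - 1, j, k, drop = FALSE]) + sum(core & !p[i + 1, j, k, drop = FALSE]) +
  sum(core & !p[i, j - 1, k, drop = FALSE]) + sum(core & !p[i, j + 1, k, drop = FALSE]) +
  sum(core & !p[i, j, k - 1, drop = FALSE]) + sum(core & !p[i, j, k + 1, drop = FALSE])
}

# one-voxel 6-neighborhood dilation, clipped to the grid
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[-1, , ]    <- out[-1, , ]    | m[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, -1, ]    <- out[, -1, ]    | m[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out[, , -1]    <- out[, , -1]    | m[, , -d[3]]
  out
}

#' Trabecular bone pattern factor (Tb.Pf)
#'
#' Dilation method: Tb.Pf = (S1 - S2) / (V1 - V2) where S and V are the
#' structure's surface (exposed voxel faces) and volume before and after a
#' one-voxel 6-neighborhood dilation. Positive for predominantly convex
#' (rod-like, poorly connected) structure, negative for concave / enclosed
#' structure.
#'
#' @param roi a `trab_roi` or 3D logical array (with `voxel_size_mm`).
#' @param voxel_size_mm voxel size for bare arrays.
#' @return Tb.Pf in 1/mm.
#' @export
tb_pf <- function(roi, voxel_size_mm = NULL) {
  if (inherits(roi, "trab_roi")) {
    m <- roi_crop(roi)$mask
    h <- roi$voxel_size
  } else {
    m <- roi
    h <- voxel_size_mm
    if (is.null(h)) stop("voxel_size_mm required for a bare array")
  }
  if (!any(m)) stop("empty mask")
  m2 <- dilate6(m)
  v1 <- sum(m); v2 <- sum(m2)
  if (v2 == v1) stop("degenerate input: dilation changed no voxels")
  s1 <- exposed_faces(m); s2 <- exposed_faces(m2)
  ((s1 - s2) * h^2) / ((v1 - v2) * h^3)
}

# quasi-uniform hemisphere directions (Fibonacci spiral)
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

mil_fit <- function(dirs, y) {
  # y = n' A n, A symmetric; columns for A11,A22,A33,A12,A13,A23
  X <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  use <- if (all(dirs[, 3] == 0)) c(1, 2, 4) else 1:6
  beta <- qr.solve(X[, use, drop = FALSE], y)
  A <- matrix(0, 3, 3)
  co <- numeric(6)
  co[use] <- beta
  A[1, 1] <- co[1]; A[2, 2] <- co[2]; A[3, 3] <- co[3]
  A[1, 2] <- A[2, 1] <- co[4]
  A[1, 3] <- A[3, 1] <- co[5]
  A[2, 3] <- A[3, 2] <- co[6]
  if (all(dirs[, 3] == 0)) A <- A[1:2, 1:2]
  A
}

#' Degree of anisotropy (DA)
#'
#' Mean intercept length (MIL) is sampled over quasi-uniform directions with
#' randomly offset parallel test lines; an MIL ellipsoid tensor is fitted by
#' least squares to 1/MIL^2 and DA = 1 - MIL_min / MIL_max of its principal
#' axes. 0 means isotropic; values approach 1 for strongly oriented
#' structure (the convention in which osteoporotic change reads as a move
#' toward isotropy when DA falls).
#'
#' @param roi a `trab_roi`.
#' @param n_directions number of test directions (Fibonacci hemisphere).
#' @param n_lines parallel lines per direction.
#' @param seed RNG seed for line offsets (recorded in the result).
#' @param step line sampling step in voxels.
#' @return DA in [0, 1) with attributes `mil_axes` (principal MILs, voxel
#'   units) and `seed`.
#' @export
degree_of_anisotropy <- function(roi, n_directions = 64, n_lines = 128,
                                 seed = 1, step = 0.5) {
  cr <- roi_crop(roi)
  if (!any(cr$mask)) stop("no intercepts: empty mask")
  if (all(cr$mask[cr$region])) stop("no intercepts: mask fully solid within the ROI")
  dirs <- fibonacci_hemisphere(n_directions)
  samp <- with_seed(seed, mil_sample_cpp(as.logical(cr$mask), as.logical(cr$region),
                                         dim(cr$mask), dirs, n_lines, step))
  ok <- samp[, 1] > 0
  if (!any(ok)) stop("no intercepts found along sampled lines")
  mil <- samp[ok, 1] / pmax(samp[ok, 2], 0.5) # length per void->bone crossing
  y <- 1 / mil^2
  A <- mil_fit(dirs[ok, , drop = FALSE], y)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, max(lam) * 1e-6)
  mil_axes <- 1 / sqrt(lam)
  da <- 1 - min(mil_axes) / max(mil_axes)
  structure(da, mil_axes = mil_axes, seed = seed)
}

# Euler characteristic of the foreground cubical complex (union of closed
# unit cubes; compatible with 26-connectivity of the foreground).
euler_characteristic <- function(m) {
  d <- dim(m)
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  orx <- function(a) a[-1, , , drop = FALSE] | a[-dim(a)[1], , , drop = FALSE]
  ory <- function(a) a[, -1, , drop = FALSE] | a[, -dim(a)[2], , drop = FALSE]
  orz <- function(a) a[, , -1, drop = FALSE] | a[, , -dim(a)[3], drop = FALSE]
  cells <- sum(m)
  V <- sum(orz(ory(orx(p))))
  Ex <- sum(orz(ory(p))[2:(d[1] + 1), , , drop = FALSE])
  Ey <- sum(orz(orx(p))[, 2:(d[2] + 1), , drop = FALSE])
  Ez <- sum(ory(orx(p))[, , 2:(d[3] + 1), drop = FALSE])
  Fx <- sum(orx(p)[, 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE])
  Fy <- sum(ory(p)[2:(d[1] + 1), , 2:(d[3] + 1), drop = FALSE])
  Fz <- sum(orz(p)[2:(d[1] + 1), 2:(d[2] + 1), , drop = FALSE])
  V - (Ex + Ey + Ez) + (Fx + Fy + Fz) - cells
}

#' Connectivity density (Conn.Dn)
#'
#' Connectivity is estimated from the Euler characteristic of the foreground
#' cubical complex: Conn = 1 - chi, reported per unit ROI volume. For a
#' single component without cavities, Conn equals the number of independent
#' handles (the first Betti number). Conn is reported as-is when the mask
#' has several components (a warning is raised), rather than forcing beta0
#' to 1.
#'
#' @param roi a `trab_roi`.
#' @return Conn.Dn in 1/mm^3, with attributes `euler` and `connectivity`.
#' @export
connectivity_density <- function(roi) {
  cr <- roi_crop(roi)
  if (!any(cr$mask)) stop("empty mask")
  chi <- euler_characteristic(cr$mask)
  ncomp <- count_components_cpp(as.logical(cr$mask), dim(cr$mask))
  if (ncomp > 1)
    warning("mask has ", ncomp, " components; Conn = 1 - chi reported as-is")
  conn <- 1 - chi
  tv <- sum(roi$region) * roi$voxel_size^3
  structure(conn / tv, euler = chi, connectivity = conn)
}

#' Full 3D structural parameter panel
#'
#' Computes the eight-parameter trabecular panel of a cylindrical ROI:
#' BV/TV, apparent BMD, Tb.Th, Tb.Sp, fractal dimension, Tb.Pf, DA and
#' Conn.Dn, plus the ROI volume TV.
#'
#' @param roi a `trab_roi`.
#' @param density optional [density_stack()] for apparent BMD.
#' @param da_seed seed for the MIL direction sampling.
#' @return object of class `morpho3d` (a named list, one value per parameter).
#' @export
analyze_3d <- function(roi, density = NULL, da_seed = 1) {
  out <- list(
    bv_tv = bv_tv(roi),
    bmd = if (is.null(density)) NA_real_ else mean_bmd(density, roi),
    tb_th = local_thickness(roi, "foreground"),
    tb_sp = local_thickness(roi, "background"),
    fd = fractal_dimension(roi),
    tb_pf = tb_pf(roi),
    da = as.numeric(degree_of_anisotropy(roi, seed = da_seed)),
    conn_dn = as.numeric(connectivity_density(roi)),
    tv = sum(roi$region) * roi$voxel_size^3,
    da_seed = da_seed)
  class(out) <- "morpho3d"
  out
}

#' @export
print.morpho3d <- function(x, ...) {
  cat(sprintf(paste0(
    "<morpho3d>  BV/TV %.1f%%  BMD %s g/cm^3  Tb.Th %.3f mm  Tb.Sp %.3f mm\n",
    "            FD %.2f  Tb.Pf %.2f /mm  DA %.3f  Conn.Dn %.1f /mm^3  TV %.2f mm^3\n"),
    x$bv_tv, ifelse(is.na(x$bmd), "NA", sprintf("%.3f", x$bmd)),
    x$tb_th, x$tb_sp, x$fd, x$tb_pf, x$da, x$conn_dn, x$tv))
  invisible(x)
}

# ---- 2D (slice-wise) analogs ----------------------------------------------

slice_thickness <- function(phase2d) {
  if (!any(phase2d)) return(NA_real_)
  th <- local_thickness_cpp(as.logical(phase2d), c(dim(phase2d), 1L))
  mean(th[as.logical(phase2d)])
}

slice_tb_pf <- function(m2d, h) {
  if (!any(m2d)) return(NA_real_)
  m <- m2d; dim(m) <- c(dim(m2d), 1L)
  # 4-neighborhood dilation and exposed-edge perimeter in-plane
  d <- dim(m)
  m2 <- m
  m2[-d[1], , ] <- m2[-d[1], , ] | m[-1, , ]
  m2[-1, , ]    <- m2[-1, , ]    | m[-d[1], , ]
  m2[, -d[2], ] <- m2[, -d[2], ] | m[, -1, ]
  m2[, -1, ]    <- m2[, -1, ]    | m[, -d[2], ]
  per <- function(mm) {
    dd <- dim(mm)
    p <- array(FALSE, dd + c(2, 2, 0))
    p[2:(dd[1] + 1), 2:(dd[2] + 1), ] <- mm
    i <- 2:(dd[1] + 1); j <- 2:(dd[2] + 1)
    core <- p[i, j, , drop = FALSE]
    sum(core & !p[i - 1, j, , drop = FALSE]) + sum(core & !p[i + 1, j, , drop = FALSE]) +
    sum(core & !p[i, j - 1, , drop = FALSE]) + sum(core & !p[i, j + 1, , drop = FALSE])
  }
  a1 <- sum(m); a2 <- sum(m2)
  if (a2 == a1) return(NA_real_)
  ((per(m) - per(m2)) * h) / ((a1 - a2) * h^2)
}

slice_da <- function(m2d, r2d, n_directions = 32, n_lines = 64, seed = 1, step = 0.5) {
  if (!any(m2d) || all(m2d[r2d])) return(NA_real_)
  ang <- pi * (seq_len(n_directions) - 0.5) / n_directions
  dirs <- cbind(cos(ang), sin(ang), 0)
  m <- m2d; dim(m) <- c(dim(m2d), 1L)
  r <- r2d; dim(r) <- c(dim(r2d), 1L)
  samp <- with_seed(seed, mil_sample_cpp(as.logical(m), as.logical(r),
                                         dim(m), dirs, n_lines, step))
  ok <- samp[, 1] > 0 & samp[, 2] > 0
  if (sum(ok) < 3) return(NA_real_)
  mil <- samp[ok, 1] / samp[ok, 2]
  A <- mil_fit(dirs[ok, , drop = FALSE], 1 / mil^2)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, max(lam) * 1e-6)
  ax <- 1 / sqrt(lam)
  1 - min(ax) / max(ax)
}

slice_fd <- function(m2d) {
  if (!any(m2d)) return(NA_real_)
  out <- try(fractal_dimension(m2d), silent = TRUE)
  if (inherits(out, "try-error")) NA_real_ else out
}

#' Slice-wise 2D structural parameters
#'
#' Computes the 2D analogs of the structural panel on each cross-sectional
#' slice of the ROI (area fraction, mean density, disc-based thickness and
#' separation, 2D box-counting dimension, perimeter-based Tb.Pf, in-plane
#' MIL anisotropy; connectivity density has no slice-wise analog and is
#' intentionally absent). Heights are normalized to [0, 1] caudal to cranial.
#'
#' @param roi a `trab_roi` with at least 2 slices.
#' @param density optional [density_stack()].
#' @param da_seed seed for in-plane MIL sampling.
#' @return data.frame with one row per slice: `slice_index`,
#'   `normalized_height`, `bv_tv`, `bmd`, `tb_th`, `tb_sp`, `fd`, `tb_pf`,
#'   `da`.
#' @export
analyze_slices <- function(roi, density = NULL, da_seed = 1) {
  zi <- roi_slices(roi)
  if (length(zi) < 2) stop("need at least 2 slices")
  if (sum(roi$region) == 0) stop("empty ROI")
  h <- roi$voxel_size
  n <- length(zi)
  rows <- lapply(seq_along(zi), function(s) {
    k <- zi[s]
    m <- roi$mask[, , k]
    r <- roi$region[, , k]
    data.frame(
      slice_index = s,
      normalized_height = (s - 1) / (n - 1),
      bv_tv = 100 * sum(m) / sum(r),
      bmd = if (is.null(density)) NA_real_ else mean(density$voxels[, , k][r]),
      tb_th = slice_thickness(m) * h,
      tb_sp = slice_thickness(r & !m) * h,
      fd = slice_fd(m),
      tb_pf = slice_tb_pf(m, h),
      da = slice_da(m, r, seed = da_seed))
  })
  do.call(rbind, rows)
}
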