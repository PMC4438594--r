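#' Wrap a voxel mask as a rectangular ROI
#'
#' Test fixtures (balls, tori, slabs) are conveniently analyzed over their
#' full rectangular grid rather than a cylinder; this wraps a mask (and an
#' optional region of interest) in the same object the morphometry
#' operations accept.
#'
#' @param mask 3D logical array (a matrix is treated as one slice).
#' @param voxel_size_mm voxel edge in mm.
#' @param region optional logical array of ROI membership (default: all).
#' @return a `trab_roi`.
#' @export
voxel_roi <- function(mask, voxel_size_mm, region = NULL) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  d <- dim(mask)
  if (is.null(region)) region <- array(TRUE, d)
  structure(list(mask = mask & region, region = region,
                 voxel_size = voxel_size_mm,
                 cylinder = list(center_xy = c(d[1] / 2, d[2] / 2),
                                 diameter_mm = min(d[1], d[2]) * voxel_size_mm,
                                 z_start = 0, z_end = d[3]),
                 height = d[3] * voxel_size_mm),
            class = "trab_roi")
}

# deterministic geometric masks -------------------------------------------

phantom_ball <- function(radius_vox, dims = rep(2 * radius_vox + 5, 3)) {
  c0 <- (dims + 1) / 2
  x <- slice.index(array(0, dims), 1) - c0[1]
  y <- slice.index(array(0, dims), 2) - c0[2]
  z <- slice.index(array(0, dims), 3) - c0[3]
  x^2 + y^2 + z^2 <= radius_vox^2
}

phantom_torus <- function(R_vox, r_vox, dims = c(2 * (R_vox + r_vox) + 5,
                                                 2 * (R_vox + r_vox) + 5,
                                                 2 * r_vox + 5)) {
  c0 <- (dims + 1) / 2
  x <- slice.index(array(0, dims), 1) - c0[1]
  y <- slice.index(array(0, dims), 2) - c0[2]
  z <- slice.index(array(0, dims), 3) - c0[3]
  (sqrt(x^2 + y^2) - R_vox)^2 + z^2 <= r_vox^2
}

phantom_slab <- function(thickness_vox, dims) {
  m <- array(FALSE, dims)
  i0 <- floor((dims[1] - thickness_vox) / 2)
  m[(i0 + 1):(i0 + thickness_vox), , ] <- TRUE
  m
}

phantom_menger <- function(level = 3, size = 3^(level + 1)) {
  k <- round(log(size, 3))
  if (3^k != size || k < level)
    stop("size must be a power of 3 with 3^level <= size")
  ax <- seq_len(size) - 1
  # iteration t removes the middle cross at cell scale size / 3^t
  digs <- sapply(seq_len(level), function(t) (ax %/% (size / 3^t)) %% 3 == 1)
  if (level == 1) digs <- matrix(digs, ncol = 1)
  m <- array(TRUE, rep(size, 3))
  for (p in seq_len(level)) {
    dx <- digs[slice.index(m, 1), p]
    dy <- digs[slice.index(m, 2), p]
    dz <- digs[slice.index(m, 3), p]
    m <- m & !((dx & dy) | (dx & dz) | (dy & dz))
  }
  m
}

# genus-2 handlebody ("pretzel"): a solid block with two parallel
# through-holes along z; Euler characteristic -1, connectivity 2
phantom_pretzel <- function(hole_vox = 5, wall_vox = 4, depth_vox = 7) {
  w <- wall_vox; h <- hole_vox
  dims <- c(3 * w + 2 * h, 2 * w + h, depth_vox)
  m <- array(TRUE, dims)
  m[(w + 1):(w + h), (w + 1):(w + h), ] <- FALSE
  m[(2 * w + h + 1):(2 * w + 2 * h), (w + 1):(w + h), ] <- FALSE
  m
}

phantom_solid_cylinder <- function(diameter_vox, height_vox, margin = 2) {
  d <- c(diameter_vox + 2 * margin, diameter_vox + 2 * margin, height_vox)
  c0 <- d[1:2] / 2
  rr <- (seq_len(d[1]) - 0.5) - c0[1]
  cc <- (seq_len(d[2]) - 0.5) - c0[2]
  disc <- outer(rr^2, cc^2, `+`) <= (diameter_vox / 2)^2
  array(disc, d)
}

phantom_rod_lattice <- function(width_vox, pitch_vox, dims) {
  i <- (slice.index(array(0, dims), 1) - 1) %% pitch_vox < width_vox
  j <- (slice.index(array(0, dims), 2) - 1) %% pitch_vox < width_vox
  i & j
}

phantom_plate_lattice <- function(thickness_vox, pitch_vox, dims) {
  (slice.index(array(0, dims), 1) - 1) %% pitch_vox < thickness_vox
}

#' Construct a geometric phantom fixture
#'
#' Deterministic voxel fixtures with known analytic properties, plus a
#' matching 8-bit gray stack with uniform bone and marrow gray levels
#' (defaults 200 and 30, straddling the 70..255 segmentation window).
#'
#' @param kind one of `"solid_cylinder"`, `"rod_lattice"`, `"plate_lattice"`,
#'   `"gaussian_trabecular"`, `"ball"`, `"torus"`, `"slab"`, `"menger"`,
#'   `"pretzel"` (a genus-2 handlebody: block with two through-holes).
#' @param voxel_size_mm voxel edge in mm (default 0.018).
#' @param dims grid dimensions where the kind does not imply them.
#' @param bone_gray,marrow_gray gray levels of the two phases.
#' @param ... kind parameters: `radius_vox` (ball), `R_vox`/`r_vox` (torus),
#'   `thickness_vox` (slab, plate_lattice), `level` (menger),
#'   `diameter_vox`/`height_vox` (solid_cylinder), `width_vox`/`pitch_vox`
#'   (lattices), and the [gaussian_trabecular()] parameters.
#' @return list with `roi` (a `trab_roi`), `stack` (a [gray_stack()]) and
#'   `spec` (the parameters used).
#' @export
make_phantom <- function(kind = c("solid_cylinder", "rod_lattice", "plate_lattice",
                                  "gaussian_trabecular", "ball", "torus",
                                  "slab", "menger", "pretzel"),
                         voxel_size_mm = 0.018, dims = NULL,
                         bone_gray = 200, marrow_gray = 30, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  if (kind == "gaussian_trabecular") {
    roi <- do.call(gaussian_trabecular,
                   c(list(voxel_size_mm = voxel_size_mm),
                     if (!is.null(dims)) list(dims = dims), args))
  } else {
    mask <- switch(kind,
      ball = do.call(phantom_ball, c(args, if (!is.null(dims)) list(dims = dims))),
      torus = do.call(phantom_torus, c(args, if (!is.null(dims)) list(dims = dims))),
      slab = phantom_slab(args$thickness_vox, dims),
      menger = do.call(phantom_menger, args),
      pretzel = do.call(phantom_pretzel, args),
      solid_cylinder = do.call(phantom_solid_cylinder, args),
      rod_lattice = phantom_rod_lattice(args$width_vox, args$pitch_vox, dims),
      plate_lattice = phantom_plate_lattice(args$thickness_vox, args$pitch_vox, dims))
    if (any(vapply(dim(mask), function(x) x <= 0, TRUE))) stop("invalid dims")
    roi <- if (kind == "solid_cylinder")
      extract_cylinder(mask, voxel_size_mm,
                       diameter_mm = args$diameter_vox * voxel_size_mm)
    else voxel_roi(mask, voxel_size_mm)
  }
  gray <- array(marrow_gray, dim(roi$mask))
  gray[roi$mask] <- bone_gray
  list(roi = roi, stack = gray_stack(gray, voxel_size_mm),
       spec = c(list(kind = kind, voxel_size_mm = voxel_size_mm,
                     bone_gray = bone_gray, marrow_gray = marrow_gray), args))
}

#' Gaussian-random-field trabecular phantom
#'
#' Seeded white noise smoothed at the stated correlation scale and
#' thresholded at the field quantile that brings the bone volume fraction
#' inside the cylindrical ROI to the target (within far less than 0.5
#' percentage points). The smoothing scale sets the trabecular scale: a
#' scale of ~3 voxels yields structures around 5-6 voxels thick.
#'
#' @param dims grid dimensions (default 68 x 68 x 100).
#' @param voxel_size_mm voxel edge in mm.
#' @param scale Gaussian smoothing sigma in voxels (>= 1).
#' @param target_bvtv target bone volume fraction in percent.
#' @param diameter_mm ROI cylinder diameter (default 64 voxels).
#' @param seed RNG seed (recorded in the result).
#' @return a `trab_roi` with attributes `field`, `threshold`, `seed`.
#' @export
gaussian_trabecular <- function(dims = c(68, 68, 100), voxel_size_mm = 0.018,
                                scale = 3, target_bvtv = 35,
                                diameter_mm = 64 * voxel_size_mm, seed = 1) {
  stopifnot(scale >= 1, target_bvtv > 0, target_bvtv < 100)
  noise <- with_seed(seed, rnorm(prod(dims)))
  field <- array(gauss_blur3d_cpp(noise, as.integer(dims), scale), dims)
  shell <- extract_cylinder(array(TRUE, dims), voxel_size_mm,
                            diameter_mm = diameter_mm)
  thr <- stats::quantile(field[shell$region], 1 - target_bvtv / 100,
                         names = FALSE, type = 1)
  roi <- shell
  roi$mask <- (field > thr) & roi$region
  attr(roi, "field") <- field
  attr(roi, "threshold") <- thr
  attr(roi, "seed") <- seed
  roi
}

#' Osteoporosis-like thinning transform
#'
#' Emulates estrogen-depletion bone loss by raising the segmentation
#' threshold on the same underlying field the phantom was generated from
#' (surface-biased erosion): the output mask is a strict subset of the
#' input and the bone volume fraction drops by `delta_bvtv` percentage
#' points. For masks without a stored field, the distance transform of the
#' bone phase serves as the erosion field.
#'
#' @param roi a `trab_roi` (typically from [gaussian_trabecular()]).
#' @param delta_bvtv drop in BV/TV, percentage points (default 12, the
#'   scale of contrast seen between sham and estrogen-depleted vertebrae).
#' @return a `trab_roi` with the thinned mask.
#' @export
ovx_transform <- function(roi, delta_bvtv = 12) {
  cur <- bv_tv(roi)
  if (delta_bvtv < 0) stop("delta_bvtv must be non-negative")
  if (delta_bvtv == 0) return(roi)
  if (delta_bvtv >= cur)
    stop(sprintf("infeasible delta: current BV/TV is %.1f%%", cur))
  field <- attr(roi, "field")
  if (is.null(field)) {
    field <- array(edt_sq_cpp(as.logical(roi$mask), dim(roi$mask)), dim(roi$mask))
    field[!roi$mask] <- -Inf
  }
  target <- cur - delta_bvtv
  vals <- field[roi$region & roi$mask]
  n_region <- sum(roi$region)
  n_target <- round(n_region * target / 100)
  if (n_target < 1) stop("infeasible delta")
  thr <- sort(vals, decreasing = TRUE)[n_target]
  out <- roi
  out$mask <- roi$mask & (field >= thr)
  # resolve ties at the threshold deterministically by dropping excess voxels
  excess <- sum(out$mask) - n_target
  if (excess > 0) {
    tied <- which(out$mask & (field == thr))
    out$mask[tied[seq_len(excess)]] <- FALSE
  }
  attr(out, "field") <- attr(roi, "field")
  attr(out, "threshold") <- thr
  attr(out, "seed") <- attr(roi, "seed")
  out
}

#' Carve a transverse foramen-like channel
#'
#' Clears a cylindrical channel running transversely through the ROI at
#' mid-height, emulating the vascular foramen that depresses mid-height
#' bone fraction in vertebral bodies.
#'
#' @param roi a `trab_roi`.
#' @param radius_mm channel radius (must be smaller than the ROI radius).
#' @return the ROI with the channel cleared from the mask.
#' @export
add_foramen <- function(roi, radius_mm) {
  if (radius_mm < 0) stop("negative radius")
  if (radius_mm == 0) return(roi)
  if (radius_mm >= roi$cylinder$diameter_mm / 2)
    stop("channel radius exceeds ROI radius")
  d <- dim(roi$mask)
  h <- roi$voxel_size
  r_vox <- radius_mm / h
  zc <- (roi$cylinder$z_start + roi$cylinder$z_end) / 2
  xc <- roi$cylinder$center_xy[1]
  x <- slice.index(array(0, d), 1) - 0.5 - xc
  z <- slice.index(array(0, d), 3) - 0.5 - zc
  channel <- x^2 + z^2 <= r_vox^2
  out <- roi
  out$mask <- roi$mask & !channel
  out
}

#' Generate a synthetic two-group study
#'
#' Builds `n_per_group` sham specimens (Gaussian trabecular phantoms with
#' per-specimen target BV/TV drawn around the sham mean) and their
#' estrogen-depleted siblings (the same fields thinned by [ovx_transform()]),
#' for each requested vertebral level. Per-specimen seeds are derived
#' deterministically from the master seed; every specimen records its seed
#' and ground-truth parameters.
#'
#' @param n_per_group specimens per group (>= 2; default 10).
#' @param levels vertebral level labels per specimen.
#' @param target_bvtv sham group mean BV/TV in percent.
#' @param bvtv_sd between-specimen SD of the target, percentage points.
#' @param delta_bvtv OVX-like deficit, percentage points.
#' @param scale trabecular smoothing scale in voxels.
#' @param dims,voxel_size_mm,diameter_mm phantom geometry (see
#'   [gaussian_trabecular()]).
#' @param foramen_radius_mm optional transverse channel radius (0 = none).
#' @param seed master seed.
#' @return object of class `trab_study`: list with `specimens` (each with
#'   `id`, `group`, `level`, `roi`, `truth`) and the generating `spec`.
#' @export
generate_study <- function(n_per_group = 10, levels = c("L4", "L5", "L6"),
                           target_bvtv = 35, bvtv_sd = 4, delta_bvtv = 12,
                           scale = 3, dims = c(68, 68, 100),
                           voxel_size_mm = 0.018,
                           diameter_mm = 64 * voxel_size_mm,
                           foramen_radius_mm = 0, seed = 1) {
  stopifnot(n_per_group >= 2)
  n_cells <- n_per_group * length(levels)
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1, n_cells),
    targets = rnorm(n_cells, target_bvtv, bvtv_sd)))
  targets <- pmin(pmax(draws$targets, delta_bvtv + 8), 60)
  specimens <- list()
  cell <- 0
  for (i in seq_len(n_per_group)) for (l in levels) {
    cell <- cell + 1
    sham <- gaussian_trabecular(dims = dims, voxel_size_mm = voxel_size_mm,
                                scale = scale, target_bvtv = targets[cell],
                                diameter_mm = diameter_mm,
                                seed = draws$seeds[cell])
    if (foramen_radius_mm > 0) sham <- add_foramen(sham, foramen_radius_mm)
    ovx <- ovx_transform(sham, delta_bvtv)
    truth <- list(target_bvtv = targets[cell], delta_bvtv = delta_bvtv,
                  seed = draws$seeds[cell], scale = scale)
    specimens[[length(specimens) + 1]] <-
      list(id = sprintf("sham_%02d", i), group = "sham", level = l,
           roi = sham, truth = truth)
    specimens[[length(specimens) + 1]] <-
      list(id = sprintf("ovx_%02d", i), group = "ovx", level = l,
           roi = ovx, truth = truth)
  }
  structure(list(specimens = specimens,
                 spec = list(n_per_group = n_per_group, levels = levels,
                             target_bvtv = target_bvtv, bvtv_sd = bvtv_sd,
                             delta_bvtv = delta_bvtv, scale = scale,
                             dims = dims, voxel_size_mm = voxel_size_mm,
                             diameter_mm = diameter_mm,
                             foramen_radius_mm = foramen_radius_mm,
                             seed = seed)),
            class = "trab_study")
}

#' @export
print.trab_study <- function(x, ...) {
  cat(sprintf("<trab_study> %d specimens (%d/group x %d levels), seed %d\n",
              length(x$specimens), x$spec$n_per_group,
              length(x$spec$levels), x$spec$seed))
  invisible(x)
}
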