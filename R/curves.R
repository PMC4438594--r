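#' Parameter curve along the normalized cylinder height
#'
#' @param parameter parameter name (e.g. "bv_tv").
#' @param grid normalized heights, strictly increasing from 0 to 1.
#' @param values parameter values at the grid nodes.
#' @return object of class `param_curve`.
#' @export
param_curve <- function(parameter, grid, values) {
  stopifnot(length(grid) == length(values), length(grid) >= 2)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (abs(grid[1]) > 1e-9 || abs(grid[length(grid)] - 1) > 1e-9)
    stop("grid endpoints must be 0 and 1")
  if (any(!is.finite(values))) stop("curve values must be finite")
  structure(list(parameter = parameter, grid = as.numeric(grid),
                 values = as.numeric(values)),
            class = "param_curve")
}

#' @export
print.param_curve <- function(x, ...) {
  cat(sprintf("<param_curve> %s, %d points, range [%.4g, %.4g]\n",
              x$parameter, length(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' Extract parameter curves from a slice-wise morphometry table
#'
#' @param slices data.frame from [analyze_slices()].
#' @param parameters column names to extract.
#' @return named list of [param_curve()]s (slices with NA values are
#'   linearly bridged; all-NA parameters are dropped).
#' @export
slice_curves <- function(slices,
                         parameters = c("bv_tv", "bmd", "tb_th", "tb_sp",
                                        "fd", "tb_pf", "da")) {
  out <- list()
  for (p in parameters) {
    v <- slices[[p]]
    if (is.null(v) || all(is.na(v))) next
    if (anyNA(v)) v <- stats::approx(slices$normalized_height[!is.na(v)],
                                     v[!is.na(v)],
                                     xout = slices$normalized_height,
                                     rule = 2)$y
    out[[p]] <- param_curve(p, slices$normalized_height, v)
  }
  out
}

#' Resample a curve onto a uniform grid
#'
#' Linear interpolation onto `n_points` equally spaced heights on [0, 1];
#' endpoints are preserved exactly.
#'
#' @param curve a [param_curve()].
#' @param n_points number of grid nodes (>= 2).
#' @return a [param_curve()] on the uniform grid.
#' @export
resample_curve <- function(curve, n_points = 100) {
  if (n_points < 2) stop("n_points must be at least 2")
  g <- seq(0, 1, length.out = n_points)
  v <- stats::approx(curve$grid, curve$values, xout = g)$y
  param_curve(curve$parameter, g, v)
}

#' Average curves across specimens
#'
#' Pointwise mean after resampling every curve to a common uniform grid;
#' used to average a group's L4/L5/L6 curves into one representative curve.
#'
#' @param curves list of [param_curve()]s of the same parameter.
#' @param n_points common grid size.
#' @return a [param_curve()].
#' @export
average_curves <- function(curves, n_points = 100) {
  stopifnot(length(curves) >= 1)
  pars <- unique(vapply(curves, `[[`, "", "parameter"))
  if (length(pars) != 1) stop("cannot average curves of different parameters")
  rs <- lapply(curves, resample_curve, n_points = n_points)
  vals <- rowMeans(vapply(rs, `[[`, numeric(n_points), "values"))
  param_curve(pars, rs[[1]]$grid, vals)
}

#' Difference of two curves (a - b)
#'
#' @param a,b [param_curve()]s of the same parameter.
#' @param n_points common grid size.
#' @return a [param_curve()] of pointwise differences.
#' @export
difference_curve <- function(a, b, n_points = 100) {
  if (!identical(a$parameter, b$parameter))
    stop("cannot difference curves of different parameters")
  ra <- resample_curve(a, n_points)
  rb <- resample_curve(b, n_points)
  param_curve(a$parameter, ra$grid, ra$values - rb$values)
}

#' Select the sub-region with the largest between-group difference
#'
#' Scores every contiguous window covering the given fraction of the
#' cylinder height by the mean absolute between-group difference, averaged
#' over parameter curves after rescaling each curve to unit maximum absolute
#' difference (so parameters with opposite-signed differences, such as
#' Tb.Sp, contribute on equal footing). Ties break toward the caudal end.
#'
#' With `fixed_caudal = TRUE` the scoring is bypassed and the caudal-anchored
#' window of the given fraction is returned directly (the conventional fixed
#' choice of the caudal 40%).
#'
#' @param diffs list of difference [param_curve()]s.
#' @param fraction window length as a fraction of the cylinder (0, 1].
#' @param n_slices number of slices of the target stack.
#' @param fixed_caudal use the fixed caudal window instead of scoring.
#' @return object of class `region_selection` with fields `anchor`,
#'   `fraction`, `z_window` (first/last slice, 1-based) and `window_scores`.
#' @export
select_region <- function(diffs, fraction = 0.4, n_slices, fixed_caudal = FALSE) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  stopifnot(length(diffs) >= 1, n_slices >= 2)
  w <- max(1L, as.integer(round(fraction * n_slices)))
  n_starts <- n_slices - w + 1L
  score <- rep(0, n_slices)
  for (cv in diffs) {
    v <- abs(resample_curve(cv, n_slices)$values)
    mx <- max(v)
    if (mx > 0) v <- v / mx
    score <- score + v / length(diffs)
  }
  win_scores <- vapply(seq_len(n_starts),
                       function(s) mean(score[s:(s + w - 1L)]), 0)
  start <- if (fixed_caudal) 1L else which.max(win_scores) # which.max: first max (caudal tie-break)
  structure(list(anchor = if (start == 1L) "caudal" else "interior",
                 fraction = fraction,
                 z_window = c(start, start + w - 1L),
                 window_scores = win_scores),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat(sprintf("<region_selection> slices %d..%d (fraction %.2f, %s anchor)\n",
              x$z_window[1], x$z_window[2], x$fraction, x$anchor))
  invisible(x)
}
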