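#' Default pipeline configuration
#'
#' All defaults follow the conventional settings of the workflow: threshold
#' window 70..255, caudal 40% fixed sub-region selection, E = 24.5 GPa,
#' nu = 0.3, apparent strain 0.05, fully-fixed bottom platen.
#'
#' @param ... overrides for any field.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    threshold = c(70, 255),
    anchors = rbind(c(100, 0.25), c(220, 0.75)),
    fraction = 0.4,
    fixed_caudal = TRUE,
    E = 24.5, nu = 0.3, strain = 0.05,
    mode = "bonded",
    tol = 1e-8, max_iter = 20000,
    n_points = 100,
    da_seed = 1,
    seed = 1,
    out_dir = NULL,
    study = list(n_per_group = 10, levels = "L4", target_bvtv = 35,
                 bvtv_sd = 4, delta_bvtv = 12, scale = 3,
                 dims = c(68, 68, 100), voxel_size_mm = 0.018,
                 diameter_mm = 64 * 0.018, foramen_radius_mm = 0))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Missing fields fall back to [default_config()].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(raw)) {
    if (nm == "study" && is.list(raw$study)) {
      for (s in names(raw$study)) cfg$study[[s]] <- raw$study[[s]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(cfg$anchors)) cfg$anchors <- matrix(unlist(cfg$anchors), ncol = 2)
  cfg
}

# density stack from a ROI's two-phase gray representation
roi_density <- function(roi, calib, bone_gray = 200, marrow_gray = 30) {
  gray <- array(marrow_gray, dim(roi$mask))
  gray[roi$mask] <- bone_gray
  apply_calibration(gray_stack(gray, roi$voxel_size), calib)
}

# restrict a ROI to a window of its own slices (1-based, inclusive)
roi_subregion <- function(roi, z_window) {
  zi <- roi_slices(roi)
  stopifnot(z_window[1] >= 1, z_window[2] <= length(zi))
  keep <- zi[z_window[1]:z_window[2]]
  out <- roi
  sel <- array(FALSE, dim(roi$mask))
  sel[, , keep] <- TRUE
  out$region <- roi$region & sel
  out$mask <- roi$mask & sel
  out$cylinder$z_start <- keep[1] - 1
  out$cylinder$z_end <- keep[length(keep)]
  out$height <- length(keep) * roi$voxel_size
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end workflow on a two-group study: per specimen, density
#' calibration, segmentation (for image input), cylindrical ROI, 3D
#' morphometry and slice-wise 2D curves; per group, averaged curves and
#' between-group difference curves guiding the selection of the caudal
#' sub-region; per specimen again, voxel hex8 meshing, linear elastic
#' compression, the stiffness index k/k' and 3D morphometry of the selected
#' segment; finally the group/level summary, between-group tests and the
#' within-group Pearson correlations of each structural parameter against
#' k/k'.
#'
#' @param config a [default_config()]-style list (or a path readable by
#'   [read_config()]). If `config$study` is set, a synthetic study is
#'   generated; otherwise `config$inputs` must list specimen image stacks
#'   (`path`, `group`, `level`, one entry per specimen).
#' @param quiet suppress progress messages.
#' @return object of class `trab_report`: `morpho3d` and `slices` tables,
#'   `selection`, `segment_morpho` (selected-region 3D panel), `stiffness`
#'   table, `summary` ([summarize_study()] of the full-ROI panel),
#'   `stiffness_test`, `correlations`, and the `config` used.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  calib <- fit_density_calibration(config$anchors)

  # ---- specimens --------------------------------------------------------
  if (!is.null(config$study)) {
    say("generating synthetic study (seed %d)", config$seed)
    st <- config$study
    study <- generate_study(n_per_group = st$n_per_group, levels = st$levels,
                            target_bvtv = st$target_bvtv, bvtv_sd = st$bvtv_sd,
                            delta_bvtv = st$delta_bvtv, scale = st$scale,
                            dims = st$dims, voxel_size_mm = st$voxel_size_mm,
                            diameter_mm = st$diameter_mm %||%
                              (64 * st$voxel_size_mm),
                            foramen_radius_mm = st$foramen_radius_mm,
                            seed = config$seed)
    specimens <- study$specimens
  } else {
    if (is.null(config$inputs)) stop("config needs either a study spec or inputs")
    specimens <- lapply(config$inputs, function(inp) {
      stk <- read_stack(inp$path, inp$voxel_size_mm)
      mask <- segment_bone(stk, config$threshold[1], config$threshold[2])
      roi <- extract_cylinder(mask, stk$voxel_size,
                              diameter_mm = inp$diameter_mm)
      list(id = inp$id %||% basename(inp$path), group = inp$group,
           level = inp$level %||% "L4", roi = roi, truth = NULL)
    })
  }
  # deterministic ordering regardless of input order
  ord <- order(vapply(specimens, function(s) paste(s$group, s$id, s$level), ""))
  specimens <- specimens[ord]

  # ---- per-specimen morphometry and curves ------------------------------
  say("morphometry on %d specimens", length(specimens))
  m3d_rows <- list()
  slice_tabs <- list()
  for (s in specimens) {
    dens <- roi_density(s$roi, calib)
    m <- analyze_3d(s$roi, dens, da_seed = config$da_seed)
    m3d_rows[[length(m3d_rows) + 1]] <-
      data.frame(specimen = s$id, group = s$group, level = s$level,
                 bv_tv = m$bv_tv, bmd = m$bmd, tb_th = m$tb_th,
                 tb_sp = m$tb_sp, fd = m$fd, tb_pf = m$tb_pf, da = m$da,
                 conn_dn = m$conn_dn, tv = m$tv)
    sl <- analyze_slices(s$roi, dens, da_seed = config$da_seed)
    sl$specimen <- s$id; sl$group <- s$group; sl$level <- s$level
    slice_tabs[[length(slice_tabs) + 1]] <- sl
  }
  morpho3d <- do.call(rbind, m3d_rows)
  slices <- do.call(rbind, slice_tabs)

  # ---- group curves, differences, region selection ----------------------
  pars <- c("bv_tv", "bmd", "fd", "tb_sp", "tb_pf")
  groups <- sort(unique(morpho3d$group))
  gcurves <- lapply(groups, function(g) {
    gs <- slices[slices$group == g, ]
    per_spec <- lapply(split(gs, interaction(gs$specimen, gs$level, drop = TRUE)),
                       slice_curves, parameters = pars)
    lapply(pars, function(p)
      average_curves(Filter(Negate(is.null), lapply(per_spec, `[[`, p)),
                     n_points = config$n_points))
  })
  names(gcurves) <- groups
  diffs <- NULL
  selection <- NULL
  n_roi_slices <- length(roi_slices(specimens[[1]]$roi))
  if (length(groups) == 2) {
    diffs <- lapply(seq_along(pars), function(i)
      difference_curve(gcurves[[1]][[i]], gcurves[[2]][[i]],
                       n_points = config$n_points))
    selection <- select_region(diffs, fraction = config$fraction,
                               n_slices = n_roi_slices,
                               fixed_caudal = isTRUE(config$fixed_caudal))
  } else {
    w <- max(1L, as.integer(round(config$fraction * n_roi_slices)))
    selection <- structure(list(anchor = "caudal", fraction = config$fraction,
                                z_window = c(1L, w), window_scores = NULL),
                           class = "region_selection")
  }
  say("selected slices %d..%d for FEA", selection$z_window[1], selection$z_window[2])

  # ---- FE on the selected segment ---------------------------------------
  material <- fe_material(config$E, config$nu)
  seg_rows <- list()
  stiff_rows <- list()
  for (s in specimens) {
    sub <- roi_subregion(s$roi, selection$z_window)
    dens <- roi_density(sub, calib)
    m <- analyze_3d(sub, dens, da_seed = config$da_seed)
    seg_rows[[length(seg_rows) + 1]] <-
      data.frame(specimen = s$id, group = s$group, level = s$level,
                 bv_tv = m$bv_tv, bmd = m$bmd, tb_th = m$tb_th,
                 tb_sp = m$tb_sp, fd = m$fd, tb_pf = m$tb_pf, da = m$da,
                 conn_dn = m$conn_dn)
    mesh <- tryCatch(build_mesh(sub), error = function(e) {
      if (grepl("no load path", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(mesh)) {
      # no bone spans the platens: the segment carries no load, k = 0
      warning(sprintf("%s %s: no spanning bone, stiffness recorded as 0",
                      s$id, s$level))
      kp <- fe_material(config$E, config$nu)$E * 1000 *
        pi * sub$cylinder$diameter_mm^2 / 4 / sub$height
      stiff_rows[[length(stiff_rows) + 1]] <-
        data.frame(specimen = s$id, group = s$group, level = s$level,
                   k = 0, k_prime = kp, index = 0, elements = 0L,
                   removed_fraction = 1, iterations = 0L, residual = 0)
      next
    }
    if (mesh$removed_fraction > 0.05)
      warning(sprintf("%s %s: %.1f%% of bone voxels off the load path",
                      s$id, s$level, 100 * mesh$removed_fraction))
    bcs <- boundary_conditions(mesh, strain = config$strain, mode = config$mode)
    sol <- solve_fe(mesh, material, bcs, tol = config$tol,
                    max_iter = config$max_iter)
    res <- stiffness_index(sol, sub$cylinder$diameter_mm)
    if (!is.null(config$out_dir)) {
      inp_dir <- file.path(config$out_dir, "inp")
      dir.create(inp_dir, showWarnings = FALSE, recursive = TRUE)
      export_inp(mesh, material, bcs,
                 file.path(inp_dir, sprintf("%s_%s.inp", s$id, s$level)))
    }
    say("  %s %s: %d elements, %d CG iterations, k/k' = %.3f",
        s$id, s$level, nrow(mesh$elements), sol$iterations, res$index)
    stiff_rows[[length(stiff_rows) + 1]] <-
      data.frame(specimen = s$id, group = s$group, level = s$level,
                 k = res$k, k_prime = res$k_prime, index = res$index,
                 elements = nrow(mesh$elements),
                 removed_fraction = mesh$removed_fraction,
                 iterations = sol$iterations, residual = sol$residual)
  }
  segment_morpho <- do.call(rbind, seg_rows)
  stiffness <- do.call(rbind, stiff_rows)

  # ---- statistics -------------------------------------------------------
  long <- do.call(rbind, lapply(
    c("bv_tv", "bmd", "tb_th", "tb_sp", "fd", "tb_pf", "da", "conn_dn"),
    function(p) data.frame(specimen = morpho3d$specimen, group = morpho3d$group,
                           level = morpho3d$level, parameter = p,
                           value = morpho3d[[p]])))
  summary <- summarize_study(long)
  stiffness_test <- NULL
  if (length(groups) == 2) {
    stiffness_test <- mann_whitney_u(
      stiffness$index[stiffness$group == groups[1]],
      stiffness$index[stiffness$group == groups[2]], mode = "asymptotic")
  }
  corr_pars <- c("bv_tv", "bmd", "tb_th", "tb_sp", "fd", "tb_pf", "da", "conn_dn")
  correlations <- do.call(rbind, lapply(corr_pars, function(p) {
    do.call(rbind, lapply(c(groups, "pooled"), function(g) {
      rows <- if (g == "pooled") rep(TRUE, nrow(segment_morpho))
              else segment_morpho$group == g
      x <- segment_morpho[[p]][rows]
      y <- stiffness$index[rows]
      if (sum(rows) < 3 || sd(x) == 0 || sd(y) == 0) return(NULL)
      ct <- pearson_correlation(x, y)
      data.frame(parameter = p, group = g, r = ct$statistic, p_value = ct$p,
                 pooled = g == "pooled")
    }))
  }))

  report <- structure(list(
    morpho3d = morpho3d, slices = slices, selection = selection,
    segment_morpho = segment_morpho, stiffness = stiffness,
    summary = summary, stiffness_test = stiffness_test,
    correlations = correlations, config = config,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "trab_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report to disk
#'
#' CSV tables plus a JSON manifest recording the configuration and seeds.
#'
#' @param report a `trab_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$morpho3d, file.path(out_dir, "morpho3d.csv"), row.names = FALSE)
  write.csv(report$slices, file.path(out_dir, "slices_2d.csv"), row.names = FALSE)
  write.csv(report$segment_morpho, file.path(out_dir, "segment_morpho3d.csv"),
            row.names = FALSE)
  write.csv(report$stiffness, file.path(out_dir, "stiffness.csv"), row.names = FALSE)
  write.csv(report$correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(report$summary$cells, file.path(out_dir, "summary_cells.csv"),
            row.names = FALSE)
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(report$config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("trabstiff")),
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   selection = report$selection[c("anchor", "fraction", "z_window")],
                   config_hash = unname(tools::md5sum(cfg_file)),
                   config = report$config)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.trab_report <- function(x, ...) {
  cat(sprintf("<trab_report> %d specimens, slices %d..%d selected\n",
              nrow(x$stiffness), x$selection$z_window[1], x$selection$z_window[2]))
  agg <- aggregate(index ~ group, x$stiffness, function(v) c(mean = mean(v), sd = sd(v)))
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  k/k' %-6s %.3f +- %.3f\n", agg$group[i],
                agg$index[i, "mean"], agg$index[i, "sd"]))
  if (!is.null(x$stiffness_test))
    cat(sprintf("  between-group Mann-Whitney p = %.4g\n", x$stiffness_test$p))
  invisible(x)
}
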