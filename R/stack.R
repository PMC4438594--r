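#' Grayscale image stack
#'
#' Container for an 8-bit micro-CT cross-sectional image stack. Voxels are
#' stored as an integer array of dimension (rows, cols, slices); the slice
#' axis runs caudal to cranial (first slice = caudal end).
#'
#' @param voxels integer array (rows x cols x slices) with values in 0..255;
#'   a matrix is treated as a single slice.
#' @param voxel_size_mm isotropic voxel edge length in mm (18 um scans: 0.018).
#' @return object of class `gray_stack` with fields `voxels`, `voxel_size`
#'   and `axis_order` (a declaration that slices stack along the third axis,
#'   caudal first).
#' @export
gray_stack <- function(voxels, voxel_size_mm) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3)
  if (anyNA(voxels)) stop("voxels contain NA")
  if (min(voxels) < 0 || max(voxels) > 255) stop("gray values must lie in [0, 255]")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1 || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a single positive number")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, voxel_size = voxel_size_mm,
                 axis_order = "rows,cols,slices (slice axis caudal->cranial)"),
            class = "gray_stack")
}

#' @export
print.gray_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<gray_stack> %d x %d pixels, %d slices, voxel %g mm\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' Calibrated density stack
#'
#' @param voxels numeric array of mineral-equivalent density (g/cm^3).
#' @param voxel_size_mm voxel edge length in mm.
#' @return object of class `density_stack`.
#' @export
density_stack <- function(voxels, voxel_size_mm) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3, voxel_size_mm > 0)
  structure(list(voxels = voxels, voxel_size = voxel_size_mm),
            class = "density_stack")
}

#' @export
print.density_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<density_stack> %d x %d x %d, voxel %g mm, mean %.4f g/cm^3\n",
              d[1], d[2], d[3], x$voxel_size, mean(x$voxels)))
  invisible(x)
}

# numeric-aware filename ordering: digit runs compare by value
natural_sort <- function(x) {
  key <- vapply(x, function(s) {
    g <- gregexpr("[0-9]+", s)[[1]]
    if (g[1] == -1) return(s)
    m <- regmatches(s, list(g))[[1]]
    pad <- vapply(m, function(v) paste0(strrep("0", max(0, 20 - nchar(v))), v), "")
    regmatches(s, list(g)) <- list(pad)
    s
  }, "")
  x[order(key)]
}

read_slice_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) {
      if (dim(img)[3] >= 3 &&
          !isTRUE(all.equal(img[, , 1], img[, , 2]))) {
        stop("non-grayscale image: ", path)
      }
      img <- img[, , 1]
    }
    return(as.integer(round(img * 255)))
  }
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (max(img) > 255) stop("non-8-bit image data: ", path)
    return(as.integer(img))
  }
  if (ext == "bmp") return(read_bmp8(path))
  stop("unsupported image format: ", path)
}

slice_dims <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    d <- dim(png::readPNG(path))
  } else if (ext %in% c("tif", "tiff")) {
    d <- dim(tiff::readTIFF(path, as.is = TRUE))
  } else {
    d <- dim(read_bmp8(path))
  }
  d[1:2]
}

#' Read an image stack
#'
#' Reads a directory of single-slice images (PNG, TIFF or 8-bit BMP, one file
#' per slice, ordered by numeric-aware filename sort) or a single multi-page
#' TIFF. The first slice in sort order is taken as the caudal end.
#'
#' If `voxel_size_mm` is omitted, a sidecar file `metadata.txt` next to the
#' images is consulted (plain `key: value` lines with a `voxel_size_mm` key).
#'
#' @param path directory of slice images, or a single image file.
#' @param voxel_size_mm voxel edge length in mm; optional when a sidecar
#'   metadata file provides it.
#' @return a [gray_stack()].
#' @export
read_stack <- function(path, voxel_size_mm = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (is.null(voxel_size_mm)) {
    side <- file.path(if (dir.exists(path)) path else dirname(path), "metadata.txt")
    if (file.exists(side)) {
      meta <- read_sidecar(side)
      voxel_size_mm <- as.numeric(meta[["voxel_size_mm"]])
    }
    if (is.null(voxel_size_mm) || !length(voxel_size_mm) || is.na(voxel_size_mm))
      stop("voxel_size_mm not given and no sidecar metadata found")
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff|bmp)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("no image files found in ", path)
    files <- natural_sort(files)
    slices <- lapply(files, function(f) {
      v <- read_slice_file(f)
      matrix(v, nrow = slice_dims(f)[1])
    })
    d1 <- dim(slices[[1]])
    for (i in seq_along(slices))
      if (!identical(dim(slices[[i]]), d1))
        stop("inconsistent slice shape: ", basename(files[i]))
    vox <- array(0L, c(d1, length(slices)))
    for (i in seq_along(slices)) vox[, , i] <- slices[[i]]
    return(gray_stack(vox, voxel_size_mm))
  }
  # single file: multi-page TIFF or single-slice image
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (max(vapply(pages, max, 0)) > 255) stop("non-8-bit image data: ", path)
    d1 <- dim(pages[[1]])[1:2]
    for (p in pages) if (!identical(dim(p)[1:2], d1)) stop("inconsistent slice shape")
    vox <- array(0L, c(d1, length(pages)))
    for (i in seq_along(pages)) {
      pg <- pages[[i]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      vox[, , i] <- as.integer(pg)
    }
    return(gray_stack(vox, voxel_size_mm))
  }
  v <- read_slice_file(path)
  d <- slice_dims(path)
  gray_stack(array(v, c(d, 1L)), voxel_size_mm)
}

#' Write an image stack
#'
#' Writes one file per slice into a directory (`format` = "png", "tiff" or
#' "bmp"), or a single multi-page TIFF when `path` ends in `.tif`/`.tiff`.
#' A sidecar `metadata.txt` with the voxel size is written alongside
#' directory output.
#'
#' @param stack a [gray_stack()] (or a logical array interpreted as 0/255).
#' @param path output directory or multi-page TIFF filename.
#' @param format slice file format for directory output.
#' @param prefix filename prefix for directory output.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("png", "tiff", "bmp"),
                        prefix = "slice") {
  format <- match.arg(format)
  vox <- stack$voxels
  ns <- dim(vox)[3]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(ns), function(k) vox[, , k] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(ns)) {
    f <- file.path(path, sprintf("%s_%04d.%s", prefix, k,
                                 switch(format, png = "png", tiff = "tif", bmp = "bmp")))
    m <- vox[, , k]
    if (format == "png") png::writePNG(m / 255, f)
    else if (format == "tiff") tiff::writeTIFF(m / 255, f, bits.per.sample = 8)
    else write_bmp8(m, f)
  }
  writeLines(c(sprintf("voxel_size_mm: %.9g", stack$voxel_size),
               "axis: slices caudal->cranial"),
             file.path(path, "metadata.txt"))
  invisible(path)
}

#' Read a key-value sidecar metadata file
#'
#' @param path text file of `key: value` lines.
#' @return named character vector.
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  setNames(vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")), ""),
           vapply(kv, function(p) trimws(p[1]), ""))
}

# ---- minimal 8-bit uncompressed BMP support -------------------------------
# (BITMAPFILEHEADER + BITMAPINFOHEADER + 256-entry grayscale palette;
#  rows bottom-up, padded to 4 bytes)

read_bmp8 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") stop("not a BMP file: ", path)
  le <- function(idx) sum(as.integer(raw[idx]) * 256^(seq_along(idx) - 1))
  offset <- le(11:14)
  width <- le(19:22)
  height_raw <- le(23:26)
  topdown <- height_raw > 2^31
  height <- if (topdown) 2^32 - height_raw else height_raw
  bits <- le(29:30)
  compression <- le(31:34)
  if (bits != 8) stop("non-8-bit image data: ", path)
  if (compression != 0) stop("compressed BMP not supported: ", path)
  pal_n <- le(47:50)
  if (pal_n == 0) pal_n <- 256
  pal <- matrix(as.integer(raw[54 + seq_len(4 * pal_n)]), nrow = 4)
  if (any(pal[1, ] != pal[2, ]) || any(pal[2, ] != pal[3, ]))
    stop("non-grayscale BMP palette: ", path)
  gray_of <- pal[1, ] # B == G == R
  rowbytes <- 4 * ceiling(width / 4)
  px <- as.integer(raw[offset + seq_len(rowbytes * height)])
  px <- matrix(px, nrow = rowbytes)[seq_len(width), , drop = FALSE]
  img <- matrix(gray_of[px + 1L], nrow = width) # cols of px are rows of image
  img <- t(img)
  if (!topdown) img <- img[rev(seq_len(height)), , drop = FALSE]
  storage.mode(img) <- "integer"
  img
}

write_bmp8 <- function(m, path) {
  m <- round(m)
  stopifnot(min(m) >= 0, max(m) <= 255)
  h <- nrow(m)
  w <- ncol(m)
  rowbytes <- 4 * ceiling(w / 4)
  data_size <- rowbytes * h
  off <- 14 + 40 + 1024
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(off + data_size); u16(0); u16(0); u32(off)
  u32(40); u32(w); u32(h); u16(1); u16(8); u32(0); u32(data_size)
  u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0, 256)))
  writeBin(pal, con)
  body <- matrix(as.raw(0), nrow = rowbytes, ncol = h)
  body[seq_len(w), ] <- as.raw(t(m[rev(seq_len(h)), , drop = FALSE]))
  writeBin(as.vector(body), con)
  invisible(path)
}
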