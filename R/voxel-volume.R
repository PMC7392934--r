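#' Voxel volume container
#'
#' A `voxel_volume` holds a 3D scalar grid with isotropic voxel spacing.
#' `values` is a numeric array indexed `(x, y, z)`; world coordinates of the
#' centre of voxel `(i, j, k)` (1-based) are
#' `origin + (c(i, j, k) - 1) * spacing`, in mm.  Grayscale levels follow the
#' dimensionless 0--1000 micro-CT convention (0 = no attenuation, 1000 =
#' maximum attenuation); masks contain only 0/1.
#'
#' @param values numeric 3D array, grayscale level or 0/1 mask.
#' @param spacing isotropic voxel edge length, mm. Must be a single value > 0.
#' @param origin numeric length-3, world position (mm) of the centre of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L))
    stop("all three array extents must be >= 1")
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("`spacing` must be a single positive value (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3-vector (mm)")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %g mm\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  origin (%g, %g, %g) mm; value range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

is_mask <- function(vol) all(vol$values %in% c(0, 1))

#' World coordinates of occupied voxel centres
#'
#' @param vol a `voxel_volume` mask.
#' @return n x 3 matrix of voxel-centre coordinates (mm) where `values != 0`.
#' @keywords internal
voxel_centers <- function(vol) {
  idx <- which(vol$values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, 3L))
  sweep((idx - 1) * vol$spacing, 2L, vol$origin, "+")
}

#' Threshold a grayscale volume into a binary mask
#'
#' Keeps voxels whose grayscale level lies in `[lo, hi]` inclusive, the
#' window-threshold segmentation used to isolate bone from air and from
#' low-density interior tissue (the conventional bone window on the 0--1000
#' scale is 250--1000).
#'
#' @param vol a `voxel_volume` (grayscale).
#' @param lo,hi window bounds, `lo <= hi`.
#' @return A `voxel_volume` mask (0/1) with spacing and origin preserved.
#'   An empty mask triggers a warning, not an error.
#' @export
segment_window <- function(vol, lo = 250, hi = 1000) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (lo > hi) stop("`lo` must be <= `hi`")
  m <- array(as.numeric(vol$values >= lo & vol$values <= hi),
             dim = dim(vol$values))
  if (sum(m) == 0)
    warning("segmentation window [", lo, ", ", hi, "] selected no voxels")
  voxel_volume(m, vol$spacing, vol$origin)
}

#' Read a 3D volume from a multi-page TIFF stack or an NRRD file
#'
#' TIFF pages are z-slices; each page is read as a float matrix indexed
#' `(x, y)` and levels are recovered as `page * scale_max` (the writer stores
#' `level / scale_max`, since TIFF float samples live in \[0, 1\]).  NRRD
#' files must be 3D, raw-encoded, with attached data; spacing is taken from
#' the `spacings` or diagonal `space directions` field.
#'
#' @param path file path, extension `.tif`/`.tiff` or `.nrrd`.
#' @param spacing_mm isotropic spacing override, mm.  Required for TIFF (the
#'   format carries none) and for NRRD files lacking a spacing field.
#' @param scale_max grayscale full-scale used for the TIFF float encoding.
#' @return A `voxel_volume`.
#' @export
load_volume <- function(path, spacing_mm = NULL, scale_max = 1000) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing_mm))
      stop("TIFF carries no voxel spacing; supply `spacing_mm`")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    vals <- array(0, dim = c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) vals[, , k] <- pages[[k]] * scale_max
    voxel_volume(vals, spacing_mm)
  } else if (ext == "nrrd") {
    read_nrrd(path, spacing_mm)
  } else stop("unsupported volume format: .", ext)
}

#' Write a volume to TIFF or NRRD
#'
#' @param vol a `voxel_volume`.
#' @param path output path; format chosen by extension.
#' @param scale_max grayscale full-scale for the TIFF float encoding.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path, scale_max = 1000) {
  stopifnot(inherits(vol, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (min(vol$values) < 0 || max(vol$values) > scale_max)
      stop("values outside [0, scale_max]; cannot encode as TIFF float")
    pages <- lapply(seq_len(dim(vol$values)[3]),
                    function(k) vol$values[, , k] / scale_max)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "nrrd") {
    write_nrrd(vol, path)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

# Minimal NRRD0004 subset: 3D, raw encoding, attached data, little-endian
# doubles.  Spacing read from "spacings" or a diagonal "space directions".
read_nrrd <- function(path, spacing_mm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    hdr[[key]] <- trimws(sub("^[^:]+:=?", "", line))
  }
  if (is.null(hdr$dimension) || as.integer(hdr$dimension) != 3L)
    stop("only 3D NRRD volumes are supported")
  sizes <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  spac <- NULL
  if (!is.null(hdr$spacings)) {
    spac <- as.numeric(strsplit(hdr$spacings, "\\s+")[[1]])
  } else if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]),
      numeric(3)))
    off <- m; diag(off) <- 0
    if (any(abs(off) > 1e-12)) stop("non-axis-aligned space directions")
    spac <- diag(m)
  }
  if (is.null(spac)) {
    if (is.null(spacing_mm))
      stop("NRRD header carries no spacing; supply `spacing_mm`")
    spac <- rep(spacing_mm, 3)
  }
  if (max(spac) - min(spac) > 1e-9 * max(spac))
    stop("anisotropic voxel spacing (", paste(signif(spac, 6), collapse = ", "),
         "); only isotropic volumes are supported")
  if (!is.null(spacing_mm)) spac <- rep(spacing_mm, 3)
  enc <- tolower(hdr$encoding %||% "raw")
  if (enc != "raw") stop("only raw NRRD encoding is supported")
  type <- tolower(hdr$type %||% "double")
  n <- prod(sizes)
  vals <- switch(type,
    "double" = , "float64" = readBin(con, "double", n, size = 8L,
                                     endian = "little"),
    "float"  = , "float32" = readBin(con, "double", n, size = 4L,
                                     endian = "little"),
    "uchar"  = , "uint8"   = as.numeric(readBin(con, "integer", n, size = 1L,
                                                signed = FALSE)),
    "short"  = , "int16"   = as.numeric(readBin(con, "integer", n, size = 2L,
                                                endian = "little")),
    "int"    = , "int32"   = as.numeric(readBin(con, "integer", n, size = 4L,
                                                endian = "little")),
    stop("unsupported NRRD type: ", type))
  if (length(vals) != n) stop("truncated NRRD data block")
  origin <- c(0, 0, 0)
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       hdr[["space origin"]]), ",")[[1]])
  voxel_volume(array(vals, dim = sizes), spac[1], origin)
}

write_nrrd <- function(vol, path) {
  d <- dim(vol$values)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.17g %.17g %.17g",
                   vol$spacing, vol$spacing, vol$spacing),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           "encoding: raw",
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol$values), con, size = 8L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
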