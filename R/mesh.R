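#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices with
#'   consistent outward orientation.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas, normals and centroids
#' @keywords internal
face_geometry <- function(mesh) {
  fc <- face_corners(mesh)
  n2 <- cross3(fc$b - fc$a, fc$c - fc$a)   # 2A * unit normal
  nrm <- sqrt(rowSums(n2^2))
  list(area = nrm / 2,
       normal = n2 / ifelse(nrm > 0, nrm, 1),
       centroid = (fc$a + fc$b + fc$c) / 3)
}

#' Total surface area of a mesh, mm^2
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) sum(face_geometry(mesh)$area)

#' Enclosed volume of a closed, outward-oriented mesh, mm^3
#'
#' Divergence-theorem signed volume; a negative result indicates inward
#' orientation and raises an error.
#' @param mesh a closed `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  v <- sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
  if (v < 0)
    stop("negative enclosed volume: mesh orientation is inward-facing")
  v
}

#' Weld coincident vertices and drop degenerate faces
#'
#' @param mesh a `surface_mesh`.
#' @param tol coordinates within `tol` (mm) are merged.
#' @return A cleaned `surface_mesh`.
#' @export
weld_vertices <- function(mesh, tol = 1e-7) {
  key <- apply(round(mesh$vertices / tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])   # new 1-based index of each old vertex
  verts <- mesh$vertices[first, , drop = FALSE]
  faces <- matrix(map[mesh$faces], ncol = 3L)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  m <- surface_mesh(verts, faces[!degen, , drop = FALSE])
  fg <- face_geometry(m)
  surface_mesh(m$vertices, m$faces[fg$area > 0, , drop = FALSE])
}

#' Read an STL file (ASCII or binary)
#'
#' Duplicate vertices are welded and zero-area faces dropped on load.
#'
#' @param path STL file path.
#' @return A `surface_mesh`.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("empty STL file: ", path)
  head <- readBin(path, "raw", n = min(sz, 512L))
  is_ascii <- grepl("^\\s*solid", rawToChar(head[seq_len(min(80, sz))])) &&
    !any(head == as.raw(0))
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("STL file contains no facets: ", path)
  verts <- tri
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  weld_vertices(surface_mesh(verts, faces))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("truncated ASCII STL: ", path)
  nums <- vapply(strsplit(trimws(vl), "\\s+"),
                 function(x) as.numeric(x[2:4]), numeric(3))
  t(nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + n * 50
  if (file.info(path)$size < expected) stop("truncated binary STL: ", path)
  tri <- matrix(0, nrow = 3L * n, ncol = 3L)
  for (i in seq_len(n)) {
    rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
  }
  tri
}

#' Write a mesh as STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  fc <- face_corners(mesh)
  fg <- face_geometry(mesh)
  n <- nrow(mesh$faces)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid ossimetrics", con)
    for (i in seq_len(n)) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         fg$normal[i, 1], fg$normal[i, 2], fg$normal[i, 3]), con)
      writeLines("    outer loop", con)
      for (v in list(fc$a[i, ], fc$b[i, ], fc$c[i, ]))
        writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid ossimetrics", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    for (i in seq_len(n)) {
      writeBin(as.numeric(c(fg$normal[i, ], fc$a[i, ], fc$b[i, ], fc$c[i, ])),
               con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  }
  invisible(path)
}
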