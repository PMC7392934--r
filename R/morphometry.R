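#' Euclidean distance between two 3D points, mm
#' @param p,q 3-vectors, mm.
#' @export
point_distance <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

#' Characteristic lengths of an ossicle from its landmarks
#'
#' Computes the per-ossicle named lengths and their conventional ratios:
#'
#' * malleus: `L_mal` (head tip to umbo tip), `L_manu` (lateral process tip
#'   to umbo tip), and with a COM, `L_head`, `L_umbo`; ratios
#'   `L_manu/L_mal`, `L_head/L_umbo`.
#' * incus: with a COM, `L_SP` (COM to short-process tip), `L_LP`
#'   (COM to articular-surface centroid, supplied as landmark
#'   `isj_centroid`); ratio `L_SP/L_LP`.
#'
#' @param lms a `landmark_set`.
#' @param ossicle `"malleus"` or `"incus"`.
#' @param com optional 3-vector COM (mm) for COM-anchored lengths.
#' @return Named numeric vector of lengths (mm) and dimensionless ratios.
#' @export
characteristic_lengths <- function(lms, ossicle = c("malleus", "incus"),
                                   com = NULL) {
  ossicle <- match.arg(ossicle)
  out <- c()
  if (ossicle == "malleus") {
    head_tip <- get_landmark(lms, "head_tip")
    umbo <- get_landmark(lms, "umbo_tip")
    lat <- get_landmark(lms, "lateral_process_tip")
    out <- c(L_mal = point_distance(head_tip, umbo),
             L_manu = point_distance(lat, umbo))
    out <- c(out, L_manu_over_L_mal = unname(out["L_manu"] / out["L_mal"]))
    if (!is.null(com)) {
      out <- c(out,
               L_head = point_distance(com, head_tip),
               L_umbo = point_distance(com, umbo))
      out <- c(out, L_head_over_L_umbo = unname(out["L_head"] / out["L_umbo"]))
    }
  } else {
    if (is.null(com)) stop("incus lengths are COM-anchored; supply `com`")
    sp <- get_landmark(lms, "short_process_tip")
    isj <- get_landmark(lms, "isj_centroid")
    out <- c(L_SP = point_distance(com, sp),
             L_LP = point_distance(com, isj))
    out <- c(out, L_SP_over_L_LP = unname(out["L_SP"] / out["L_LP"]))
  }
  out
}

#' Area and centroid of a surface patch
#'
#' @param patch a `surface_mesh` (the patch's faces).
#' @return A list of class `surface_patch`: `mesh`, `area` (mm²),
#'   `centroid` (area-weighted mean of face centroids, mm).
#' @export
patch_area_centroid <- function(patch) {
  stopifnot(inherits(patch, "surface_mesh"))
  fg <- face_geometry(patch)
  A <- sum(fg$area)
  if (A <= 0) stop("patch has zero total area")
  structure(list(mesh = patch, area = A,
                 centroid = colSums(fg$centroid * fg$area) / A),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch> %d faces, area %.4g mm^2, centroid (%.4g, %.4g, %.4g)\n",
              nrow(x$mesh$faces), x$area,
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

as_patch <- function(x) {
  if (inherits(x, "surface_patch")) x else patch_area_centroid(x)
}

# Exact area-weighted second moment of the surface about its centroid:
# for each triangle, integral of (p-c)(p-c)' dA = (A/12)(sum v_i v_i' +
# 9 g g') with vertices v_i and face centroid g taken relative to c.
surface_second_moment <- function(patch) {
  p <- as_patch(patch)
  fc <- face_corners(p$mesh)
  fg <- face_geometry(p$mesh)
  c0 <- p$centroid
  M <- matrix(0, 3, 3)
  a <- sweep(fc$a, 2L, c0); b <- sweep(fc$b, 2L, c0); cc <- sweep(fc$c, 2L, c0)
  g <- (a + b + cc) / 3
  for (i in seq_len(nrow(g))) {
    S <- tcrossprod(a[i, ]) + tcrossprod(b[i, ]) + tcrossprod(cc[i, ]) +
      9 * tcrossprod(g[i, ])
    M <- M + fg$area[i] / 12 * S
  }
  M
}

#' Total-least-squares plane fit to a surface patch
#'
#' Minimises area-weighted orthogonal distances: the plane passes through
#' the patch centroid and its normal is the eigenvector of the smallest
#' eigenvalue of the exact area-weighted second-moment matrix of the
#' surface.
#'
#' @param patch a `surface_mesh` or `surface_patch`.
#' @return List `point` (3-vector on the plane) and `normal` (unit
#'   3-vector; sign chosen so the largest-magnitude component is positive).
#' @export
fit_plane <- function(patch) {
  p <- as_patch(patch)
  M <- surface_second_moment(p)
  eig <- eigen(M, symmetric = TRUE)
  if (eig$values[2] < 1e-12 * max(eig$values, 1e-300))
    stop("degenerate (collinear) patch: plane fit is not defined")
  n <- eig$vectors[, 3]             # smallest eigenvalue of symmetric eigen()
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  list(point = p$centroid, normal = n)
}

plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u, v)
}

#' Area of a patch projected onto a plane, counting overlaps once
#'
#' Faces are projected along the plane normal and the area of the covered
#' planar region is measured by rasterising the projected triangles on a
#' regular pixel grid (a fold in the surface would be double-counted by a
#' naive sum of projected triangle areas).  The default pixel edge is 1/200
#' of the shorter projected bounding-box extent.
#'
#' @param patch a `surface_mesh` or `surface_patch`.
#' @param plane plane as returned by [fit_plane()]; default fits one.
#' @param pixel pixel edge, mm; default `min(bbox extents) / 200`.
#' @return Projected area, mm².
#' @export
projected_area <- function(patch, plane = fit_plane(patch), pixel = NULL) {
  p <- as_patch(patch)
  B <- plane_basis(plane$normal)
  uv <- sweep(p$mesh$vertices, 2L, plane$point) %*% B
  tri <- p$mesh$faces
  rng_u <- range(uv[, 1]); rng_v <- range(uv[, 2])
  ext <- c(diff(rng_u), diff(rng_v))
  if (any(ext <= 0)) stop("projected patch is degenerate")
  if (is.null(pixel)) pixel <- min(ext) / 200
  nx <- max(2L, ceiling(ext[1] / pixel)); ny <- max(2L, ceiling(ext[2] / pixel))
  px <- rng_u[1] + (seq_len(nx) - 0.5) * ext[1] / nx
  py <- rng_v[1] + (seq_len(ny) - 0.5) * ext[2] / ny
  covered <- matrix(FALSE, nx, ny)
  sum_proj <- 0   # exact sum of projected triangle areas: union upper bound
  for (i in seq_len(nrow(tri))) {
    a <- uv[tri[i, 1], ]; b <- uv[tri[i, 2], ]; cc <- uv[tri[i, 3], ]
    det <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
    sum_proj <- sum_proj + abs(det) / 2
    if (abs(det) < 1e-300) next
    ix <- which(px >= min(a[1], b[1], cc[1]) & px <= max(a[1], b[1], cc[1]))
    iy <- which(py >= min(a[2], b[2], cc[2]) & py <= max(a[2], b[2], cc[2]))
    if (!length(ix) || !length(iy)) next
    gx <- rep(px[ix], times = length(iy)); gy <- rep(py[iy], each = length(ix))
    l1 <- ((b[1] - a[1]) * (gy - a[2]) - (gx - a[1]) * (b[2] - a[2])) / det
    l0 <- ((gx - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (gy - a[2])) / det
    inside <- l0 >= 0 & l1 >= 0 & (l0 + l1) <= 1
    covered[cbind(rep(ix, times = length(iy)),
                  rep(iy, each = length(ix)))] <-
      covered[cbind(rep(ix, times = length(iy)),
                    rep(iy, each = length(ix)))] | inside
  }
  min(sum(covered) * (ext[1] / nx) * (ext[2] / ny), sum_proj)
}

#' Equivalent circular diameter of an area
#' @param A area, mm².
#' @return `sqrt(4 A / pi)`, mm.
#' @export
equivalent_diameter <- function(A) {
  if (any(A <= 0)) stop("`A` must be > 0")
  sqrt(4 * A / pi)
}

#' Local anatomical frame of the stapes from its footplate
#'
#' Builds the footplate-based stapes frame: the origin is the centroid of
#' the footplate medial surface; z is the fitted-plane normal signed toward
#' the stapes head (lateral); x is the long in-plane axis of the footplate
#' (principal direction of the area-weighted 2D second moments of the
#' projected footplate, anterior--posterior anatomically); y = z × x
#' (superior).  With inputs in the right-ear convention the frame is
#' right-handed.
#'
#' @param footplate footplate medial-surface patch (`surface_mesh` or
#'   `surface_patch`).
#' @param head stapes-head lateral-surface patch, used to sign z and to
#'   measure heights.
#' @param com optional stapes COM (mm) for `h_c` and in-plane COM
#'   coordinates.
#' @return List: `frame` (`anatomical_frame`), and measurements `a`, `b`
#'   (footplate long/short lengths, mm), `h` (footplate centroid to head
#'   centroid, mm), `A_FT`, `A_FTproj` (mm²), `d_FT_eq`, `d_FTproj_eq`
#'   (mm), and if `com` given: `h_c` (footplate centroid to COM distance),
#'   `x_c`, `y_c` (in-plane COM coordinates), `h_c_over_h`.
#' @export
stapes_frame <- function(footplate, head, com = NULL) {
  fp <- as_patch(footplate)
  hd <- as_patch(head)
  pl <- fit_plane(fp)
  z <- pl$normal
  toward_head <- hd$centroid - fp$centroid
  comp <- sum(toward_head * z)
  if (abs(comp) < 1e-9)
    stop("stapes head centroid lies in the footplate plane; cannot sign the z-axis")
  if (comp < 0) z <- -z
  # long in-plane axis from area-weighted 2D second moments of the outline
  M <- surface_second_moment(fp)
  B <- plane_basis(z)
  M2 <- t(B) %*% M %*% B
  e2 <- eigen(M2, symmetric = TRUE)
  x <- B %*% e2$vectors[, 1]        # largest in-plane spread = long axis
  x <- as.numeric(x - sum(x * z) * z)
  x <- x / sqrt(sum(x^2))
  k <- which.max(abs(x)); if (x[k] < 0) x <- -x
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  frame <- anatomical_frame(fp$centroid, cbind(x, y, z))
  local <- to_frame_coords(fp$mesh$vertices, frame)
  a <- diff(range(local[, 1])); b <- diff(range(local[, 2]))
  A_FT <- fp$area
  A_proj <- projected_area(fp, pl)
  out <- list(frame = frame, a = a, b = b, a_over_b = a / b,
              h = point_distance(fp$centroid, hd$centroid),
              A_FT = A_FT, A_FTproj = A_proj,
              d_FT_eq = equivalent_diameter(A_FT),
              d_FTproj_eq = equivalent_diameter(A_proj))
  if (!is.null(com)) {
    cl <- to_frame_coords(com, frame)
    out$h_c <- point_distance(fp$centroid, com)
    out$x_c <- cl[1]; out$y_c <- cl[2]
    out$h_c_over_h <- out$h_c / out$h
  }
  out
}

#' Hinge-like rotational axis of the malleus--incus complex
#'
#' The line through the malleus anterior process and the tip of the incus
#' short process, where the complex is tethered to the skull.  The
#' direction sign is normalised (largest-magnitude component positive) so
#' swapping the inputs returns the same line.
#'
#' @param anterior_process malleus anterior-process point, mm.
#' @param short_process_tip incus short-process tip, mm.
#' @return An `axis3d`.
#' @export
hinge_axis <- function(anterior_process, short_process_tip) {
  d <- as.numeric(short_process_tip) - as.numeric(anterior_process)
  if (sqrt(sum(d^2)) < 1e-12) stop("hinge landmarks coincide")
  k <- which.max(abs(d)); if (d[k] < 0) d <- -d
  axis3d(anterior_process, d)
}

#' Ossicular lever arms about the hinge axis
#'
#' `L1` and `L2` are the perpendicular 3D distances from the rotational
#' axis to the umbo tip and to the centroid of the incudostapedial articular
#' surface; their ratio is the anatomical lever ratio of the malleus--incus
#' complex.  `d_axis_com` is the distance from the axis to the complex COM.
#'
#' @param axis hinge `axis3d`.
#' @param umbo_tip,isj_centroid 3-vectors, mm.
#' @param com optional malleus--incus complex COM, mm.
#' @return List of class `lever_geometry`: `axis`, `L1`, `L2`, `ratio`,
#'   `d_axis_com` (NA if `com` not given).
#' @export
lever_geometry <- function(axis, umbo_tip, isj_centroid, com = NULL) {
  stopifnot(inherits(axis, "axis3d"))
  L1 <- point_axis_distance(umbo_tip, axis)
  L2 <- point_axis_distance(isj_centroid, axis)
  if (L2 <= 0) stop("ISJ centroid lies on the hinge axis: lever ratio undefined")
  if (L1 <= 0) stop("umbo tip lies on the hinge axis: lever ratio undefined")
  structure(list(axis = axis, L1 = L1, L2 = L2, ratio = L1 / L2,
                 d_axis_com = if (is.null(com)) NA_real_
                              else point_axis_distance(com, axis)),
            class = "lever_geometry")
}

#' @export
print.lever_geometry <- function(x, ...) {
  cat(sprintf("<lever_geometry> L1 %.4g mm, L2 %.4g mm, lever ratio %.4g\n",
              x$L1, x$L2, x$ratio))
  if (is.finite(x$d_axis_com))
    cat(sprintf("  axis-to-COM distance %.4g mm\n", x$d_axis_com))
  invisible(x)
}

#' Global intrinsic frame of the ossicular chain
#'
#' Axes are copied from the stapes local frame; the origin moves to the COM
#' of the entire ossicular chain, so per-ossicle COMs can be reported in
#' chain-intrinsic coordinates.
#'
#' @param chain `mass_properties` of the combined chain (see
#'   [combine_bodies()]).
#' @param stapes_frame the stapes `anatomical_frame`.
#' @param parts optional named list of per-ossicle `mass_properties`; their
#'   COMs are re-expressed in the global frame.
#' @return List: `frame` (`anatomical_frame` at the chain COM) and
#'   `part_coms` (named matrix of re-expressed COMs, if `parts` given).
#' @export
global_frame <- function(chain, stapes_frame, parts = NULL) {
  stopifnot(inherits(chain, "mass_properties"),
            inherits(stapes_frame, "anatomical_frame"))
  frame <- anatomical_frame(chain$com, stapes_frame$axes)
  out <- list(frame = frame)
  if (!is.null(parts)) {
    coms <- t(vapply(parts, `[[`, numeric(3), "com"))
    local <- to_frame_coords(coms, frame)
    local <- matrix(local, ncol = 3L,
                    dimnames = list(names(parts), c("x", "y", "z")))
    out$part_coms <- local
  }
  out
}
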