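#' A 3D axis: point plus unit direction
#'
#' @param point 3-vector, mm, a point on the axis.
#' @param direction 3-vector; normalised on construction.
#' @return An object of class `axis3d`.
#' @export
axis3d <- function(point, direction) {
  point <- as.numeric(point); direction <- as.numeric(direction)
  stopifnot(length(point) == 3L, length(direction) == 3L)
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) stop("axis direction must be non-zero")
  structure(list(point = point, direction = direction / n), class = "axis3d")
}

#' @export
print.axis3d <- function(x, ...) {
  cat(sprintf("<axis3d> through (%.4g, %.4g, %.4g) along (%.4g, %.4g, %.4g)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Perpendicular distance from a point to an axis, mm
#'
#' @param p 3-vector or n x 3 matrix of points.
#' @param axis an `axis3d`.
#' @export
point_axis_distance <- function(p, axis) {
  stopifnot(inherits(axis, "axis3d"))
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
  rel <- sweep(p, 2L, axis$point)
  along <- rel %*% axis$direction
  perp <- rel - along %*% t(axis$direction)
  d <- sqrt(rowSums(perp^2))
  if (length(d) == 1L) as.numeric(d) else d
}

#' Orthonormal anatomical frame
#'
#' Axes are the columns of a 3 x 3 matrix `axes = [x | y | z]`; handedness is
#' the sign of its determinant.  All ossicle frames in this package are
#' right-handed after left ears are mirrored at load time.
#'
#' @param origin 3-vector, mm.
#' @param axes 3 x 3 matrix with orthonormal columns.
#' @return An object of class `anatomical_frame` with a `handedness` field
#'   (`"right"` or `"left"`).
#' @export
anatomical_frame <- function(origin, axes) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal")
  structure(list(origin = origin, axes = axes,
                 handedness = if (det(axes) > 0) "right" else "left"),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> origin (%.4g, %.4g, %.4g) mm, %s-handed\n",
              x$origin[1], x$origin[2], x$origin[3], x$handedness))
  print(round(x$axes, 6))
  invisible(x)
}

#' Express world points in a frame's coordinates
#'
#' @param p 3-vector or n x 3 matrix of world points.
#' @param frame an `anatomical_frame`.
#' @export
to_frame_coords <- function(p, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
  out <- sweep(p, 2L, frame$origin) %*% frame$axes
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' Rotation matrix about a unit axis (Rodrigues)
#' @param u unit 3-vector.
#' @param theta angle, radians.
#' @keywords internal
rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

#' Apply a rigid transform to points
#' @param p n x 3 matrix or 3-vector.
#' @param R 3 x 3 rotation.
#' @param t translation 3-vector.
#' @keywords internal
rigid_transform <- function(p, R, t = c(0, 0, 0)) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
  out <- sweep(p %*% t(R), 2L, t, "+")
  if (nrow(out) == 1L) as.numeric(out) else out
}
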