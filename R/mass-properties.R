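#' Rigid-body mass properties of a voxel mask
#'
#' Treats every occupied voxel as a point mass at its centre (the standard
#' discretisation for micro-CT inertia work) and computes volume, mass,
#' centre of mass, the inertia tensor about the COM, and its principal
#' decomposition.  Units are fixed throughout the package: mm, mg, mg·mm²,
#' densities in mg/mm³.
#'
#' The principal axes are the eigenvectors of the COM inertia tensor with
#' moments sorted ascending (I_MIN <= I_MED <= I_MAX).  Signs follow a
#' deterministic convention: each axis is flipped so its largest-magnitude
#' component is positive (ties broken by the first nonzero component) and
#' the third axis is flipped if needed to force det = +1, so the axes always
#' form a right-handed rotation.
#'
#' @param mask a `voxel_volume` 0/1 mask (any nonzero voxel counts).
#' @param density uniform density assigned to occupied voxels, mg/mm³.
#' @param cube_correction add the solid-cube self-inertia of each voxel
#'   (`+ m_vox * s^2 / 6` on the tensor diagonal) instead of pure point
#'   masses.  Default FALSE: the point-mass convention.
#' @return An object of class `mass_properties` with fields `volume` (mm³),
#'   `mass` (mg), `density` (mg/mm³), `com` (mm), `inertia_com`
#'   (3 x 3, mg·mm²), `principal_moments` (ascending), `principal_axes`
#'   (columns), `n_voxels`, `spacing`.
#' @export
mass_properties_from_mask <- function(mask, density, cube_correction = FALSE) {
  stopifnot(inherits(mask, "voxel_volume"))
  if (!is.finite(density) || density <= 0) stop("`density` must be > 0")
  pts <- voxel_centers(mask)
  n <- nrow(pts)
  if (n == 0L) stop("mask is empty: no occupied voxels")
  s <- mask$spacing
  volume <- n * s^3
  mass <- density * volume
  m_vox <- density * s^3
  com <- colMeans(pts)
  I <- inertia_tensor_points(pts, m_vox, com)
  if (cube_correction) I <- I + diag(3) * (n * m_vox * s^2 / 6)
  mass_properties(volume = volume, mass = mass, density = density,
                  com = com, inertia_com = I,
                  n_voxels = n, spacing = s)
}

# Sum of point-mass second moments about `about`.
inertia_tensor_points <- function(pts, m_vox, about) {
  r <- sweep(pts, 2L, about)
  r2 <- rowSums(r^2)
  xx <- sum(r2 - r[, 1]^2); yy <- sum(r2 - r[, 2]^2); zz <- sum(r2 - r[, 3]^2)
  xy <- -sum(r[, 1] * r[, 2]); xz <- -sum(r[, 1] * r[, 3])
  yz <- -sum(r[, 2] * r[, 3])
  m_vox * matrix(c(xx, xy, xz, xy, yy, yz, xz, yz, zz), 3L, 3L)
}

#' Construct mass properties from explicit fields
#'
#' Used by the voxel route, by analytic phantom ground truths, and by
#' [combine_bodies()].  The principal decomposition is (re)computed from
#' `inertia_com` unless both parts are supplied.
#'
#' @param volume mm³.
#' @param mass mg.
#' @param density mg/mm³ (defaults to `mass / volume`).
#' @param com 3-vector, mm.
#' @param inertia_com symmetric 3 x 3 tensor about the COM, mg·mm².
#' @param ... further fields stored on the object (e.g. `n_voxels`).
#' @export
mass_properties <- function(volume, mass, density = mass / volume,
                            com = c(0, 0, 0), inertia_com, ...) {
  inertia_com <- (inertia_com + t(inertia_com)) / 2
  eig <- eigen(inertia_com, symmetric = TRUE)
  ord <- order(eig$values)           # ascending: I_MIN, I_MED, I_MAX
  moments <- eig$values[ord]
  axes <- canonical_axes(eig$vectors[, ord, drop = FALSE])
  structure(list(volume = volume, mass = mass, density = density,
                 com = as.numeric(com), inertia_com = inertia_com,
                 principal_moments = moments, principal_axes = axes, ...),
            class = "mass_properties")
}

# Deterministic eigenvector signs: largest-|component| positive, ties broken
# by first nonzero; then det forced to +1 by flipping the last axis.
canonical_axes <- function(V) {
  for (j in 1:3) {
    v <- V[, j]
    k <- which(abs(v) == max(abs(v)))[1]
    if (v[k] < 0) V[, j] <- -v
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' @export
print.mass_properties <- function(x, ...) {
  cat("<mass_properties>\n")
  cat(sprintf("  volume  %.4g mm^3   mass %.4g mg   density %.4g mg/mm^3\n",
              x$volume, x$mass, x$density))
  cat(sprintf("  COM     (%.4g, %.4g, %.4g) mm\n",
              x$com[1], x$com[2], x$com[3]))
  cat(sprintf("  principal moments (mg mm^2): I_MIN %.4g  I_MED %.4g  I_MAX %.4g\n",
              x$principal_moments[1], x$principal_moments[2],
              x$principal_moments[3]))
  invisible(x)
}

#' @export
summary.mass_properties <- function(object, ...) {
  pm <- object$principal_moments
  out <- c(V = object$volume, m = object$mass, rho = object$density,
           I_MIN = pm[1], I_MED = pm[2], I_MAX = pm[3],
           I_MIN_over_I_MAX = pm[1] / pm[3],
           I_MED_over_I_MAX = pm[2] / pm[3])
  class(out) <- c("summary.mass_properties", class(out))
  out
}

#' @export
print.summary.mass_properties <- function(x, ...) {
  print(unclass(signif(x, 4)))
  invisible(x)
}

#' Moment of inertia about an arbitrary axis
#'
#' Transforms the COM inertia tensor to the requested axis:
#' `I = n' I_com n + m d^2`, where `n` is the axis direction and `d` the
#' perpendicular distance from the COM to the axis (the parallel-axis
#' theorem).  For an axis through the COM along a principal direction this
#' returns the corresponding principal moment exactly.
#'
#' @param mp a `mass_properties`.
#' @param axis an `axis3d`.
#' @return Moment of inertia, mg·mm².
#' @export
moment_about_axis <- function(mp, axis) {
  stopifnot(inherits(mp, "mass_properties"), inherits(axis, "axis3d"))
  n <- axis$direction
  d <- point_axis_distance(mp$com, axis)
  as.numeric(t(n) %*% mp$inertia_com %*% n) + mp$mass * d^2
}

#' Moments of inertia about the three axes of an anatomical frame
#'
#' Evaluates [moment_about_axis()] for each frame axis through a common
#' point (default: the body's own COM; for the ossicular chain the global
#' intrinsic frame puts this point at the chain COM).
#'
#' @param mp a `mass_properties`.
#' @param frame an `anatomical_frame`.
#' @param through 3-vector the axes pass through; default `mp$com`.
#' @return Named vector `c(I_x, I_y, I_z)` mg·mm² — anterior--posterior,
#'   superior--inferior, lateral--medial for the anatomical convention.
#' @export
moments_in_frame <- function(mp, frame, through = mp$com) {
  stopifnot(inherits(mp, "mass_properties"), inherits(frame, "anatomical_frame"))
  out <- vapply(1:3, function(j)
    moment_about_axis(mp, axis3d(through, frame$axes[, j])), numeric(1))
  names(out) <- c("I_x", "I_y", "I_z")
  out
}

#' Density of the bony (high-density) phase given a low-density fraction
#'
#' When a fraction `v_L` of the segmented volume is low-density tissue
#' (marrow, vessels, fluid) of density `rho_L`, the density of the remaining
#' bony phase consistent with the measured total mass `m` and volume `V` is
#' `rho_H = (m - v_L * rho_L * V) / ((1 - v_L) * V)`.
#'
#' @param m measured mass, mg.
#' @param V total segmented volume, mm³.
#' @param v_L volume fraction of low-density parts, in `[0, 1)`.
#' @param rho_L density assigned to the low-density parts, mg/mm³
#'   (1 = water).
#' @return `rho_H`, mg/mm³.
#' @export
density_correction <- function(m, V, v_L, rho_L) {
  if (!is.finite(v_L) || v_L < 0 || v_L >= 1) stop("`v_L` must be in [0, 1)")
  if (m <= 0 || V <= 0) stop("`m` and `V` must be > 0")
  num <- m - v_L * rho_L * V
  if (num <= 0) stop("v_L * rho_L * V exceeds the measured mass")
  num / ((1 - v_L) * V)
}

#' Relative sensitivity of the bony-phase density to the low-density phase
#'
#' How much larger the bony-phase density is when the low-density parts are
#' assigned zero mass rather than density `rho_L`, relative to the zero-mass
#' estimate: `(rho_H(0) - rho_H(rho_L)) / rho_H(0) = v_L * rho_L * V / m`.
#'
#' @inheritParams density_correction
#' @return Dimensionless relative factor.
#' @export
density_correction_factor <- function(m, V, v_L, rho_L = 1) {
  rho0 <- density_correction(m, V, v_L, 0)
  rhoL <- density_correction(m, V, v_L, rho_L)
  (rho0 - rhoL) / rho0
}

#' Combine rigid bodies into one composite
#'
#' Standard rigid-body addition in a common world frame: masses and volumes
#' add, the composite COM is the mass-weighted mean, and each part's COM
#' inertia tensor is transported to the joint COM by the tensor parallel-axis
#' rule before summation.  The principal decomposition is recomputed.
#'
#' @param parts list of `mass_properties` in one world frame.
#' @return A `mass_properties` for the composite body.
#' @export
combine_bodies <- function(parts) {
  if (length(parts) == 0L) stop("`parts` must contain at least one body")
  stopifnot(all(vapply(parts, inherits, TRUE, "mass_properties")))
  if (length(parts) == 1L) return(parts[[1]])
  masses <- vapply(parts, `[[`, numeric(1), "mass")
  volume <- sum(vapply(parts, `[[`, numeric(1), "volume"))
  mass <- sum(masses)
  coms <- t(vapply(parts, `[[`, numeric(3), "com"))
  com <- colSums(coms * masses) / mass
  I <- matrix(0, 3, 3)
  for (i in seq_along(parts)) {
    d <- parts[[i]]$com - com
    I <- I + parts[[i]]$inertia_com +
      masses[i] * (sum(d^2) * diag(3) - tcrossprod(d))
  }
  mass_properties(volume = volume, mass = mass, com = com, inertia_com = I)
}
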