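# Synthetic ossicle-like phantoms with closed-form mass properties.
#
# A phantom is a list of solid primitives (sphere / ellipsoid / cylinder /
# box), each tagged as "bone" or "low" (low-density inclusion).  Analytic
# volume, COM and inertia come from the standard closed forms plus the
# tensor parallel-axis rule; low-density inclusions must lie inside bone and
# are composed with negative mass, so the analytic record describes exactly
# the bone phase the segmentation window selects.

#' Solid primitive constructors for phantoms
#'
#' @param center 3-vector, mm.
#' @param r,semi,radius,length,half size parameters, mm.
#' @param R 3 x 3 rotation giving the local axes (columns).
#' @param phase `"bone"` or `"low"` (low-density inclusion).
#' @return A `phantom_primitive`.
#' @name phantom-primitives
NULL

new_primitive <- function(type, center, R, phase, ...) {
  stopifnot(phase %in% c("bone", "low"))
  structure(list(type = type, center = as.numeric(center), R = R,
                 phase = phase, ...),
            class = "phantom_primitive")
}

#' @rdname phantom-primitives
#' @export
prim_sphere <- function(center, r, phase = "bone")
  new_primitive("sphere", center, diag(3), phase, r = r)

#' @rdname phantom-primitives
#' @export
prim_ellipsoid <- function(center, semi, R = diag(3), phase = "bone")
  new_primitive("ellipsoid", center, R, phase, semi = as.numeric(semi))

#' @rdname phantom-primitives
#' @export
prim_cylinder <- function(center, radius, length, R = diag(3), phase = "bone")
  new_primitive("cylinder", center, R, phase, radius = radius, length = length)

#' @rdname phantom-primitives
#' @export
prim_box <- function(center, half, R = diag(3), phase = "bone")
  new_primitive("box", center, R, phase, half = as.numeric(half))

prim_volume <- function(p) switch(p$type,
  sphere = 4 / 3 * pi * p$r^3,
  ellipsoid = 4 / 3 * pi * prod(p$semi),
  cylinder = pi * p$radius^2 * p$length,
  box = 8 * prod(p$half))

# COM inertia tensor in world axes for unit mass.
prim_unit_inertia <- function(p) {
  I_local <- switch(p$type,
    sphere = diag(3) * (2 / 5 * p$r^2),
    ellipsoid = diag(c(p$semi[2]^2 + p$semi[3]^2,
                       p$semi[1]^2 + p$semi[3]^2,
                       p$semi[1]^2 + p$semi[2]^2) / 5),
    cylinder = diag(c((3 * p$radius^2 + p$length^2) / 12,
                      (3 * p$radius^2 + p$length^2) / 12,
                      p$radius^2 / 2)),
    box = diag(c(p$half[2]^2 + p$half[3]^2,
                 p$half[1]^2 + p$half[3]^2,
                 p$half[1]^2 + p$half[2]^2) / 3))
  p$R %*% I_local %*% t(p$R)
}

# Conservative bounding radius around the centre.
prim_bound <- function(p) switch(p$type,
  sphere = p$r,
  ellipsoid = max(p$semi),
  cylinder = sqrt(p$radius^2 + (p$length / 2)^2),
  box = sqrt(sum(p$half^2)))

prim_inside <- function(p, pts) {
  q <- sweep(pts, 2L, p$center) %*% p$R
  switch(p$type,
    sphere = rowSums(q^2) <= p$r^2,
    ellipsoid = rowSums(sweep(q, 2L, p$semi, "/")^2) <= 1,
    cylinder = (q[, 1]^2 + q[, 2]^2 <= p$radius^2) &
      (abs(q[, 3]) <= p$length / 2),
    box = abs(q[, 1]) <= p$half[1] & abs(q[, 2]) <= p$half[2] &
      abs(q[, 3]) <= p$half[3])
}

#' Phantom specification
#'
#' @param primitives list of `phantom_primitive`s.  Bone primitives must not
#'   overlap each other; `"low"` inclusions must lie entirely inside bone
#'   (so the analytic bone-phase record is a signed composition).
#' @param spacing voxel edge, mm.
#' @param levels grayscale levels `c(background, bone, low)` on the 0--1000
#'   scale; defaults 0 / 600 / 100 so the conventional 250--1000 bone window
#'   separates the phases exactly.
#' @param bounds optional 2 x 3 matrix `rbind(lo, hi)` of the grid extent,
#'   mm; primitives outside it are an error.  Default: auto-fit with a
#'   2-voxel margin.
#' @param seed integer recorded in the output metadata.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(primitives, spacing = 0.02,
                         levels = c(background = 0, bone = 600, low = 100),
                         bounds = NULL, seed = NULL) {
  stopifnot(length(primitives) > 0,
            all(vapply(primitives, inherits, TRUE, "phantom_primitive")))
  structure(list(primitives = primitives, spacing = spacing,
                 levels = levels, bounds = bounds, seed = seed),
            class = "phantom_spec")
}

#' Analytic mass properties of a phantom's bone phase
#'
#' Closed-form volume/COM/inertia per primitive, composed with the tensor
#' parallel-axis rule; low-density inclusions enter with negative mass.
#'
#' @param spec a `phantom_spec` (or list of primitives).
#' @param density bone density, mg/mm³.
#' @return A `mass_properties`.
#' @export
analytic_mass_properties <- function(spec, density) {
  prims <- if (inherits(spec, "phantom_spec")) spec$primitives else spec
  sgn <- ifelse(vapply(prims, `[[`, character(1), "phase") == "low", -1, 1)
  vols <- vapply(prims, prim_volume, numeric(1)) * sgn
  masses <- density * vols
  volume <- sum(vols)
  mass <- sum(masses)
  coms <- t(vapply(prims, `[[`, numeric(3), "center"))
  com <- colSums(coms * masses) / mass
  I <- matrix(0, 3, 3)
  for (i in seq_along(prims)) {
    d <- prims[[i]]$center - com
    # prim_unit_inertia is per unit mass; a signed mass subtracts inclusions
    I <- I + masses[i] * prim_unit_inertia(prims[[i]]) +
      masses[i] * (sum(d^2) * diag(3) - tcrossprod(d))
  }
  mass_properties(volume = volume, mass = mass, com = com, inertia_com = I)
}

#' Voxelize a phantom into grayscale volume, mask and ground truth
#'
#' A voxel is occupied iff its centre lies inside an analytic solid
#' (matching the point-mass discretisation, so the voxel-vs-analytic bias is
#' second order).  Low-density inclusions override bone where they overlap.
#'
#' @param spec a `phantom_spec`.
#' @param density bone density used for the analytic truth record, mg/mm³.
#' @return List: `grayscale` (`voxel_volume`), `mask` (bone 0/1
#'   `voxel_volume`), `truth` (analytic `mass_properties` of the bone
#'   phase plus bookkeeping: `v_L_realized`, `n_bone`, `n_low`, `seed`).
#' @export
voxelize <- function(spec, density = 2.2) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$spacing
  ctr <- t(vapply(spec$primitives, `[[`, numeric(3), "center"))
  rad <- vapply(spec$primitives, prim_bound, numeric(1))
  lo <- apply(ctr - rad, 2L, min) - 2 * s
  hi <- apply(ctr + rad, 2L, max) + 2 * s
  if (!is.null(spec$bounds)) {
    if (any(ctr - rad < matrix(spec$bounds[1, ], nrow(ctr), 3, byrow = TRUE)) ||
        any(ctr + rad > matrix(spec$bounds[2, ], nrow(ctr), 3, byrow = TRUE)))
      stop("primitive exceeds the requested phantom bounds")
    lo <- spec$bounds[1, ]; hi <- spec$bounds[2, ]
  }
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / s)))
  origin <- lo + s / 2
  gx <- origin[1] + (seq_len(dims[1]) - 1) * s
  gy <- origin[2] + (seq_len(dims[2]) - 1) * s
  gz <- origin[3] + (seq_len(dims[3]) - 1) * s
  lev <- array(spec$levels[["background"]], dim = dims)
  # slice-wise to bound memory
  xy <- cbind(rep(gx, times = dims[2]), rep(gy, each = dims[1]))
  for (k in seq_len(dims[3])) {
    pts <- cbind(xy, gz[k])
    slab <- rep(0L, nrow(pts))   # 0 bg, 1 bone, 2 low
    for (p in spec$primitives) {
      ins <- prim_inside(p, pts)
      slab[ins & slab == 0L & p$phase == "bone"] <- 1L
      if (p$phase == "low") slab[ins] <- 2L
    }
    lev[, , k] <- matrix(spec$levels[["background"]] +
                           (slab == 1L) * (spec$levels[["bone"]] -
                                             spec$levels[["background"]]) +
                           (slab == 2L) * (spec$levels[["low"]] -
                                             spec$levels[["background"]]),
                         dims[1], dims[2])
  }
  grayscale <- voxel_volume(lev, s, origin)
  mask_arr <- array(as.numeric(lev == spec$levels[["bone"]]), dim = dims)
  mask <- voxel_volume(mask_arr, s, origin)
  n_bone <- sum(mask_arr)
  n_low <- sum(lev == spec$levels[["low"]])
  truth <- analytic_mass_properties(spec, density)
  truth$v_L_realized <- if (n_bone + n_low > 0) n_low / (n_bone + n_low) else 0
  truth$n_bone <- n_bone
  truth$n_low <- n_low
  truth$seed <- spec$seed
  list(grayscale = grayscale, mask = mask, truth = truth)
}

#' Brute-force moment of inertia of a mask about an axis
#'
#' Literal per-voxel sum of `m_vox * d_perp^2` with no tensor algebra —
#' the independent oracle for [moment_about_axis()].  Test use only.
#'
#' @param mask a `voxel_volume` mask.
#' @param density mg/mm³.
#' @param axis an `axis3d`.
#' @return Moment of inertia, mg·mm².
#' @export
brute_force_inertia <- function(mask, density, axis) {
  pts <- voxel_centers(mask)
  if (nrow(pts) == 0L) return(0)
  m_vox <- density * mask$spacing^3
  d <- point_axis_distance(pts, axis)
  m_vox * sum(d^2)
}
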