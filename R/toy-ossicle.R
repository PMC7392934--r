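# Toy ossicle phantoms: compact head + slender handle "malleus", body + two
# process "incus", plate + crura + head "stapes", or the assembled chain.
# Dimensions sit near published sheep/human means (malleus total length
# ~7.9 mm sheep / ~8.2 mm human, footplate 2.03 x 0.93 mm sheep, lever arms
# ~4.16/1.69 mm sheep); every fixture carries closed-form ground truth.

rot_z_to <- function(d) {
  d <- d / sqrt(sum(d^2))
  seed <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- seed - sum(seed * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  cbind(u, v, d)   # local z maps to d
}

toy_scales <- function(scale) {
  switch(scale,
    sheep = list(L_mal = 7.88, L_manu = 5.26, r_head = 1.00, r_handle = 0.30,
                 r_body = 0.95, r_sp = 0.25, r_lp = 0.22,
                 L1 = 4.16, L2 = 1.69,
                 fp_a = 1.015, fp_b = 0.465, fp_t = 0.22, h = 2.10,
                 r_shead = 0.28, r_crus = 0.12, crus_off = 0.45,
                 isj_a = 0.42, isj_b = 0.32),
    human = list(L_mal = 8.15, L_manu = 4.78, r_head = 1.40, r_handle = 0.35,
                 r_body = 1.25, r_sp = 0.30, r_lp = 0.25,
                 L1 = 3.20, L2 = 2.56,
                 fp_a = 1.405, fp_b = 0.635, fp_t = 0.26, h = 3.28,
                 r_shead = 0.34, r_crus = 0.14, crus_off = 0.55,
                 isj_a = 0.30, isj_b = 0.25),
    stop("unknown scale: ", scale))
}

#' Generate a toy ossicle fixture with analytic ground truth
#'
#' Builds an ossicle-like solid out of analytic primitives, voxelizes it,
#' and emits grayscale volume, bone mask, surface patches, landmarks and a
#' ground-truth record (closed-form mass properties, characteristic
#' lengths, hinge axis and lever arms for the chain).  The same seed gives a
#' bit-identical fixture; `jitter > 0` perturbs the construction dimensions
#' by a relative Gaussian factor, for synthetic cohorts.
#'
#' @param kind `"malleus"`, `"incus"`, `"stapes"` or `"chain"`.
#' @param scale `"sheep"` or `"human"` — which species' published mean
#'   dimensions the toy is built near.
#' @param seed integer RNG seed (only consumed when `jitter > 0`).
#' @param spacing voxel edge, mm (default 0.05; the toys are evaluated at a
#'   coarser grid than raw micro-CT to keep fixtures light).
#' @param density bone density, mg/mm³.
#' @param jitter relative s.d. applied to key dimensions (0 = exact).
#' @param v_L volume fraction of a low-density spherical inclusion placed in
#'   the head/body (0 = none).
#' @return List with `spec` (`phantom_spec`), `grayscale`, `mask`
#'   (`voxel_volume`s), `landmarks` (`landmark_set`), `patches` (named
#'   `surface_mesh` list), and `truth` (analytic `mass_properties` plus
#'   named lengths, and for the chain: `hinge`, `L1`, `L2`,
#'   `lever_ratio`, per-part records).
#' @export
toy_ossicle <- function(kind = c("malleus", "incus", "stapes", "chain"),
                        scale = c("sheep", "human"), seed = 1L,
                        spacing = 0.05, density = 2.2, jitter = 0,
                        v_L = 0) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  par <- toy_scales(scale)
  if (jitter > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    jit <- function(x) x * exp(stats::rnorm(length(x), 0, jitter))
    for (nm in c("L_mal", "L_manu", "r_head", "r_handle", "r_body",
                 "L1", "L2", "fp_a", "fp_b", "h"))
      par[[nm]] <- jit(par[[nm]])
  }
  build <- switch(kind,
    malleus = toy_malleus(par),
    incus = toy_incus(par),
    stapes = toy_stapes(par),
    chain = toy_chain(par))
  if (v_L > 0) {
    # spherical inclusion centred in the first (head/body) primitive
    host <- build$prims[[1]]
    # inclusion sits inside bone, so gross volume = net bone + inclusion
    v_gross <- sum(vapply(build$prims, prim_volume, numeric(1)))
    r_inc <- (3 * v_L * v_gross / (4 * pi))^(1 / 3)
    build$prims <- c(build$prims,
                     list(prim_sphere(host$center, r_inc, phase = "low")))
  }
  spec <- phantom_spec(build$prims, spacing = spacing, seed = seed)
  vox <- voxelize(spec, density = density)
  truth <- vox$truth
  truth[names(build$truth)] <- build$truth
  lms <- landmark_set(build$landmarks, side = "right")
  list(kind = kind, scale = scale, seed = seed, spec = spec,
       grayscale = vox$grayscale, mask = vox$mask,
       landmarks = lms, patches = build$patches, truth = truth)
}

toy_malleus <- function(par, head_center = c(0, 0.6, 0)) {
  r_h <- par$r_head
  head_tip <- head_center + c(0, r_h, 0)
  # umbo placed antero-inferiorly so |head_tip - umbo| = L_mal and the
  # perpendicular distance from the x-axis (the chain hinge) is L1
  dy <- par$L1 + head_center[2] + r_h           # head_tip y - umbo y
  xu2 <- par$L_mal^2 - dy^2
  if (xu2 <= 0) stop("inconsistent toy malleus dimensions")
  umbo <- c(sqrt(xu2), -par$L1, 0)
  d_h <- (umbo - head_center) / sqrt(sum((umbo - head_center)^2))
  len <- sqrt(sum((umbo - head_center)^2)) - r_h
  handle_center <- head_center + d_h * (r_h + len / 2)
  t_lat <- sqrt(par$L_manu^2 - par$r_handle^2)
  n_perp <- c(-d_h[2], d_h[1], 0)
  lateral <- umbo - d_h * t_lat + n_perp * par$r_handle
  anterior <- head_center + c(r_h + 0.2, -0.6, 0)
  prims <- list(prim_sphere(head_center, r_h),
                prim_cylinder(handle_center, par$r_handle, len,
                              R = rot_z_to(d_h)))
  list(prims = prims,
       landmarks = list(head_tip = head_tip, umbo_tip = umbo,
                        lateral_process_tip = lateral,
                        anterior_process = c(anterior[1], 0, 0)),
       patches = list(),
       truth = list(L_mal = par$L_mal, L_manu = par$L_manu))
}

toy_incus <- function(par, body_center = c(-1.9, 0.6, 0)) {
  r_b <- par$r_body
  sp_tip <- c(-3.9, 0, 0)                        # on the chain hinge axis
  d_sp <- (sp_tip - body_center) / sqrt(sum((sp_tip - body_center)^2))
  len_sp <- sqrt(sum((sp_tip - body_center)^2)) - r_b
  isj <- c(body_center[1], -0.85, -sqrt(par$L2^2 - 0.85^2))
  d_lp <- (isj - body_center) / sqrt(sum((isj - body_center)^2))
  len_lp <- sqrt(sum((isj - body_center)^2)) - r_b
  prims <- list(
    prim_sphere(body_center, r_b),
    prim_cylinder(body_center + d_sp * (r_b + len_sp / 2), par$r_sp, len_sp,
                  R = rot_z_to(d_sp)),
    prim_cylinder(body_center + d_lp * (r_b + len_lp / 2), par$r_lp, len_lp,
                  R = rot_z_to(d_lp)))
  isj_patch <- mesh_elliptical_disk(par$isj_a, par$isj_b, center = isj,
                                    R = rot_z_to(c(0, 0, -1)))
  list(prims = prims,
       landmarks = list(short_process_tip = sp_tip, isj_centroid = isj),
       patches = list(isj = isj_patch),
       truth = list(isj_centroid = isj,
                    A_ISJ = pi * par$isj_a * par$isj_b))
}

toy_stapes <- function(par, fp_center = c(-1.9, -0.85, -3.61)) {
  z_s <- c(0, 0, 1)                              # lateral, toward the head
  head_centroid <- fp_center + z_s * par$h
  prims <- list(
    prim_box(fp_center + z_s * par$fp_t / 2,
             c(par$fp_a, par$fp_b, par$fp_t / 2)),
    prim_cylinder(fp_center + c(par$crus_off, 0, par$fp_t +
                                  (par$h - par$fp_t - par$r_shead) / 2),
                  par$r_crus, par$h - par$fp_t - par$r_shead,
                  R = diag(3)),
    prim_cylinder(fp_center + c(-par$crus_off, 0, par$fp_t +
                                  (par$h - par$fp_t - par$r_shead) / 2),
                  par$r_crus, par$h - par$fp_t - par$r_shead,
                  R = diag(3)),
    prim_sphere(head_centroid - z_s * par$r_shead, par$r_shead))
  fp_patch <- mesh_elliptical_disk(par$fp_a, par$fp_b, center = fp_center)
  head_patch <- mesh_elliptical_disk(0.3 * par$r_shead / 0.28,
                                     0.3 * par$r_shead / 0.28,
                                     center = head_centroid)
  list(prims = prims,
       landmarks = list(footplate_centroid = fp_center,
                        head_centroid = head_centroid),
       patches = list(footplate = fp_patch, head = head_patch),
       truth = list(a = 2 * par$fp_a, b = 2 * par$fp_b, h = par$h,
                    A_FT = pi * par$fp_a * par$fp_b))
}

toy_chain <- function(par) {
  m <- toy_malleus(par)
  i <- toy_incus(par)
  s <- toy_stapes(par)
  prims <- c(m$prims, i$prims, s$prims)
  landmarks <- c(m$landmarks, i$landmarks, s$landmarks)
  hinge <- hinge_axis(landmarks$anterior_process, landmarks$short_process_tip)
  lever <- lever_geometry(hinge, landmarks$umbo_tip, landmarks$isj_centroid)
  list(prims = prims, landmarks = landmarks,
       patches = c(i$patches, s$patches),
       truth = c(m$truth, i$truth, s$truth,
                 list(hinge = hinge, L1 = lever$L1, L2 = lever$L2,
                      lever_ratio = lever$ratio)))
}

#' Gently curved synthetic footplate with closed-form projected-area ratio
#'
#' A spherical-cap footplate stand-in: full area `2*pi*R_sph*h_cap`,
#' projected (rim-plane) area `pi*(2*R_sph*h_cap - h_cap^2)`, so the
#' analytic projected-to-full ratio is `1 - h_cap / (2*R_sph)`.
#'
#' @param rim_radius footplate rim radius, mm.
#' @param ratio target projected-area/full-area ratio (e.g. 0.94).
#' @param n_rings,n_seg mesh resolution.
#' @return List: `mesh` (`surface_mesh`), `A` (full area), `A_proj`
#'   (projected area), `ratio` — all closed-form.
#' @export
synthetic_footplate <- function(rim_radius = 0.7, ratio = 0.94,
                                n_rings = 32, n_seg = 72) {
  stopifnot(ratio > 0.5, ratio < 1)
  # ratio = (1 + (h/r_rim)^2 ... solve via h: A_proj/A = r^2 / (r^2 + h^2)
  # with rim radius r and cap height h (since 2*R*h = r^2 + h^2)
  h <- rim_radius * sqrt(1 / ratio - 1)
  R_sph <- (rim_radius^2 + h^2) / (2 * h)
  mesh <- mesh_spherical_cap(R_sph, h, n_rings = n_rings, n_seg = n_seg)
  A <- 2 * pi * R_sph * h
  A_proj <- pi * rim_radius^2
  list(mesh = mesh, A = A, A_proj = A_proj, ratio = A_proj / A)
}
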