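test_that("a voxelized sphere reproduces (2/5) m r^2 on all principal axes", {
  v <- voxel_sphere()                       # r = 0.4 mm at 0.01 mm spacing
  mp <- mass_properties_from_mask(v$mask, 1)
  I_ref <- 2 / 5 * mp$mass * 0.4^2
  expect_equal(mp$principal_moments, rep(I_ref, 3), tolerance = 0.01)
  expect_equal(mp$volume, 4 / 3 * pi * 0.4^3, tolerance = 0.005)
})

test_that("a single voxel is a point mass at its centre", {
  arr <- array(0, dim = c(3, 3, 3)); arr[2, 2, 2] <- 1
  vol <- voxel_volume(arr, 0.01, origin = c(0.1, 0.2, 0.3))
  mp <- mass_properties_from_mask(vol, 1)
  expect_equal(mp$com, c(0.11, 0.21, 0.31))
  expect_equal(mp$inertia_com, matrix(0, 3, 3))
  expect_equal(mp$mass, 1e-6)
  # the solid-cube correction adds m s^2 / 6 on the diagonal
  mpc <- mass_properties_from_mask(vol, 1, cube_correction = TRUE)
  expect_equal(mpc$inertia_com, diag(3) * 1e-6 * 0.01^2 / 6)
})

test_that("voxelized ellipsoid matches the closed-form inertia family", {
  v <- voxelize(phantom_spec(list(prim_ellipsoid(c(0, 0, 0), c(0.8, 0.4, 0.2))),
                             spacing = 0.01), density = 1)
  mp <- mass_properties_from_mask(v$mask, 1)
  m <- mp$mass
  ref <- sort(m / 5 * c(0.4^2 + 0.2^2, 0.8^2 + 0.2^2, 0.8^2 + 0.4^2))
  expect_equal(mp$principal_moments, ref, tolerance = 0.01)
  # axes aligned with the generator axes within 1 degree
  dots <- abs(diag(t(mp$principal_axes) %*% v$truth$principal_axes))
  expect_true(all(dots > cos(pi / 180)))
  expect_equal(det(mp$principal_axes), 1, tolerance = 1e-9)
})

test_that("moment_about_axis reduces to principal moments and obeys Eq.-2 offsets", {
  v <- voxel_sphere()
  mp <- mass_properties_from_mask(v$mask, 1)
  for (j in 1:3) {
    ax <- axis3d(mp$com, mp$principal_axes[, j])
    expect_equal(moment_about_axis(mp, ax), mp$principal_moments[j])
  }
  # sphere: any axis through the COM gives the same moment
  set.seed(42)
  vals <- replicate(8, moment_about_axis(mp, axis3d(mp$com, random_unit_vector())))
  expect_equal(max(vals) / min(vals), 1, tolerance = 1e-9)
  # parallel-axis: offsetting the axis adds exactly m d^2
  n <- c(0, 0, 1); d <- 0.37
  base <- moment_about_axis(mp, axis3d(mp$com, n))
  off <- moment_about_axis(mp, axis3d(mp$com + c(d, 0, 0), n))
  expect_equal(off - base, mp$mass * d^2)
})

test_that("moments_in_frame returns the three axis moments through a point", {
  fx <- toy_sheep_malleus()
  mp <- mass_properties_from_mask(fx$mask, 2.2)
  pf <- anatomical_frame(mp$com, mp$principal_axes)
  expect_equal(unname(moments_in_frame(mp, pf)), mp$principal_moments)
  # rotating the frame 90 degrees about z swaps the x and y moments
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rot <- anatomical_frame(mp$com, pf$axes %*% Rz)
  mo <- moments_in_frame(mp, pf); mr <- moments_in_frame(mp, rot)
  expect_equal(unname(mr), unname(mo[c(2, 1, 3)]))
  expect_error(anatomical_frame(mp$com, matrix(1, 3, 3)), "orthonormal")
  # matches the brute-force voxel sum on a composite phantom
  two <- voxelize(phantom_spec(list(prim_sphere(c(0, 0, 0), 0.25),
                                    prim_sphere(c(0.7, 0.1, 0), 0.18)),
                               spacing = 0.01), density = 2)
  mp2 <- mass_properties_from_mask(two$mask, 2)
  fr <- anatomical_frame(c(0.2, 0, 0), diag(3))
  got <- moments_in_frame(mp2, fr, through = c(0.2, 0, 0))
  bf <- vapply(1:3, function(j)
    brute_force_inertia(two$mask, 2, axis3d(c(0.2, 0, 0), diag(3)[, j])),
    numeric(1))
  expect_equal(unname(got), bf, tolerance = 0.005)
})

test_that("bony-phase density correction matches its closed form", {
  # zero low-density fraction: plain m / V
  expect_equal(density_correction(22.9, 10.4, 0, 1), 22.9 / 10.4)
  # water-density low phase at 1% and 2% of the chain volume
  expect_equal(signif(density_correction_factor(22.9, 10.4, 0.01, 1), 2), 0.0045)
  expect_equal(signif(density_correction_factor(22.9, 10.4, 0.02, 1), 2), 0.0091)
  expect_error(density_correction(22.9, 10.4, 1, 1), "v_L")
  expect_error(density_correction(1, 10, 0.5, 1), "mass")
})

test_that("combine_bodies follows rigid-body addition", {
  fx <- toy_sheep_malleus()
  mp <- mass_properties_from_mask(fx$mask, 2.2)
  expect_identical(combine_bodies(list(mp)), mp)
  # two equal point masses m at +/- d/2 on x: I about y = 2 m (d/2)^2
  m <- 3; d <- 1.4
  pm <- function(x) mass_properties(volume = 1, mass = m, com = c(x, 0, 0),
                                    inertia_com = matrix(0, 3, 3))
  comb <- combine_bodies(list(pm(-d / 2), pm(d / 2)))
  expect_equal(moment_about_axis(comb, axis3d(c(0, 0, 0), c(0, 1, 0))),
               2 * m * (d / 2)^2)
  expect_equal(comb$com, c(0, 0, 0))
  # sphere + rod combined part-wise vs voxelizing the union directly
  sphere <- prim_sphere(c(0, 0, 0), 0.3)
  rod <- prim_cylinder(c(0, 0, 0.55), 0.08, 0.5)
  apart <- lapply(list(sphere, rod), function(p)
    mass_properties_from_mask(
      voxelize(phantom_spec(list(p), spacing = 0.008), 2)$mask, 2))
  union <- mass_properties_from_mask(
    voxelize(phantom_spec(list(sphere, rod), spacing = 0.008), 2)$mask, 2)
  comb2 <- combine_bodies(apart)
  expect_equal(comb2$principal_moments, union$principal_moments,
               tolerance = 0.01)
  expect_error(combine_bodies(list()), "at least one")
})

test_that("principal moments are invariant under rotations of the body", {
  fx <- toy_sheep_incus()
  a <- mass_properties_from_mask(fx$mask, 2)
  # 90-degree grid rotation (x, y, z) -> (x, z, -y): exact to machine precision
  d3 <- dim(fx$mask$values)[3]
  rot <- voxel_volume(aperm(fx$mask$values[, , d3:1], c(1, 3, 2)),
                      fx$mask$spacing)
  b <- mass_properties_from_mask(rot, 2)
  expect_equal(b$principal_moments, a$principal_moments, tolerance = 1e-12)
  expect_equal(sum(diag(b$inertia_com)), sum(diag(a$inertia_com)),
               tolerance = 1e-12)
  # arbitrary-angle re-voxelized rotation: invariant within 1%
  R <- rotation_about_test(c(1, 2, 2) / 3, 0.7)
  rot_prims <- list(prim_ellipsoid(c(0, 0, 0), c(0.5, 0.3, 0.15), R = R))
  base_prims <- list(prim_ellipsoid(c(0, 0, 0), c(0.5, 0.3, 0.15)))
  pa <- mass_properties_from_mask(
    voxelize(phantom_spec(base_prims, spacing = 0.008), 1)$mask, 1)
  pb <- mass_properties_from_mask(
    voxelize(phantom_spec(rot_prims, spacing = 0.008), 1)$mask, 1)
  expect_equal(pb$principal_moments, pa$principal_moments, tolerance = 0.01)
})

test_that("rigid-body spectral invariants hold on random phantoms", {
  for (s in 1:5) {
    v <- random_phantom(100 + s)
    mp <- mass_properties_from_mask(v$mask, 2)
    pmom <- mp$principal_moments
    expect_true(all(pmom >= 0))
    expect_true(all(diff(pmom) >= -1e-12))
    expect_lte(pmom[3], pmom[1] + pmom[2] + 1e-9 * pmom[3])
    expect_equal(max(abs(mp$inertia_com - t(mp$inertia_com))), 0)
  }
})

test_that("the COM-axis moment is minimised along the first principal axis", {
  fx <- toy_sheep_malleus()
  mp <- mass_properties_from_mask(fx$mask, 2.2)
  set.seed(7)
  dirs <- cbind(replicate(500, random_unit_vector()))
  vals <- apply(dirs, 2, function(n) moment_about_axis(mp, axis3d(mp$com, n)))
  expect_gte(min(vals), mp$principal_moments[1] - 1e-9)
})
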