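test_that("characteristic lengths are plain 3D distances with named errors", {
  lm <- landmark_set(list(head_tip = c(0, 0, 0), umbo_tip = c(0, 0, 7.88),
                          lateral_process_tip = c(0, 0.3, 2.7)), "right")
  cl <- characteristic_lengths(lm, "malleus")
  expect_equal(unname(cl["L_mal"]), 7.88)
  expect_equal(point_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  lm2 <- landmark_set(list(head_tip = c(0, 0, 0)), "right")
  expect_error(characteristic_lengths(lm2, "malleus"), "umbo_tip")
})

test_that("sheep manubrium-to-total-length ratio is consistent with the toy build", {
  fx <- toy_sheep_malleus()
  cl <- characteristic_lengths(fx$landmarks, "malleus")
  expect_equal(unname(cl["L_mal"]), fx$truth$L_mal)
  expect_equal(unname(cl["L_manu"]), fx$truth$L_manu)
  expect_equal(unname(cl["L_manu_over_L_mal"]), 0.67, tolerance = 0.015)
})

test_that("patch area and centroid follow the triangle-sum definitions", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(1:3, 1))
  p <- patch_area_centroid(tri)
  expect_equal(p$area, 0.5)
  expect_equal(p$centroid, c(1 / 3, 1 / 3, 0))
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  ps <- patch_area_centroid(sq)
  expect_equal(ps$area, 1)
  expect_equal(ps$centroid, c(0.5, 0.5, 0))
  hemi <- mesh_hemisphere(1, n_rings = 48, n_seg = 128)
  expect_equal(mesh_area(hemi), 2 * pi, tolerance = 0.005)
  degen <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        matrix(1:3, 1))
  expect_error(patch_area_centroid(degen), "zero total area")
})

test_that("plane fitting and projection handle flat and curved patches", {
  sq <- surface_mesh(rbind(c(0, 0, 1), c(2, 0, 1), c(2, 1, 1), c(0, 1, 1)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  pl <- fit_plane(sq)
  expect_equal(abs(pl$normal), c(0, 0, 1))
  expect_equal(projected_area(sq, pl), 2, tolerance = 1e-9)
  hemi <- mesh_hemisphere(1, n_rings = 48, n_seg = 128)
  eq_plane <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  a_proj <- projected_area(hemi, eq_plane)
  expect_equal(a_proj, pi, tolerance = 0.01)
  expect_equal(a_proj / mesh_area(hemi), 0.5, tolerance = 0.01)
  line <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 0, 0)),
                       rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_error(fit_plane(line), "collinear|zero total area")
})

test_that("projected area never exceeds patch area", {
  fp <- synthetic_footplate(0.7, 0.94)
  expect_lte(projected_area(fp$mesh), mesh_area(fp$mesh))
  expect_equal(projected_area(fp$mesh) / mesh_area(fp$mesh), fp$ratio,
               tolerance = 0.01)
  hemi <- mesh_hemisphere(0.8)
  expect_lte(projected_area(hemi), mesh_area(hemi))
})

test_that("equivalent diameters match the printed footplate means", {
  expect_equal(equivalent_diameter(2.86), 1.90, tolerance = 0.01)
  expect_equal(equivalent_diameter(1.45), 1.36, tolerance = 0.005)
  expect_equal(equivalent_diameter(pi / 4), 1)
  # inverse identity
  for (A in c(0.3, 1.45, 2.86, 10))
    expect_equal(pi * equivalent_diameter(A)^2 / 4, A)
  expect_error(equivalent_diameter(0), "> 0")
})

test_that("the stapes frame recovers footplate geometry from the toy build", {
  fx <- toy_sheep_stapes()
  mp <- mass_properties_from_mask(fx$mask, 2.11)
  sf <- stapes_frame(fx$patches$footplate, fx$patches$head, com = mp$com)
  expect_equal(sf$a, fx$truth$a, tolerance = 0.01)
  expect_equal(sf$b, fx$truth$b, tolerance = 0.01)
  expect_equal(sf$h, fx$truth$h, tolerance = 0.01)
  expect_equal(sf$a_over_b, 2.2, tolerance = 0.05)     # sheep-like aspect
  expect_equal(sf$A_FT, fx$truth$A_FT, tolerance = 0.01)
  # z axis signed toward the head (lateral)
  head_c <- patch_area_centroid(fx$patches$head)$centroid
  expect_gt(sum((head_c - sf$frame$origin) * sf$frame$axes[, 3]), 0)
  expect_equal(sf$frame$handedness, "right")
  expect_gt(sf$h_c, 0)
  expect_equal(sf$h_c_over_h, sf$h_c / sf$h)
})

test_that("stapes measurements are invariant under rigid motion", {
  fx <- toy_sheep_stapes()
  R <- rotation_about_test(c(2, -1, 1), 1.1)
  t <- c(3, -2, 5)
  move <- function(mesh) surface_mesh(
    sweep(mesh$vertices %*% t(R), 2, t, "+"), mesh$faces)
  a <- stapes_frame(fx$patches$footplate, fx$patches$head)
  b <- stapes_frame(move(fx$patches$footplate), move(fx$patches$head))
  expect_equal(b$a, a$a, tolerance = 1e-6)
  expect_equal(b$b, a$b, tolerance = 1e-6)
  expect_equal(b$h, a$h, tolerance = 1e-9)
  expect_equal(b$A_FTproj, a$A_FTproj, tolerance = 1e-6)
})

test_that("the hinge axis is the sign-normalised line through its landmarks", {
  ax <- hinge_axis(c(0, 0, 0), c(1, 0, 0))
  expect_equal(ax$direction, c(1, 0, 0))
  sw <- hinge_axis(c(1, 0, 0), c(0, 0, 0))
  expect_equal(sw$direction, ax$direction)
  expect_equal(point_axis_distance(c(0.3, 0, 0), sw), 0)
  expect_error(hinge_axis(c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("lever arms are perpendicular distances and their ratio the lever ratio", {
  ax <- axis3d(c(0, 0, 0), c(1, 0, 0))
  lev <- lever_geometry(ax, c(0, 4, 0), c(0, 2, 0))
  expect_equal(lev$L1, 4); expect_equal(lev$L2, 2); expect_equal(lev$ratio, 2)
  # mean arm lengths give a ratio consistent with per-sample averaging
  lev2 <- lever_geometry(ax, c(5, 4.16, 0), c(-1, 0, 1.69))
  expect_equal(lev2$ratio, 2.47, tolerance = 0.02)
  expect_error(lever_geometry(ax, c(1, 0, 0), c(0, 2, 0)), "umbo")
  expect_error(lever_geometry(ax, c(0, 4, 0), c(2, 0, 0)), "ISJ")
  # uniform scaling leaves the ratio unchanged, arms scale linearly
  s <- 3.7
  lev3 <- lever_geometry(ax, s * c(0, 4, 0), s * c(0, 2, 0))
  expect_equal(lev3$ratio, lev$ratio)
  expect_equal(lev3$L1, s * lev$L1)
})

test_that("the toy chain's landmarks reproduce its stored lever truth", {
  fx <- toy_sheep_chain()
  hx <- hinge_axis(get_landmark(fx$landmarks, "anterior_process"),
                   get_landmark(fx$landmarks, "short_process_tip"))
  lev <- lever_geometry(hx, get_landmark(fx$landmarks, "umbo_tip"),
                        get_landmark(fx$landmarks, "isj_centroid"))
  expect_equal(lev$L1, fx$truth$L1)
  expect_equal(lev$L2, fx$truth$L2)
  expect_equal(lev$ratio, fx$truth$lever_ratio)
  expect_equal(point_axis_distance(
    get_landmark(fx$landmarks, "anterior_process"), hx), 0)
})

test_that("the global intrinsic frame recentres the chain on its COM", {
  fx <- toy_sheep_chain()
  chain <- mass_properties_from_mask(fx$mask, 2.2)
  sfr <- anatomical_frame(c(0, 0, 0), diag(3))
  parts <- list(m = mass_properties(1, 2, com = c(1, 0, 0),
                                    inertia_com = diag(3) * 0.1),
                i = mass_properties(1, 2, com = c(-1, 0, 0),
                                    inertia_com = diag(3) * 0.1))
  gf <- global_frame(combine_bodies(parts), sfr, parts = parts)
  # identity axes: coordinates shift by minus the chain COM
  expect_equal(gf$frame$origin, c(0, 0, 0))
  expect_equal(gf$part_coms["m", ], c(x = 1, y = 0, z = 0))
  # mass-weighted mean of re-expressed COMs is the origin
  masses <- vapply(parts, `[[`, numeric(1), "mass")
  expect_equal(colSums(gf$part_coms * masses) / sum(masses),
               c(x = 0, y = 0, z = 0))
  gf2 <- global_frame(chain, sfr)
  expect_equal(gf2$frame$origin, chain$com)
})

test_that("lengths and areas are invariant under random rigid transforms", {
  fx <- toy_sheep_malleus()
  set.seed(11)
  for (k in 1:3) {
    u <- random_unit_vector()
    R <- rotation_about_test(u, stats::runif(1, 0, 2 * pi))
    t <- stats::rnorm(3, sd = 4)
    moved <- lapply(fx$landmarks$points, function(p) as.numeric(R %*% p + t))
    lm2 <- landmark_set(moved, "right")
    cl1 <- characteristic_lengths(fx$landmarks, "malleus")
    cl2 <- characteristic_lengths(lm2, "malleus")
    expect_equal(cl2, cl1, tolerance = 1e-9)
  }
})
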