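test_that("circuit radius is the RMS of the ellipse semi-axes", {
  expect_equal(circuit_radius(600, 600), 600)
  expect_equal(circuit_radius(3, 4), sqrt(12.5))
  expect_error(circuit_radius(0, 4), class = "gazestab_input_error")
})

test_that("X_max follows the R r^2 law", {
  expect_equal(xmax(1, 1), 1)
  expect_equal(xmax(2, 1) / xmax(1, 1), 2)       # linear in R
  expect_equal(xmax(1, 2) / xmax(1, 1), 4)       # quadratic in r
  # species sensitivity ordering from the printed radii
  xen <- species_preset("xenopus_54"); axo <- species_preset("axolotl_54")
  ratio <- xmax(axo$circuit_radius, axo$lumen_radius) /
    xmax(xen$circuit_radius, xen$lumen_radius)
  expect_lt(ratio, 1)
  g <- xmax_grid(c(20, 120), c(300, 800), n = 10)
  expect_equal(nrow(g), 100)
  expect_error(xmax(-1, 1), class = "gazestab_input_error")
})

test_that("direct ellipse fits recover exact and noisy boundaries", {
  fit <- fit_ellipse_2d(ellipse_points(600, 500, angle = 0.4,
                                       center = c(120, -40)))
  expect_rel(fit$semi_major, 600, 0.001)
  expect_rel(fit$semi_minor, 500, 0.001)
  expect_equal(fit$x0, 120, tolerance = 0.5)

  circ <- fit_ellipse_2d(ellipse_points(300, 300))
  expect_equal(circ$semi_major / circ$semi_minor, 1, tolerance = 1e-6)

  set.seed(13)
  noisy <- fit_ellipse_2d(ellipse_points(600, 500, noise_sd = 0.01))
  expect_rel(noisy$semi_major, 600, 0.02)
  expect_rel(noisy$semi_minor, 500, 0.02)

  expect_error(fit_ellipse_2d(tibble(x = 1:5, y = 1:5)),
               class = "gazestab_fit_error")
  line <- tibble(x = seq(0, 1, length.out = 30),
                 y = 2 * seq(0, 1, length.out = 30))
  expect_error(fit_ellipse_2d(line), class = "gazestab_fit_error")
})

test_that("ampulla shape ratio is 1 for circles and orders elongation", {
  expect_equal(ampulla_shape(ellipse_points(50, 50))$ratio, 1,
               tolerance = 1e-6)
  expect_equal(ampulla_shape(ellipse_points(80, 40))$ratio, 2,
               tolerance = 1e-3)
  round_amp <- ampulla_shape(ellipse_points(55, 50))
  long_amp <- ampulla_shape(ellipse_points(90, 50))
  expect_gt(long_amp$ratio, round_amp$ratio)
})

test_that("segmentation recovers blurred noisy phantoms", {
  cfg <- canal_config(semi_axes = c(180, 180), tube_radius = 28,
                      arc_span = 300, voxel_size = 5)
  clean <- simulate_canal(cfg)
  dice <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

  blurred <- simulate_canal(canal_config(semi_axes = c(180, 180),
                                         tube_radius = 28, arc_span = 300,
                                         voxel_size = 5, blur_sigma = 1))
  seg <- segment_volume(blurred, blur_sigma = 0)
  expect_gt(dice(seg$voxels, clean$voxels), 0.98)

  set.seed(77)
  d <- dim(clean$voxels)
  noisy <- canal_volume(
    array(pmin(pmax(blurred$voxels +
                      array(rnorm(prod(d), 0, 0.1), d), 0), 1), d), 5)
  segn <- segment_volume(noisy, blur_sigma = 1.5)
  expect_gt(dice(segn$voxels, clean$voxels), 0.95)

  blank <- canal_volume(array(0, c(20, 20, 20)), 2)
  expect_error(segment_volume(blank, blur_sigma = 0, threshold = 0.5),
               class = "gazestab_segmentation_error")
})

test_that("equivalent ellipsoids recover analytic shapes and orderings", {
  ell <- fit_ellipsoid_3d(solid_ellipsoid(600, 500, 100, voxel = 10))
  expect_rel(ell$a / ell$b, 1.2, 0.03)
  expect_rel(ell$b / ell$c, 5, 0.03)
  expect_rel(ell$a, 600, 0.03)
  expect_rel(ell$volume, 4 / 3 * pi * 600 * 500 * 100, 0.05)

  sph <- fit_ellipsoid_3d(solid_ellipsoid(200, 200, 200, voxel = 8))
  expect_equal(sph$elongation, 1, tolerance = 0.02)
  expect_equal(sph$flatness, 1, tolerance = 0.02)

  # vertical-extent mode: a tilted canal is less flat than a planar one
  planar <- simulate_canal(canal_config(semi_axes = c(250, 230),
                                        tube_radius = 35, arc_span = 330,
                                        voxel_size = 5))
  tilted <- simulate_canal(canal_config(semi_axes = c(250, 230),
                                        tube_radius = 35, arc_span = 330,
                                        voxel_size = 5,
                                        out_of_plane_tilt = 30))
  fp <- fit_ellipsoid_3d(planar, c_axis = "z")
  ft <- fit_ellipsoid_3d(tilted, c_axis = "z")
  expect_gt(fp$flatness, ft$flatness)

  tiny <- canal_volume(array(c(rep(0, 995), rep(1, 5)), c(10, 10, 10)), 2)
  expect_error(fit_ellipsoid_3d(tiny), class = "gazestab_resolution_error")
})

test_that("metrics scale correctly under voxel-size rescaling", {
  vol1 <- simulate_canal(canal_config(semi_axes = c(200, 180),
                                      tube_radius = 30, arc_span = 300,
                                      voxel_size = 5))
  vol2 <- canal_volume(vol1$voxels, vol1$voxel_size * 2,
                       is_binary = TRUE)     # same grid, doubled spacing
  f1 <- fit_ellipsoid_3d(vol1); f2 <- fit_ellipsoid_3d(vol2)
  expect_equal(f2$a / f1$a, 2, tolerance = 1e-9)
  expect_equal(f2$volume / f1$volume, 8, tolerance = 1e-9)
  expect_equal(f2$elongation, f1$elongation, tolerance = 1e-9)
  expect_equal(f2$flatness, f1$flatness, tolerance = 1e-9)
  cl1 <- extract_centerline(vol1); cl2 <- extract_centerline(vol2)
  expect_rel(attr(cl2, "duct_length") / attr(cl1, "duct_length"), 2, 0.02)
})

test_that("centerline length matches analytic tubes and arcs", {
  tube <- straight_tube(radius = 40, length = 1000, voxel = 4)
  cl <- extract_centerline(tube)
  expect_rel(attr(cl, "duct_length"), 1000, 0.03)

  half <- simulate_canal(canal_config(semi_axes = c(350, 350),
                                      tube_radius = 40, arc_span = 180,
                                      voxel_size = 4))
  clh <- extract_centerline(half)
  expect_rel(attr(clh, "duct_length"), pi * 350, 0.03)

  closed <- simulate_canal(canal_config(semi_axes = c(150, 150),
                                        tube_radius = 25, voxel_size = 6))
  expect_error(extract_centerline(closed), class = "gazestab_topology_error")
})

test_that("cross-section profiles are flat for tubes and find stenoses", {
  half <- simulate_canal(canal_config(semi_axes = c(300, 300),
                                      tube_radius = 40, arc_span = 180,
                                      voxel_size = 3))
  cl <- extract_centerline(half)
  prof <- cross_section_profile(half, cl)
  expect_true(all(abs(prof$area / (pi * 40^2) - 1) < 0.05))
  g <- glance(prof)
  expect_rel(g$equivalent_radius, 40, 0.03)
  expect_false(g$stenosis_detected)
  expect_lte(g$stenosis_ratio, 1)

  sten <- simulate_canal(canal_config(semi_axes = c(300, 300),
                                      tube_radius = 40, arc_span = 240,
                                      voxel_size = 3, ampulla_scale = 1.5,
                                      stenosis = c(0.82, 0.5)))
  cls <- extract_centerline(sten)
  profs <- cross_section_profile(sten, cls)
  gs <- glance(profs)
  gt <- attr(sten, "ground_truth")
  # area scales as the square of the constriction factor
  expect_lt(abs(gs$stenosis_ratio - gt$stenosis_ratio), 0.05)
  expect_lt(abs(gs$stenosis_position - gt$stenosis_position), 0.03)
  expect_true(gs$stenosis_detected)
})

test_that("the full morphometry chain summarises one specimen", {
  vol <- simulate_canal(canal_config(semi_axes = c(260, 240),
                                     tube_radius = 35, arc_span = 320,
                                     voxel_size = 4))
  m <- canal_morphometry(vol)
  expect_rel(m$lumen_radius, 35, 0.05)
  expect_rel(m$circuit_radius, circuit_radius(260, 240), 0.06)
  expect_gte(m$elongation, 1)
  expect_equal(m$xmax_relative, m$circuit_radius * m$lumen_radius^2)
  expect_s3_class(attr(m, "cs_profile"), "cs_profile")
})
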