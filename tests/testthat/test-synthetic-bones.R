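cylinder_params <- function(radius = 10) {
  bone_params(axis_length = 70, axial_curvature = 0,
              station_profiles = data.frame(zf = c(0, 1),
                                            half_width = radius,
                                            half_depth = radius,
                                            squareness = 2),
              styloid_height = 0, tubercle_prominence = 0)
}

test_that("a plain cylinder reproduces the circular closed forms", {
  b <- generate_bone(cylinder_params(10), resolution = 0.5)
  expect_true(validate_mesh(b$mesh)$watertight)
  pl <- cut_plane("middle", c(0, 0, 35))
  m <- section_morphometrics(cross_section(b$mesh, pl))
  expect_equal(m$width, 20, tolerance = 0.01)
  expect_equal(m$depth, 20, tolerance = 0.01)
  expect_equal(m$perimeter, 2 * pi * 10, tolerance = 0.01)
  expect_equal(m$area, pi * 100, tolerance = 0.01)
})

test_that("proximal taper shrinks the analytic section area", {
  sp <- data.frame(zf = c(0, 1), half_width = c(8, 10),
                   half_depth = c(8, 10), squareness = 2)
  p <- bone_params(axis_length = 70, axial_curvature = 0,
                   station_profiles = sp, styloid_height = 0,
                   tubercle_prominence = 0)
  a_prox <- abs(radiusSSM:::polygon_signed_area(analytic_section(p, 10)))
  a_dist <- abs(radiusSSM:::polygon_signed_area(analytic_section(p, 65)))
  expect_lt(a_prox, a_dist)
  # against the superellipse closed form
  pr <- radiusSSM:::profile_at(p, 10)
  expect_equal(a_prox, superellipse_area(pr$a, pr$b, pr$p),
               tolerance = 1e-5)
})

test_that("left bones are exact mirror images of right bones", {
  pr <- generate_bone(bone_params(side = "R"), resolution = 1.2)
  pl <- generate_bone(bone_params(side = "L"), resolution = 1.2)
  expect_equal(mirror_mesh(pr$mesh)$vertices, pl$mesh$vertices)
  expect_equal(pl$truth_landmarks$styloid_tip * c(-1, 1, 1),
               pr$truth_landmarks$styloid_tip)
  expect_equal(mesh_volume(pl$mesh), mesh_volume(pr$mesh))
})

test_that("degenerate profiles are rejected", {
  expect_error(bone_params(station_profiles = data.frame(
    zf = c(0, 1), half_width = c(0, 10), half_depth = 8, squareness = 2)),
    "degenerate")
  expect_error(bone_params(station_profiles = data.frame(
    zf = c(0.5, 0.2), half_width = 10, half_depth = 8, squareness = 2)),
    "increasing")
  expect_error(generate_bone(bone_params(), resolution = -1))
})

test_that("truth landmarks are mesh vertices on the surface", {
  b <- generate_bone(bone_params(), resolution = 1.2)
  for (lm in b$truth_landmarks) {
    d <- closest_point_on_mesh(matrix(lm, 1, 3), b$mesh)$distance
    expect_lt(d, 1e-9)
  }
})

test_that("population sampling is byte-identical under a seed", {
  cfg <- population_config(n_per_group = 3, seed = 7, mesh_resolution = 2.5)
  p1 <- sample_population(cfg)
  p2 <- sample_population(cfg)
  expect_identical(names(p1), names(p2))
  for (id in names(p1))
    expect_identical(p1[[id]]$mesh$vertices, p2[[id]]$mesh$vertices)
  # and the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(sample_population(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the planted gender size ratio is recovered from samples", {
  cfg <- population_config(n_per_group = 250, seed = 21)
  pars <- sample_population(cfg, meshes = FALSE)
  g <- vapply(pars, function(p) attr(p, "gender"), "")
  w <- vapply(pars, function(p)
    2 * max(p$station_profiles$half_width) * p$global_scale, 0)
  # tolerance = 3 x the Monte-Carlo SE of the ratio at this sample size
  expect_equal(mean(w[g == "M"]) / mean(w[g == "F"]), 33 / 29,
               tolerance = 0.015)
})

test_that("mesh morphometrics converge to the analytic section values", {
  p <- bone_params()
  b <- generate_bone(p, resolution = 0.5)
  zt <- p$tubercle_z_fraction * p$axis_length
  truth <- section_morphometrics(analytic_section(p, zt))
  m <- section_morphometrics(cross_section(b$mesh,
                                           cut_plane("distal", c(0, 0, zt))))
  expect_equal(m$width, truth$width, tolerance = 0.005)
  expect_equal(m$depth, truth$depth, tolerance = 0.005)
  expect_equal(m$perimeter, truth$perimeter, tolerance = 0.005)
  expect_equal(m$area, truth$area, tolerance = 0.005)
})

test_that("the calibrated default bone hits the reference distal anchors", {
  p <- bone_params()
  zt <- p$tubercle_z_fraction * p$axis_length
  m <- section_morphometrics(analytic_section(p, zt))
  expect_equal(m$width, 29.0, tolerance = 1e-6)
  expect_equal(m$depth, 21.0, tolerance = 1e-6)
  expect_equal(m$area, 472.6, tolerance = 1e-3)
})

test_that("population manifest CSV records ids, labels and landmarks", {
  cfg <- population_config(n_per_group = 2, seed = 4, mesh_resolution = 3)
  pop <- sample_population(cfg)
  path <- tempfile(fileext = ".csv")
  write_population_manifest(pop, path, seed = 4)
  d <- read.csv(path)
  expect_identical(nrow(d), 8L)
  expect_setequal(names(d), c("id", "gender", "side", "seed",
                              "styloid_x", "styloid_y", "styloid_z",
                              "tubercle_x", "tubercle_y", "tubercle_z"))
  unlink(path)
})
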