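test_that("landmark detection matches the generator ground truth", {
  for (side in c("R", "L")) {
    b <- generate_bone(bone_params(side = side), resolution = 1.2)
    lm <- detect_landmarks(b$mesh)
    tol <- 2 * median(edge_lengths(b$mesh))
    expect_lt(sqrt(sum((lm$styloid_tip - b$truth_landmarks$styloid_tip)^2)),
              tol)
    expect_lt(sqrt(sum((lm$tubercle_dorsal -
                          b$truth_landmarks$tubercle_dorsal)^2)), tol)
  }
})

test_that("landmarks of mirrored bones are mirror images", {
  br <- generate_bone(bone_params(side = "R"), resolution = 1.2)
  bl <- generate_bone(bone_params(side = "L"), resolution = 1.2)
  lr <- detect_landmarks(br$mesh)
  ll <- detect_landmarks(bl$mesh)
  expect_equal(ll$styloid_tip * c(-1, 1, 1), lr$styloid_tip)
  expect_equal(ll$tubercle_dorsal * c(-1, 1, 1), lr$tubercle_dorsal)
})

test_that("a featureless cylinder has no identifiable landmarks", {
  p <- bone_params(axis_length = 70, axial_curvature = 0,
                   station_profiles = data.frame(zf = c(0, 1),
                                                 half_width = 10,
                                                 half_depth = 10,
                                                 squareness = 2),
                   styloid_height = 0, tubercle_prominence = 0)
  b <- generate_bone(p, resolution = 1)
  expect_error(detect_landmarks(b$mesh), "not identifiable")
})

test_that("cut planes follow the landmark arithmetic", {
  lm <- structure(list(styloid_tip = c(10, 0, 100),
                       tubercle_dorsal = c(0, 12, 90),
                       frame = list(axis = c(0, 0, 1), dorsal = c(0, 1, 0),
                                    lateral = c(1, 0, 0))),
                  class = "landmarks")
  pl <- define_cut_planes(lm)
  expect_equal(pl$distal$origin[3], 90)
  expect_equal(pl$middle$origin[3], 87.5)
  expect_equal(pl$proximal$origin[3], 85)
  # equidistant gaps of d/4
  expect_equal(pl$distal$origin[3] - pl$middle$origin[3], 2.5)
  expect_equal(pl$middle$origin[3] - pl$proximal$origin[3], 2.5)
  lm$styloid_tip[3] <- 90
  expect_error(define_cut_planes(lm), "not positive")
})

test_that("cube and sphere cross-sections match closed forms", {
  cu <- unit_cube()
  m <- section_morphometrics(cross_section(cu, cut_plane("d", c(0, 0, 0.5))))
  expect_equal(m$width, 1, tolerance = 1e-9)
  expect_equal(m$depth, 1, tolerance = 1e-9)
  expect_equal(m$perimeter, 4, tolerance = 1e-9)
  expect_equal(m$area, 1, tolerance = 1e-9)

  s <- icosphere(5, 4)
  ms <- section_morphometrics(cross_section(s, cut_plane("d", c(0, 0, 3))))
  expect_equal(ms$perimeter, 2 * pi * 4, tolerance = 0.005)
  expect_equal(ms$area, pi * 16, tolerance = 0.005)

  expect_error(cross_section(s, cut_plane("d", c(0, 0, 7))), "misses")
})

test_that("section morphometrics match simple polygon oracles", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  m <- section_morphometrics(sq)
  expect_equal(unclass(m)[c("width", "depth", "perimeter", "area")],
               list(width = 1, depth = 1, perimeter = 4, area = 1))
  # dense ellipse with the male distal half-axes
  th <- seq(0, 2 * pi, length.out = 4001)[-1]
  el <- cbind(16.5 * cos(th), 11.9 * sin(th))
  me <- section_morphometrics(el)
  expect_equal(me$width, 33, tolerance = 1e-4)
  expect_equal(me$depth, 23.8, tolerance = 1e-4)
  expect_equal(me$area, pi * 16.5 * 11.9, tolerance = 1e-4)
  # L-shaped polygon, hand-computed shoelace
  ls <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
  ml <- section_morphometrics(ls)
  expect_equal(ml$area, 3)
  expect_equal(ml$perimeter, 8)
  expect_equal(ml$width, 2)
  expect_equal(ml$depth, 2)
  expect_error(section_morphometrics(sq[1:2, ]), "3 vertices")
})

test_that("morphometric type invariants hold on computed bone sections", {
  b <- generate_bone(bone_params(), resolution = 1)
  lm <- detect_landmarks(b$mesh)
  for (pl in define_cut_planes(lm)) {
    m <- section_morphometrics(cross_section(b$mesh, pl))
    expect_true(all(unlist(m) > 0))
    expect_lte(4 * pi * m$area, m$perimeter^2 * (1 + 1e-9))
    expect_lte(m$area, m$width * m$depth)
    expect_gte(m$perimeter, 2 * max(m$width, m$depth))
  }
})

test_that("translating the mesh along the axis leaves morphometrics fixed", {
  b <- generate_bone(bone_params(), resolution = 1.5)
  shifted <- transform_mesh(b$mesh, rigid_transform(diag(3), c(0, 0, 12.3)))
  m0 <- specimen_morphometrics(b$mesh)
  m1 <- specimen_morphometrics(shifted)
  expect_equal(m1$plane_z, m0$plane_z + 12.3, tolerance = 1e-9)
  for (col in c("width", "depth", "perimeter", "area"))
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9)
})
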