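test_that("tri_mesh rejects malformed input", {
  expect_error(tri_mesh(matrix(1, 2, 2), matrix(1L, 1, 3)), "n x 3")
  expect_error(tri_mesh(matrix(1, 3, 3), matrix(c(1L, 2L, 5L), 1, 3)),
               "out of range")
  expect_error(tri_mesh(matrix(c(1, NA, 1), 1, 3), matrix(integer(0), 0, 3)),
               "non-finite")
})

test_that("validate_mesh reports watertightness, orientation, components", {
  s <- icosphere(1, 2)
  rep <- validate_mesh(s)
  expect_true(rep$watertight)
  expect_true(rep$oriented)
  expect_identical(rep$n_components, 1L)
  expect_identical(rep$n_degenerate_faces, 0L)

  holed <- tri_mesh(s$vertices, s$faces[-1, , drop = FALSE])
  expect_false(validate_mesh(holed)$watertight)

  two <- tri_mesh(rbind(s$vertices, sweep(s$vertices, 2, c(5, 0, 0), `-`)),
                  rbind(s$faces, s$faces + nrow(s$vertices)))
  expect_identical(validate_mesh(two)$n_components, 2L)
  expect_error(assert_pipeline_mesh <- radiusSSM:::assert_pipeline_mesh(two),
               "components=2")
})

test_that("area and volume converge to sphere closed forms", {
  s <- icosphere(10, 4)
  expect_equal(mesh_area(s), 4 * pi * 100, tolerance = 0.005)
  expect_equal(mesh_volume(s), 4 / 3 * pi * 1000, tolerance = 0.005)
  expect_equal(mesh_volume(unit_cube()), 1, tolerance = 1e-12)
  expect_equal(mesh_area(unit_cube()), 6, tolerance = 1e-12)
})

test_that("mirroring is an involution that preserves orientation", {
  s <- icosphere(2, 2)
  m <- mirror_mesh(mirror_mesh(s))
  expect_equal(m$vertices, s$vertices)
  expect_equal(m$faces, s$faces)
  expect_true(validate_mesh(mirror_mesh(s))$oriented)
  expect_equal(mesh_volume(mirror_mesh(s)), mesh_volume(s))
})
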