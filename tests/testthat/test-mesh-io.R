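test_that("PLY, STL and OBJ round-trip a tetrahedron", {
  tet <- unit_tetrahedron()
  # perturb coordinates so precision is exercised
  tet$vertices <- tet$vertices + 1 / 3
  for (fmt in c("ply", "stl", "obj")) {
    for (binary in c(TRUE, FALSE)) {
      if (fmt == "obj" && binary) next
      path <- tempfile(fileext = paste0(".", fmt))
      write_mesh(tet, path, binary = binary)
      back <- read_mesh(path)
      # STL re-derives connectivity from coordinates, so compare as
      # vertex sets + volume instead of raw ordering
      expect_equal(sort(as.vector(back$vertices)),
                   sort(as.vector(tet$vertices)), tolerance = 1e-6)
      expect_equal(mesh_volume(back), mesh_volume(tet), tolerance = 1e-6)
      expect_identical(nrow(back$faces), nrow(tet$faces))
      unlink(path)
    }
  }
})

test_that("PLY preserves connectivity and double precision exactly", {
  tet <- unit_tetrahedron()
  tet$vertices <- tet$vertices * pi
  path <- tempfile(fileext = ".ply")
  write_mesh(tet, path, binary = TRUE)
  back <- read_mesh(path)
  expect_identical(back$faces, tet$faces)
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-15)
  unlink(path)
})

test_that("corrupt or unknown inputs fail with descriptive errors", {
  empty <- tempfile(fileext = ".ply")
  file.create(empty)
  expect_error(read_mesh(empty), "empty")
  expect_error(read_mesh(tempfile(fileext = ".xyz")), "does not exist")
  bad <- tempfile(fileext = ".xyz")
  writeLines("x", bad)
  expect_error(read_mesh(bad), "unknown mesh format")
  notply <- tempfile(fileext = ".ply")
  writeLines(c("hello", "world"), notply)
  expect_error(read_mesh(notply), "magic")
})

test_that("PLY quads are fan-triangulated on read", {
  path <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), path)
  m <- read_mesh(path)
  expect_identical(nrow(m$faces), 2L)
  expect_equal(mesh_area(m), 1)
  unlink(path)
})
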