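test_that("rigid transforms compose, invert and serialize", {
  set.seed(1)
  a <- rigid_transform(random_rotation(), rnorm(3))
  b <- rigid_transform(random_rotation(), rnorm(3))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(compose_transform(a, b), p),
               apply_transform(a, apply_transform(b, p)))
  ident <- compose_transform(a, invert_transform(a))
  expect_equal(ident$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-12)
  path <- tempfile(fileext = ".json")
  write_transform_json(a, path)
  back <- read_transform_json(path)
  expect_equal(back$rotation, a$rotation, tolerance = 1e-12)
  expect_equal(back$translation, a$translation, tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  unlink(path)
})

test_that("ICP recovers a known rigid motion from an identity start", {
  b <- generate_bone(bone_params(), resolution = 1.5)$mesh
  truth <- rigid_transform(rotation_z(10), c(5, -3, 2))
  src <- transform_mesh(b, invert_transform(truth))
  reg <- rigid_icp(src, b)
  err <- compose_transform(reg$transform, invert_transform(truth))
  expect_lt(norm(err$rotation - diag(3), "F"), 1e-6)
  expect_lt(sqrt(sum(err$translation^2)), 1e-6)
  # rotation error in degrees
  ang <- acos(pmin(1, (sum(diag(err$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.01)
  expect_true(all(diff(reg$residuals) <= 1e-9))
})

test_that("ICP on identical inputs returns the identity", {
  b <- generate_bone(bone_params(), resolution = 2)$mesh
  reg <- rigid_icp(b, b, max_iter = 10)
  expect_lt(reg$rms, 1e-9)
  expect_lt(norm(reg$transform$rotation - diag(3), "F"), 1e-9)
  expect_error(rigid_icp(matrix(c(1, NaN, 1), 1, 3), b), "non-finite")
})

test_that("GPA collapses rigidly perturbed copies of one shape", {
  set.seed(7)
  shp <- matrix(rnorm(60), 20, 3)
  shapes <- lapply(1:5, function(i)
    shp %*% t(random_rotation()) + rep(1, 20) %o% rnorm(3, sd = 5))
  g <- generalized_procrustes(shapes)
  expect_lt(max(g$residuals), 1e-9)
  # the mean equals the shape up to a rigid motion
  k <- radiusSSM:::kabsch(sweep(shp, 2, colMeans(shp)), g$mean)
  moved <- sweep(shp, 2, colMeans(shp)) %*% t(k$rotation)
  expect_equal(moved, g$mean, tolerance = 1e-7)
})

test_that("GPA is order-invariant and preserves centroid size", {
  set.seed(8)
  shapes <- lapply(1:4, function(i) matrix(rnorm(45, sd = 3), 15, 3))
  g1 <- generalized_procrustes(shapes)
  g2 <- generalized_procrustes(shapes[c(3, 1, 4, 2)])
  k <- radiusSSM:::kabsch(g2$mean, g1$mean)
  expect_equal(g2$mean %*% t(k$rotation), g1$mean, tolerance = 1e-7)
  sizes_in <- vapply(shapes, centroid_size, 0)
  sizes_out <- vapply(g1$aligned, centroid_size, 0)
  expect_equal(sizes_out, sizes_in, tolerance = 1e-12)
  expect_error(generalized_procrustes(list(shapes[[1]])), "at least 2")
  expect_error(generalized_procrustes(list(shapes[[1]],
                                           matrix(0, 3, 3))),
               "mismatched")
})

test_that("two-shape GPA gives the midpoint mean and half-distance residuals", {
  set.seed(9)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.1), 10, 3)
  g <- generalized_procrustes(list(a, b))
  aligned_dist <- sqrt(mean(rowSums((g$aligned[[1]] - g$aligned[[2]])^2)))
  expect_equal(g$mean, (g$aligned[[1]] + g$aligned[[2]]) / 2,
               tolerance = 1e-9)
  expect_equal(unname(g$residuals), rep(aligned_dist / 2, 2),
               tolerance = 1e-9)
})
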