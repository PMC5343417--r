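test_that("template projection is the identity on the template's own mesh", {
  b <- generate_bone(bone_params(), resolution = 2)$mesh
  template <- make_template(b, n = 150, seed = 3)
  out <- correspond_to_template(template, b)
  expect_equal(out$points, template$points, tolerance = 1e-9)
})

test_that("projection onto a scaled sphere is radial", {
  s1 <- icosphere(1, 3)
  s2 <- tri_mesh(s1$vertices * 2, s1$faces)
  template <- make_template(s1, n = 80, seed = 1)
  out <- correspond_to_template(template, s2, guard = 10)
  norms <- sqrt(rowSums(out$points^2))
  # faceted sphere: points lie on chords, slightly inside radius 2
  sagitta <- 2 * (1 - cos(0.5 * median(edge_lengths(s2)) / 2))
  expect_true(all(norms <= 2 + 1e-9))
  expect_true(all(norms >= 2 - 2 * sagitta))
  # direction preserved
  dirs <- out$points / norms
  t_dirs <- template$points / sqrt(rowSums(template$points^2))
  expect_equal(dirs, t_dirs, tolerance = 0.05)
})

test_that("projected points lie exactly on the target surface", {
  b <- generate_bone(bone_params(global_scale = 1.05), resolution = 2)$mesh
  ref <- generate_bone(bone_params(), resolution = 2)$mesh
  template <- make_template(ref, n = 25, seed = 2)
  out <- correspond_to_template(template, b, guard = 40)
  pr <- closest_point_on_mesh(out$points, b)
  # already-projected points are their own projection
  expect_lt(max(pr$distance), 1e-9)
  grid <- 12L
  max_edge <- max(edge_lengths(b))
  for (i in seq_len(nrow(out$points))) {
    # independent brute-force oracle, accurate to its sampling grid
    expect_lt(oracle_point_to_mesh(out$points[i, ], b, grid),
              max_edge / grid)
    # exact check: the point satisfies the carrying triangle's equations
    tri <- b$vertices[b$faces[pr$face[i], ], ]
    e1 <- tri[2, ] - tri[1, ]
    e2 <- tri[3, ] - tri[1, ]
    rhs <- out$points[i, ] - tri[1, ]
    uv <- solve(rbind(c(sum(e1 * e1), sum(e1 * e2)),
                      c(sum(e1 * e2), sum(e2 * e2))),
                c(sum(rhs * e1), sum(rhs * e2)))
    in_plane <- rhs - uv[1] * e1 - uv[2] * e2
    expect_lt(sqrt(sum(in_plane^2)), 1e-9)
    expect_true(all(uv >= -1e-9) && sum(uv) <= 1 + 1e-9)
  }
})

test_that("correspondence is equivariant under rigid motion of the target", {
  set.seed(4)
  b <- generate_bone(bone_params(), resolution = 2.5)$mesh
  ref <- generate_bone(bone_params(global_scale = 0.97),
                       resolution = 2.5)$mesh
  template <- make_template(ref, n = 100, seed = 5)
  base <- correspond_to_template(template, b, guard = 40)
  mot <- rigid_transform(random_rotation(), rnorm(3, sd = 10))
  moved <- transform_mesh(b, mot)
  # moving the target and registering it back must reproduce the output
  out <- correspond_to_template(template, moved,
                                transform = invert_transform(mot),
                                guard = 40)
  # equality up to projection ties: where the closest point is not unique
  # (e.g. the symmetric volar face), either representative is valid, but
  # the projection distance must agree exactly
  dev <- sqrt(rowSums((out$points - base$points)^2))
  d_base <- sqrt(rowSums((template$points - base$points)^2))
  d_out <- sqrt(rowSums((template$points - out$points)^2))
  expect_true(all(dev < 1e-6 | abs(d_out - d_base) < 1e-9))
  expect_lt(mean(dev > 1e-6), 0.05)
})

test_that("gross misregistration trips the projection guard", {
  b <- generate_bone(bone_params(), resolution = 2.5)$mesh
  far <- transform_mesh(b, rigid_transform(diag(3), c(100, 0, 0)))
  template <- make_template(b, n = 50, seed = 1)
  expect_error(correspond_to_template(template, far), "misregistered")
})

test_that("farthest-point template is deterministic and well spread", {
  b <- generate_bone(bone_params(), resolution = 1.5)$mesh
  t1 <- make_template(b, n = 200, seed = 9)
  t2 <- make_template(b, n = 200, seed = 9)
  expect_identical(t1$points, t2$points)
  # spread: nearest-neighbour distances should not collapse
  d <- as.matrix(dist(t1$points))
  diag(d) <- Inf
  expect_gt(min(apply(d, 1, min)), 0.5 * median(edge_lengths(b)))
})
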