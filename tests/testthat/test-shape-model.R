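planted_shapes <- function(n = 200, n_landmarks = 40, sds = c(3, 1),
                           seed = 11) {
  set.seed(seed)
  d <- 3 * n_landmarks
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  v <- rnorm(d); v <- v - sum(u * v) * u; v <- v / sqrt(sum(v^2))
  mu <- rnorm(d, sd = 5)
  shapes <- lapply(seq_len(n), function(i) {
    x <- mu + rnorm(1, 0, sds[1]) * u + rnorm(1, 0, sds[2]) * v
    matrix(x, ncol = 3, byrow = TRUE)
  })
  list(shapes = shapes, u = u, v = v, mu = mu)
}

test_that("the PDM recovers a planted two-factor spectrum", {
  pl <- planted_shapes(200, 40, c(3, 1))
  m <- pdm(pl$shapes)
  expect_equal(m$eigenvalues[1], 9, tolerance = 0.15)
  expect_equal(m$eigenvalues[2], 1, tolerance = 0.15)
  expect_lt(max(m$eigenvalues[-(1:2)]), 1e-9)
  expect_equal(m$mean, pl$mu, tolerance = 0.5)
  # modes span the planted plane
  expect_equal(abs(sum(m$modes[, 1] * pl$u)), 1, tolerance = 0.05)
  expect_equal(abs(sum(m$modes[, 2] * pl$v)), 1, tolerance = 0.05)
})

test_that("model invariants: orthonormal modes, variance conservation", {
  pl <- planted_shapes(30, 25, c(2, 0.5), seed = 3)
  m <- pdm(pl$shapes)
  expect_equal(crossprod(m$modes), diag(ncol(m$modes)), tolerance = 1e-9)
  expect_lte(length(m$eigenvalues), m$n_samples - 1)
  x <- t(vapply(pl$shapes, function(s) as.vector(t(s)),
                numeric(75)))
  total_var <- sum(apply(x, 2, var))
  expect_equal(sum(m$eigenvalues), total_var, tolerance = 1e-6)
})

test_that("identical shapes give a zero-variance model", {
  s <- matrix(rnorm(30), 10, 3)
  m <- pdm(list(s, s, s))
  expect_lt(sum(m$eigenvalues), 1e-18)
  expect_equal(m$mean, as.vector(t(s)))
  expect_identical(num_modes(m), 0L)
})

test_that("num_modes applies the inclusive threshold rule", {
  fake <- function(ev) structure(list(eigenvalues = ev), class = "pdm")
  expect_identical(num_modes(fake(c(9, 1)), 0.95), 2L)
  expect_identical(num_modes(fake(c(19, 1)), 0.95), 1L)
  expect_identical(num_modes(fake(c(3, 2, 1, 0, 0)), 1.0), 3L)
  # non-decreasing in the threshold
  ev <- c(5, 3, 1.5, 0.4, 0.1)
  counts <- vapply(seq(0.05, 1, by = 0.05), function(t)
    num_modes(fake(ev), t), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("projection and synthesis are exact inverses on training shapes", {
  pl <- planted_shapes(20, 15, c(2, 1), seed = 5)
  m <- pdm(pl$shapes)
  x <- pl$shapes[[7]]
  co <- project_shape(m, x)
  back <- synthesize_shape(m, co)
  expect_equal(unname(back$points), unname(x), tolerance = 1e-6)
  expect_equal(project_shape(m, matrix(m$mean, ncol = 3, byrow = TRUE)),
               rep(0, ncol(m$modes)), tolerance = 1e-9)
  dev <- mode_deviation(m, 1, 3)
  expect_equal(sqrt(sum((as.vector(t(dev$points)) - m$mean)^2)),
               3 * sqrt(m$eigenvalues[1]), tolerance = 1e-9)
  expect_error(mode_deviation(m, 50, 1), "out of range")
  expect_error(project_shape(m, x, n_modes = 100), "out of range")
})

test_that("higher left-side latent variance needs more modes than right", {
  cfg <- population_config(n_per_group = 100, side_variance_ratio = 3,
                           seed = 5)
  pars <- sample_population(cfg, meshes = FALSE)
  sides <- substr(names(pars), 2, 2)
  set.seed(99)
  shapes <- lapply(pars, function(p) {
    s <- sample_surface_points(p, n_theta = 20, n_z = 16)
    s$points <- s$points + rnorm(length(s$points), 0, cfg$vertex_noise_sd)
    s
  })
  mL <- pdm(generalized_procrustes(shapes[sides == "L"])$aligned)
  mR <- pdm(generalized_procrustes(shapes[sides == "R"])$aligned)
  expect_gt(num_modes(mL), num_modes(mR))
})

test_that("a PDM survives a JSON round-trip", {
  pl <- planted_shapes(10, 8, c(2, 1), seed = 13)
  m <- pdm(pl$shapes)
  path <- tempfile(fileext = ".json")
  write_pdm_json(m, path)
  back <- read_pdm_json(path)
  expect_equal(back$mean, m$mean, tolerance = 1e-12)
  expect_equal(back$eigenvalues, m$eigenvalues, tolerance = 1e-12)
  expect_equal(back$modes, unname(m$modes), tolerance = 1e-12)
  unlink(path)
})
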