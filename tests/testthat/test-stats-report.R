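fake_morpho <- function(widths, plane = "distal", gender = "F", side = "L") {
  data.frame(id = sprintf("s%d", seq_along(widths)), gender = gender,
             side = side, plane = plane, width = widths,
             depth = widths * 0.7, perimeter = widths * 2.8,
             area = widths^2 * 0.55, plane_z = 0)
}

test_that("group descriptives are exact sample statistics", {
  d <- group_descriptives(fake_morpho(c(2, 4)), by = "plane")
  w <- d[d$parameter == "width", ]
  expect_equal(w$mean, 3)
  expect_equal(w$sd, sqrt(2))
  expect_equal(w$min, 2)
  expect_equal(w$max, 4)
  expect_identical(w$n, 2L)
  s1 <- group_descriptives(fake_morpho(5), by = "plane")
  expect_identical(s1$n[1], 1L)
  expect_equal(s1$sd[1], 0)
})

test_that("the Lilliefors normality check separates normal from skewed", {
  set.seed(101)
  norm_draw <- rnorm(1000)
  r <- normality_check(norm_draw)
  expect_gt(r$p, 0.05)
  expect_lt(normality_check(rexp(1000))$p, 0.001)
  # statistic is invariant to affine rescaling
  expect_equal(normality_check(3 + 5 * norm_draw)$statistic, r$statistic,
               tolerance = 1e-12)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2, 3)), "at least 4")
})

test_that("the pooled t-test matches the closed form on a tiny example", {
  r <- compare_groups(c(1, 2, 3, 4, 5, 6),
                      factor(rep(c("a", "b"), each = 3)))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131, tolerance = 1e-3)
  expect_false(r$significant)   # 0.021 > 0.0125
  expect_equal(r$direction, -1)
  same <- compare_groups(rep(1, 6), factor(rep(c("a", "b"), each = 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("gender is detected and side is not on planted populations", {
  set.seed(55)
  n <- 60
  base <- rnorm(n, 29, 2.1)
  m <- rbind(
    fake_morpho(base, gender = rep(c("F", "M"), each = n / 2),
                side = rep(c("L", "R"), n / 2)))
  m[m$gender == "M", c("width", "depth", "perimeter")] <-
    m[m$gender == "M", c("width", "depth", "perimeter")] * 33 / 29
  m[m$gender == "M", "area"] <- m[m$gender == "M", "area"] * (33 / 29)^2
  g <- compare_gender_side(m, "gender")
  expect_true(all(g$significant))
  expect_true(all(g$p <= 0.001))
  s <- compare_gender_side(m, "side")
  expect_true(all(!s$significant))
})

test_that("across-plane ANOVA with Bonferroni post hoc behaves", {
  set.seed(66)
  vals <- rnorm(30, 10, 1)
  same <- rbind(fake_morpho(vals, "distal"), fake_morpho(vals, "middle"),
                fake_morpho(vals, "proximal"))
  r0 <- compare_planes_anova(same, "width")
  expect_lt(r0$f, 1e-9)
  expect_gt(r0$p, 0.999)
  expect_equal(r0$posthoc$p_adjusted,
               pmin(1, 3 * r0$posthoc$p_raw))

  tapered <- rbind(fake_morpho(rnorm(30, 29, 1), "distal"),
                   fake_morpho(rnorm(30, 28.2, 1), "middle"),
                   fake_morpho(rnorm(30, 26.3, 1), "proximal"))
  r1 <- compare_planes_anova(tapered, "width")
  expect_lt(r1$p, 0.001)
  expect_true(all(r1$posthoc$p_adjusted < 0.0125))
  expect_error(compare_planes_anova(fake_morpho(vals, "distal"), "width"),
               "all three planes")
})

test_that("the t-test holds its nominal type-I error under the null", {
  set.seed(77)
  reps <- 5000
  alpha <- 0.05
  hits <- 0L
  for (i in seq_len(reps)) {
    r <- compare_groups(rnorm(16), factor(rep(c("a", "b"), each = 8)),
                        alpha = alpha)
    hits <- hits + (r$p < alpha)
  }
  rate <- hits / reps
  band <- 3 * sqrt(alpha * (1 - alpha) / reps)
  expect_gt(rate, alpha - band)
  expect_lt(rate, alpha + band)
})

test_that("the full report bundles descriptives, tests and ANOVAs", {
  set.seed(88)
  m <- NULL
  for (g in c("F", "M")) for (pl in c("distal", "middle", "proximal")) {
    scale <- ifelse(g == "M", 33 / 29, 1) *
      c(distal = 1, middle = 0.97, proximal = 0.91)[[pl]]
    m <- rbind(m, fake_morpho(rnorm(20, 29 * scale, 1.5), pl, g,
                              side = rep(c("L", "R"), 10)))
  }
  rep <- stats_report(m)
  expect_s3_class(rep, "stats_report")
  expect_identical(nrow(rep$gender), 12L)
  expect_true(all(rep$gender$significant))
  expect_equal(rep$alpha, 0.0125)
  expect_identical(length(rep$planes), 8L)
})
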