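test_that("well-separated classes are classified perfectly", {
  rec <- make_records(10, side_sep = 10, gender_sep = 10, noise = 1,
                      seed = 2)
  for (lab in c("side", "gender")) {
    a <- loocv_random_forest(rec, lab, n_iterations = 5, seed = 7)
    expect_equal(a$median, 1.0)
    expect_true(all(a$per_iteration >= 0 & a$per_iteration <= 1))
  }
})

test_that("pure-noise features score at chance level", {
  rec <- make_records(10, side_sep = 0, gender_sep = 0, noise = 1, seed = 3)
  a <- loocv_random_forest(rec, "side", n_iterations = 7, seed = 11)
  # central 99% binomial band around 0.5 for n = 40
  band <- 2.58 * sqrt(0.25 / 40)
  expect_gt(a$median, 0.5 - band - 0.1)
  expect_lt(a$median, 0.5 + band)
})

test_that("planted accuracy strictly beats the permuted-label accuracy", {
  rec <- make_records(10, side_sep = 4, gender_sep = 0, noise = 1, seed = 4)
  a1 <- loocv_random_forest(rec, "side", n_iterations = 5, seed = 5)
  set.seed(6)
  perm <- rec
  perm$side <- sample(perm$side)
  a0 <- loocv_random_forest(perm, "side", n_iterations = 5, seed = 5)
  expect_gt(a1$median, a0$median)
})

test_that("classification is deterministic under a seed", {
  rec <- make_records(6, side_sep = 1, gender_sep = 1, seed = 8)
  a1 <- loocv_random_forest(rec, "gender", n_iterations = 4, seed = 21)
  a2 <- loocv_random_forest(rec, "gender", n_iterations = 4, seed = 21)
  expect_identical(a1$per_iteration, a2$per_iteration)
  expect_identical(a1$confusion, a2$confusion)
  s1 <- stepwise_side_then_gender(rec, n_iterations = 3, seed = 22)
  s2 <- stepwise_side_then_gender(rec, n_iterations = 3, seed = 22)
  expect_identical(s1$per_iteration, s2$per_iteration)
})

test_that("step-wise side-then-gender recovers disjoint planted features", {
  rec <- make_records(10, side_sep = 10, gender_sep = 10, noise = 1,
                      seed = 9)
  s <- stepwise_side_then_gender(rec, n_iterations = 5, seed = 13)
  expect_equal(s$median, 1.0)
})

test_that("step-wise accuracy on noise matches two independent coin flips", {
  rec <- make_records(10, side_sep = 0, gender_sep = 0, noise = 1, seed = 10)
  s <- stepwise_side_then_gender(rec, n_iterations = 7, seed = 14)
  band <- 2.58 * sqrt(0.25 * 0.75 / 40)
  expect_gt(s$median, 0.25 - band - 0.1)
  expect_lt(s$median, 0.25 + band + 0.05)
  # combined success is never above the side accuracy
  a_side <- loocv_random_forest(rec, "side", n_iterations = 7, seed = 14)
  expect_lte(s$median, a_side$median + 0.05)
})

test_that("single-class inputs are rejected", {
  rec <- make_records(4, seed = 15)
  rec$side <- factor(rep("L", length(rec$id)), levels = c("L", "R"))
  expect_error(loocv_random_forest(rec, "side"), "two classes")
})

test_that("morphometrics can serve as the feature source", {
  cfg <- population_config(n_per_group = 4, seed = 31, mesh_resolution = 2.5)
  pop <- sample_population(cfg)
  morpho <- do.call(rbind, lapply(pop, function(b)
    specimen_morphometrics(b$mesh, id = b$id, gender = b$gender,
                           side = b$side)))
  rec <- specimen_records(vapply(pop, `[[`, "", "id"),
                          vapply(pop, `[[`, "", "gender"),
                          vapply(pop, `[[`, "", "side"),
                          morphometrics = morpho)
  a <- loocv_random_forest(rec, "gender", n_iterations = 3, seed = 2,
                           features = "morphometrics")
  expect_s3_class(a, "accuracy_summary")
  expect_identical(a$n_iterations, 3L)
  # male sizes are planted much larger, so this should beat chance clearly
  expect_gt(a$median, 0.7)
})
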