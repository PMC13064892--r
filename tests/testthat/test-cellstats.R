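cells_df <- function(values, condition, replicate = 1) {
  data.frame(mean_target_adjusted = values, condition = condition,
             replicate = replicate, stringsAsFactors = FALSE)
}

test_that("normalization divides by the reference mean", {
  d <- cells_df(c(2, 4, 1, 3), c("ref", "ref", "test", "test"))
  n <- normalize_to_reference(d, "ref")
  expect_equal(n$value_norm, c(2 / 3, 4 / 3, 1 / 3, 1))
  expect_equal(mean(n$value_norm[n$condition == "ref"]), 1)
})

test_that("normalization is idempotent and errors name the replicate", {
  d <- cells_df(c(2, 4, 1, 3), c("ref", "ref", "test", "test"))
  n1 <- normalize_to_reference(d, "ref")
  n2 <- normalize_to_reference(n1, "ref", value_col = "value_norm")
  expect_equal(n2$value_norm, n1$value_norm)
  bad <- cells_df(c(1, 2), c("test", "test"), replicate = c(1, 2))
  bad <- rbind(bad, cells_df(3, "ref", 1))
  expect_error(normalize_to_reference(bad, "ref"), "replicate '2'")
})

test_that("per-replicate mode forces every replicate's reference to 1", {
  d <- rbind(cells_df(c(10, 20, 5), c("ref", "ref", "test"), 1),
             cells_df(c(100, 200, 50), c("ref", "ref", "test"), 2))
  n <- normalize_to_reference(d, "ref", mode = "per_replicate")
  rm <- replicate_means(n)
  ref_rows <- rm[rm$condition == "ref", ]
  expect_equal(ref_rows$mean_value, c(1, 1))
  # the replicate scale difference cancels: test means identical
  test_rows <- rm[rm$condition == "test", ]
  expect_equal(test_rows$mean_value[1], test_rows$mean_value[2])
})

test_that("replicate means drop missing cells and empty cells warn", {
  d <- cells_df(c(1, 2, 3, NA), rep("a", 4))
  d$value_norm <- d$mean_target_adjusted
  rm <- replicate_means(d)
  expect_equal(rm$mean_value, 2)
  expect_equal(rm$n_cells, 3)
  d2 <- rbind(cells_df(c(1, 2, 3, NA), rep("a", 4)),
              cells_df(NA_real_, "b"))
  d2$value_norm <- d2$mean_target_adjusted
  expect_warning(replicate_means(d2), "empty")
})

test_that("grand mean of replicate means equals the pooled mean for
           equal-sized replicates", {
  set.seed(5)
  d <- cells_df(rnorm(60), "a", rep(1:3, each = 20))
  d$value_norm <- d$mean_target_adjusted
  rm <- replicate_means(d)
  expect_equal(mean(rm$mean_value), mean(d$value_norm))
})

test_that("Welch's t test reproduces the closed-form worked example", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -sqrt(3 / 2), tolerance = 1e-10)
  expect_lt(abs(w$t - (-1.2247)), 1e-4)
  expect_equal(w$df, 4, tolerance = 1e-10)
  expect_equal(w$p, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-10)
  expect_lt(abs(w$p - 0.2879), 1e-4)
})

test_that("Welch's t test handles degenerate and symmetric cases", {
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welch_t_test(c(0, 0), c(1, 1)), "constant")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # order swap: p invariant, t changes sign
  a <- c(1.2, 3.4, 2.2); b <- c(4.1, 5.0, 6.3)
  expect_equal(welch_t_test(a, b)$p, welch_t_test(b, a)$p)
  expect_equal(welch_t_test(a, b)$t, -welch_t_test(b, a)$t)
})

test_that("Welch equals the pooled t test for equal variances and sizes", {
  set.seed(8)
  a <- rnorm(5); b <- rnorm(5)
  w <- welch_t_test(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_lte(w$df, unname(pooled$parameter))
})

test_that("pairwise comparisons flag untestable pairs", {
  rm <- data.frame(condition = c("a", "a", "b"), replicate = c(1, 2, 1),
                   mean_value = c(1, 1.1, 2), n_cells = 10)
  cmp <- pairwise_welch(rm)
  expect_true(cmp$test_missing)
  expect_true(is.na(cmp$p))
})

test_that("regression recovers exact linear relations and expected R2", {
  d <- data.frame(mean_nuclear_edu = 0:9,
                  mean_target_adjusted = 2 * (0:9) + 1, replicate = 1)
  r <- intensity_edu_regression(d, normalize_within_replicate = FALSE)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # constant response: error
  d2 <- d; d2$mean_target_adjusted <- 5
  expect_error(intensity_edu_regression(d2,
                                        normalize_within_replicate = FALSE),
               "variance")
  # noisy case: R2 near var(x) / (var(x) + sigma^2)
  set.seed(3)
  x <- rnorm(4000, 0, 2)
  y <- x + rnorm(4000, 0, 1)
  d3 <- data.frame(mean_nuclear_edu = x, mean_target_adjusted = y,
                   replicate = 1)
  r3 <- intensity_edu_regression(d3, normalize_within_replicate = FALSE)
  expect_equal(r3$r_squared, 4 / 5, tolerance = 0.03)
  # R2 invariant to affine rescaling
  d4 <- d3
  d4$mean_nuclear_edu <- 3 * d4$mean_nuclear_edu + 10
  d4$mean_target_adjusted <- -2 * d4$mean_target_adjusted + 1
  r4 <- intensity_edu_regression(d4, normalize_within_replicate = FALSE)
  expect_equal(r4$r_squared, r3$r_squared, tolerance = 1e-12)
})
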