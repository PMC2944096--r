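test_that("standardize maps the observed range onto [0, range_width]", {
  expect_equal(standardize(c(2, 4, 10)), c(0, 2.5, 10))
  x <- c(-3, 0, 7)
  s <- standardize(x)
  expect_equal(s[x == min(x)], 0)
  expect_equal(s[x == max(x)], 10)
  expect_equal(standardize(c(2, 4, 10), range_width = 100)[2], 25)
})

test_that("standardize rejects degenerate and out-of-range inputs", {
  expect_error(standardize(rep(3, 5)), "degenerate")
  expect_error(standardize(c(1, 5), min_value = 2, max_value = 4), "outside")
  expect_equal(standardize(c(1, 5), min_value = 2, max_value = 4, clamp = TRUE),
               c(0, 10))
})

test_that("standardize is affine: order-preserving and idempotent", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(30, sd = runif(1, 0.5, 50))
    s <- standardize(x)
    expect_equal(order(s), order(x))
    # re-standardizing with its own range is the identity
    expect_equal(standardize(s), s, tolerance = 1e-12)
  }
})

test_that("population weighting pulls aggregates toward populous children", {
  expect_equal(population_weighted_mean(7.3, 1200), 7.3)
  expect_equal(population_weighted_mean(c(2, 4, 6), rep(500, 3)), 4)
  expect_equal(population_weighted_mean(c(0, 10), c(1000, 3000)), 7.5)
  expect_error(population_weighted_mean(c(1, 2), c(0, 0)), "zero")
  expect_error(population_weighted_mean(c(1, 2), 1), "length")
})

test_that("orientation reflects negative-polarity indicators on the scale", {
  expect_equal(orient_indicator(3.2, +1), 3.2)
  expect_equal(orient_indicator(0, -1), 10)
  expect_equal(orient_indicator(2.5, -1), 7.5)
  x <- runif(50, 0, 10)
  expect_equal(orient_indicator(orient_indicator(x, -1), -1), x)
  expect_error(orient_indicator(11, -1), "outside")
})

test_that("composite index is a convex weighted mean of its columns", {
  expect_equal(composite_index(cbind(4, 8), c(0.25, 0.75)), 7)
  # all columns equal -> composite equals that value for any weights
  m <- matrix(6.2, nrow = 4, ncol = 3)
  expect_equal(composite_index(m, c(1, 2, 5)), rep(6.2, 4))
  # degenerate weighting selects a single column
  m2 <- cbind(a = c(1, 2), b = c(9, 8), c = c(5, 5))
  expect_equal(composite_index(m2, c(1, 0, 0)), c(1, 2))
  # invariance to positive rescaling of the weights
  w <- c(0.2, 0.5, 0.3)
  expect_equal(composite_index(m2, w), composite_index(m2, w * 17))
  m2[2, 1] <- NA
  expect_error(composite_index(m2, w), "missing indicator value")
  expect_error(composite_index(cbind(1, 2), c(0, 0)), "zero")
})

test_that("jenks breaks separate well-separated clusters", {
  expect_identical(jenks_breaks(c(4, 9, 2), 1), numeric(0))
  expect_equal(jenks_breaks(c(1, 2, 10, 11), 2), 2)
  b <- jenks_breaks(c(1, 2, 3, 10, 11, 12, 30, 31, 32), 3)
  expect_equal(classify_values(c(1, 2, 3, 10, 11, 12, 30, 31, 32), b),
               rep(1:3, each = 3))
  expect_error(jenks_breaks(c(1, 1, 1, 2), 3), "distinct")
})

test_that("jenks equals the exhaustive contiguous-partition optimum", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < k) next
    b <- jenks_breaks(x, k)
    expect_equal(breaks_sse(x, b), brute_jenks_sse(x, k), tolerance = 1e-9)
  }
})

test_that("classification sends boundary values to the lower class", {
  b <- c(2, 5, 9)
  expect_equal(classify_values(c(1, 2, 2.1, 5, 5.1, 9, 42), b),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  expect_equal(classify_values(-3, b), 1L)
  expect_error(classify_values(1, c(5, 2)), "ascending")
})

test_that("the rating grid holds 25 ordered pairs with fixed extremes", {
  r <- all_ratings()
  expect_equal(nrow(r), 25)
  expect_equal(length(unique(r$label)), 25)
  expect_equal(vulnerability_rating(5, 1)$designation, "worst")
  expect_equal(vulnerability_rating(1, 5)$designation, "best")
  expect_true(is.na(vulnerability_rating(3, 3)$designation))
  expect_error(vulnerability_rating(0, 3), "1..5")
  expect_error(vulnerability_rating(2, 6), "1..5")
})
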