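test_that("the cumulative conversion curve matches the hand empirical CDF", {
  vals <- rep(c(1, 10, 100), 4) # >= 10 values, same empirical CDF
  cdf <- build_cdf(vals, grid_size = 201, u_range = c(0, 2))
  a <- function(u) cdf$alpha[which.min(abs(cdf$u_grid - u))]
  expect_equal(a(0), 100 / 3)
  expect_equal(a(1), 200 / 3)
  expect_equal(a(2), 100)
  expect_true(all(diff(cdf$alpha) >= 0))

  # point mass: single step to 100
  pm <- build_cdf(rep(50, 12), grid_size = 11, u_range = c(1, 2))
  expect_true(all(pm$alpha[pm$u_grid >= log10(50)] == 100))
  expect_true(all(pm$alpha[pm$u_grid < log10(50)] == 0))

  # duplicating the dataset leaves alpha unchanged
  set.seed(12)
  v <- rlnorm(40)
  expect_equal(build_cdf(c(v, v), grid_size = 101)$alpha,
               build_cdf(v, grid_size = 101)$alpha)
  expect_error(build_cdf(c(1, 2, 3)), "fewer than 10")
})

test_that("inflexion points sit at the density modes of a bimodal mixture", {
  spec <- scenario_spec(seed = 6)
  g <- generate_mito_population(spec, n_cells = 10000)
  cdf <- find_inflexions(build_cdf(g$values))
  expect_identical(length(cdf$thetas), 2L)
  expect_true(all(abs(cdf$thetas - g$truth$modes_u) < 0.1))
  expect_false(cdf$single_population)

  # unimodal: one theta at the mode
  uni <- 10^rnorm(10000, 2, 0.3)
  c1 <- find_inflexions(build_cdf(uni))
  expect_identical(length(c1$thetas), 1L)
  expect_lt(abs(c1$thetas - 2), 0.1)

  # uniform in u: flat derivative, single-population flag
  set.seed(61)
  flat <- 10^runif(5000, 0, 3)
  c2 <- find_inflexions(build_cdf(flat))
  expect_true(c2$single_population)
  expect_equal(unname(segment_fractions(c2)), c(100, 0, 0))
})

test_that("the derivative integrates back to the full conversion range", {
  set.seed(62)
  cdf <- find_inflexions(build_cdf(10^rnorm(2000, 1.5, 0.4)))
  du <- cdf$u_grid[2] - cdf$u_grid[1]
  expect_equal(sum(cdf$derivative) * du, 100, tolerance = 2)
})

test_that("segment fractions follow the defining equations and sum to 100", {
  vals <- rep(c(1, 10, 100), 4)
  cdf <- build_cdf(vals, grid_size = 50, u_range = c(0, 2))
  fr <- segment_fractions(cdf, theta1 = 0.5, theta2 = 1.5)
  expect_equal(unname(fr), c(100 / 3, 100 / 3, 100 / 3))

  # point mass between the thresholds
  pm <- build_cdf(rep(30, 20), grid_size = 20, u_range = c(0, 3))
  expect_equal(unname(segment_fractions(pm, 1, 2)), c(0, 100, 0))

  expect_error(segment_fractions(cdf, 1.5, 0.5), "theta1 < theta2")

  set.seed(63)
  for (i in 1:20) {
    v <- rlnorm(sample(10:200, 1), rnorm(1), runif(1, 0.2, 1))
    u <- log10(v)
    th <- sort(runif(2, min(u), max(u)))
    fr <- segment_fractions(build_cdf(v), th[1], th[2])
    expect_equal(sum(fr), 100, tolerance = 1e-12)
    expect_true(all(fr >= 0 & fr <= 100))
  }
})

test_that("single-threshold fallback yields a two-segment partition", {
  cdf <- build_cdf(rep(c(1, 10), 6))
  fr <- segment_fractions(cdf, theta1 = 0.5)
  expect_equal(unname(fr[1:2]), c(50, 50))
  expect_true(is.na(fr[3]))
})

test_that("classification agrees with the segment fractions and is ordinally invariant", {
  set.seed(64)
  v <- rlnorm(300, 1, 1)
  cdf <- build_cdf(v)
  th <- as.numeric(stats::quantile(log10(v), c(0.3, 0.8)))
  fr <- segment_fractions(cdf, th[1], th[2])
  cl <- classify_population(v, th[1], th[2])
  expect_equal(unname(cl$percent), unname(fr))
  expect_equal(sum(cl$percent), 100)

  # strictly increasing transform of X with identically transformed thetas
  # preserves every label (cube in linear space = *3 in u)
  cl2 <- classify_population(v^3, 3 * th[1], 3 * th[2])
  expect_identical(cl2$labels, cl$labels)

  # forced case: everything below theta1
  cl3 <- classify_population(v, max(log10(v)) + 1, max(log10(v)) + 2)
  expect_equal(unname(cl3$percent), c(100, 0, 0))
})

test_that("fractions are invariant to vertical scaling of the underlying histogram", {
  # scaling cell counts (duplicating every cell) changes histogram height
  # but no fraction
  set.seed(65)
  v <- rlnorm(200, 1, 0.8)
  th <- c(0.5, 1.5)
  f1 <- segment_fractions(build_cdf(v), th[1], th[2])
  f2 <- segment_fractions(build_cdf(rep(v, 5)), th[1], th[2])
  expect_equal(f1, f2)
})

test_that("redistribution reports signed deltas against the 5-point rule", {
  rd <- redistribution(c(30, 40, 30), c(48, 36, 16))
  expect_equal(unname(rd$deltas), c(18, -4, -14))
  expect_identical(unname(rd$significant), c(TRUE, FALSE, TRUE))
  expect_equal(sum(rd$deltas), 0)

  rd0 <- redistribution(c(20, 30, 50), c(20, 30, 50))
  expect_true(all(rd0$deltas == 0))
  expect_false(any(rd0$significant))

  set.seed(66)
  for (i in 1:10) {
    a <- diff(c(0, sort(runif(2)), 1)) * 100
    b <- diff(c(0, sort(runif(2)), 1)) * 100
    expect_equal(sum(redistribution(a, b)$deltas), 0, tolerance = 1e-9)
  }
  expect_error(redistribution(c(50, 50, 50), c(30, 40, 30)), "sum to 100")
})
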