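test_that("ROI power distributions are normalized squared-amplitude means", {
  coords <- matrix(rnorm(9), 3)
  x <- matrix(0, 3, 10)
  x[2, ] <- 4
  pd <- roi_power(x, c(0, 0.9), coords, fs = 10)
  expect_equal(pd$mass, c(0, 1, 0))

  xc <- matrix(1, 3, 10)
  expect_equal(roi_power(xc, c(0, 0.9), coords, fs = 10)$mass, rep(1 / 3, 3))

  # amplitudes (1, 2) give squared-power masses (0.2, 0.8)
  x2 <- rbind(rep(1, 10), rep(2, 10))
  pd2 <- roi_power(x2, c(0, 0.9), coords[1:2, ], fs = 10)
  expect_equal(pd2$mass, c(0.2, 0.8))
  expect_equal(sum(pd2$mass), 1)

  expect_error(roi_power(matrix(0, 3, 10), c(0, 0.9), coords, fs = 10),
               "undefined")
  expect_error(roi_power(x, c(5, 6), coords, fs = 10), "no samples")
})

test_that("Wasserstein distance matches closed forms", {
  p1 <- make_power_dist(1, matrix(c(0, 0, 0), 1))
  q1 <- make_power_dist(1, matrix(c(10, 0, 0), 1))
  expect_equal(wasserstein(p1, q1), 10, tolerance = 1e-7)
  # equal split 10 mm apart vs midpoint mass: each half moves 5 mm
  p2 <- make_power_dist(c(0.5, 0.5), rbind(c(0, 0, 0), c(10, 0, 0)))
  q2 <- make_power_dist(1, matrix(c(5, 0, 0), 1))
  expect_equal(wasserstein(p2, q2), 5, tolerance = 1e-7)
  expect_lt(wasserstein(p2, p2), 1e-7)
  bad <- p2; bad$mass <- bad$mass * 2
  expect_error(wasserstein(bad, q2), "normalized")
})

test_that("exact solver agrees with an independent dense LP", {
  set.seed(19)
  for (r in 1:10) {
    m <- sample(5:25, 1); n <- sample(5:25, 1)
    a <- runif(m); a <- a / sum(a)
    b <- runif(n); b <- b / sum(b)
    C <- matrix(runif(m * n, 0, 100), m)
    expect_equal(transport_plan(a, b, C)$cost, transport_lp_oracle(a, b, C),
                 tolerance = 1e-6)
  }
})

test_that("transport plans satisfy the marginal constraints", {
  set.seed(23)
  a <- runif(12); a <- a / sum(a)
  b <- runif(7); b <- b / sum(b)
  C <- matrix(runif(84, 0, 50), 12)
  tp <- transport_plan(a, b, C)
  expect_lt(max(abs(rowSums(tp$plan) - a)), 1e-8)
  expect_lt(max(abs(colSums(tp$plan) - b)), 1e-8)
  expect_true(all(tp$plan >= 0))
})

test_that("Wasserstein is a metric with the expected covariances", {
  set.seed(31)
  coords <- matrix(rnorm(60, sd = 40), 20)
  P <- make_power_dist(runif(20), coords)
  Q <- make_power_dist(runif(20), coords)
  R <- make_power_dist(runif(20), coords)
  dpq <- wasserstein(P, Q)
  expect_gte(dpq, 0)
  expect_equal(dpq, wasserstein(Q, P), tolerance = 1e-6)
  expect_lte(dpq, wasserstein(P, R) + wasserstein(R, Q) + 1e-6)

  # translation leaves the distance unchanged; scaling coords scales it
  shift <- function(pd, v) { pd$coords <- sweep(pd$coords, 2, v, "+"); pd }
  expect_equal(wasserstein(shift(P, c(5, -3, 2)), shift(Q, c(5, -3, 2))),
               dpq, tolerance = 1e-6)
  scl <- function(pd, s) { pd$coords <- pd$coords * s; pd }
  expect_equal(wasserstein(scl(P, 2.5), scl(Q, 2.5)), 2.5 * dpq,
               tolerance = 1e-6)
})

test_that("the entropic fast path approximates the exact distance", {
  set.seed(37)
  coords <- matrix(rnorm(45, sd = 30), 15)
  P <- make_power_dist(runif(15), coords)
  Q <- make_power_dist(runif(15), coords)
  exact <- wasserstein(P, Q)
  fast <- wasserstein(P, Q, method = "sinkhorn", epsilon = 0.5)
  expect_lt(abs(fast - exact) / exact, 0.05)
})

test_that("percent reduction follows its definition", {
  # values derived from a published raw-vs-preprocessed pair (6.23, 1.26)
  expect_equal(percent_reduction(6.23, 1.26), 79.77528, tolerance = 1e-5)
  expect_equal(percent_reduction(3.7, 3.7), 0)
  expect_equal(percent_reduction(5, 0), 100)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("paired comparisons match the t closed form and handle ties", {
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)
  res <- compare_conditions(x, y)
  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)) = 2 sqrt(3)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_false(res$degenerate)
  expect_equal(res$p_bonferroni, min(1, res$p))

  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3) - 2)
  expect_true(same$degenerate)
  expect_false(same$significant)
})

test_that("paired test keeps its nominal size under the null", {
  set.seed(41)
  reps <- 800
  rej <- 0L
  for (r in seq_len(reps)) {
    x <- rnorm(12)
    y <- rnorm(12)
    if (compare_conditions(x, y)$significant) rej <- rej + 1L
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rej / reps - 0.05), 3 * se + 0.005)
})
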