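test_that("patch priors are unit-trace, symmetric and localized", {
  hm <- fixture_head(200, seed = 3)
  pr <- build_patches(hm, n_patches = 32, smoothing_mm = 10)
  expect_equal(ncol(pr$patches), 32L)
  q <- pr$patches[, 5]
  # rank-one component qq': trace = ||q||^2 = 1, PSD and symmetric by form
  expect_equal(sum(q^2), 1, tolerance = 1e-9)
  expect_true(all(q >= 0))
  # smoothing -> 0 approaches a single-vertex indicator
  pr0 <- build_patches(hm, n_patches = 16, smoothing_mm = 1e-3)
  expect_equal(max(abs(pr0$patches[, 3])), 1, tolerance = 1e-9)
  expect_equal(Matrix::colSums(pr0$patches > 0), rep(1, 16),
               ignore_attr = TRUE)
  expect_error(build_patches(hm, smoothing_mm = 0), "positive")
  expect_error(build_patches(hm, n_patches = 1000), "more patches")
})

test_that("MSP inversion: zero data, monotone free energy, localization", {
  hm0 <- fixture_head(200, seed = 3)
  red <- reduce_montage(
    forward_project(hm0, matrix(0, 200, 50)), hm0, montage_labels(32))
  z <- invert_msp(eeg_signal(matrix(0, 32, 50) + 0, fs = 100,
                             labels = montage_labels(32)),
                  red$head)
  expect_true(all(z$xhat == 0))

  # noiseless single source at a patch center
  hm <- fixture_head(200, seed = 3)
  pr <- build_patches(hm, n_patches = 64, smoothing_mm = 10)
  src <- pr$centers[10]
  x <- matrix(0, 200, 100)
  x[src, ] <- tone(8, fs = 100, dur = 0.99)
  y <- forward_project(hm, x)
  y$fs <- 100
  red <- reduce_montage(y, hm, montage_labels(32))
  prr <- build_patches(red$head, n_patches = 64, smoothing_mm = 10)
  est <- invert_msp(red$signal, red$head, prr)
  expect_true(all(diff(est$free_energy_trace) >= -1e-10))
  pk <- which.max(rowMeans(est$xhat^2))
  dist_mm <- sqrt(sum((hm$vertex_coords[pk, ] - hm$vertex_coords[src, ])^2))
  expect_lt(dist_mm, 20)
})

test_that("MSP estimates scale with the data", {
  hm <- fixture_head(200, seed = 3)
  x <- matrix(0, 200, 80)
  x[25, ] <- tone(6, fs = 100, dur = 0.79)
  y <- forward_project(hm, x)
  y$fs <- 100
  yn <- add_noise(y, 10, seed = 1)
  red <- reduce_montage(yn, hm, montage_labels(16))
  pr <- build_patches(red$head, n_patches = 64)
  e1 <- invert_msp(red$signal, red$head, pr)
  y3 <- eeg_signal(red$signal$data * 7, fs = red$signal$fs,
                   labels = red$signal$labels)
  e7 <- invert_msp(y3, red$head, pr)
  expect_equal(e7$xhat, 7 * e1$xhat, tolerance = 1e-8)
})

test_that("minimum norm matches its closed forms and a dense oracle", {
  hm <- fixture_head(200, seed = 3)
  y <- forward_project(hm, make_scenario("one", hm, fs = 100, t_end = 1))
  red <- reduce_montage(y, hm, montage_labels(8))

  # lambda -> infinity shrinks the estimate to zero
  big <- invert_mn(red$signal, red$head, regularization = 1e9)
  expect_lt(max(abs(big$xhat)), 1e-6 * max(abs(red$signal$data)))

  # orthonormal lead-field rows with lambda = 0: xhat = M' y exactly
  M <- qr.Q(qr(matrix(rnorm(50 * 8), 50)))[, 1:8]
  toy <- head_model(t(M), matrix(rnorm(150), 50), paste0("e", 1:8),
                    matrix(rnorm(24), 8))
  yt <- eeg_signal(matrix(rnorm(8 * 20), 8), fs = 10, labels = paste0("e", 1:8))
  mn0 <- invert_mn(yt, toy, regularization = 0)
  expect_equal(mn0$xhat, M %*% yt$data, tolerance = 1e-10)

  # random 8 x 50 systems against an explicit normal-equations solve
  set.seed(12)
  for (r in 1:3) {
    Mr <- matrix(rnorm(8 * 50), 8)
    toy <- head_model(Mr, matrix(rnorm(150), 50), paste0("e", 1:8),
                      matrix(rnorm(24), 8))
    yr <- eeg_signal(matrix(rnorm(8 * 10), 8), fs = 10,
                     labels = paste0("e", 1:8))
    lam <- 0.3 * sum(diag(tcrossprod(Mr))) / 8
    oracle <- t(Mr) %*% solve(tcrossprod(Mr) + diag(lam, 8), yr$data)
    got <- invert_mn(yr, toy, regularization = 0.3)
    expect_equal(got$xhat, oracle, tolerance = 1e-8)
  }
  expect_error(invert_mn(yt, toy, regularization = -1), "non-negative")
})
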