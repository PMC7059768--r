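test_that("windowed sinusoid matches a straight-line reimplementation", {
  fs <- 200
  x <- windowed_sinusoid(f = 10, c = 1, sigma = 0.12, fs = fs)
  t <- seq(0, 6, by = 1 / fs)
  oracle <- exp(-0.5 * ((t - 1) / 0.12)^2) * sin(2 * pi * 10 * t)
  expect_lt(max(abs(x - oracle)), 1e-12)

  # value at the window center: sin(2 pi 10 * 1) = 0
  expect_equal(x[t == 1], 0, tolerance = 1e-12)
  # window factor at c +/- sigma is exp(-1/2)
  env <- exp(-0.5 * ((t - 1) / 0.12)^2)
  expect_equal(env[which.min(abs(t - 1.12))], exp(-0.5), tolerance = 1e-3)
  # Gaussian tail at 5 sigma
  expect_lt(env[which.min(abs(t - (1 + 5 * 0.12)))], 4e-6)
  expect_error(windowed_sinusoid(10, 1, fs = 15), "fs > 2")
})

test_that("scenarios place the documented sources", {
  head <- fixture_head(500)
  one <- make_scenario("one", head)
  expect_equal(sum(rowSums(one$x^2) > 0), 1L)
  pk <- which.max(abs(one$x[one$specs$vertex[1], ]))
  expect_lt(abs((pk - 1) / one$fs - 1), 0.05)
  expect_equal(one$specs$f, 10)

  three <- make_scenario("three", head)
  expect_equal(sum(rowSums(three$x^2) > 0), 3L)
  expect_equal(three$specs$f, c(20, 12, 4))
  expect_equal(three$specs$c, c(1, 3, 5))

  five <- make_scenario("five", head)
  expect_equal(sum(rowSums(five$x^2) > 0), 5L)
  expect_equal(five$specs$f, c(20, 15, 10, 6, 2))
  expect_equal(five$specs$c, 1:5)
  for (i in seq_len(5)) {
    env_peak <- which.max(abs(five$x[five$specs$vertex[i], ]))
    expect_lt(abs((env_peak - 1) / five$fs - five$specs$c[i]), 0.1)
  }
  expect_error(make_scenario("seven", head))
})

test_that("forward projection is exact linear algebra", {
  head <- fixture_head(500)
  n <- ncol(head$leadfield)
  T <- 8L
  x1 <- matrix(rnorm(n * T), n)
  x2 <- matrix(rnorm(n * T), n)
  y1 <- forward_project(head, x1)
  y2 <- forward_project(head, x2)
  ylin <- forward_project(head, 2 * x1 - 3 * x2)
  expect_equal(ylin$data, 2 * y1$data - 3 * y2$data)

  xj <- matrix(0, n, T); xj[17, ] <- 1
  expect_equal(unname(forward_project(head, xj)$data),
               matrix(head$leadfield[, 17], nrow(head$leadfield), T))

  toy <- suppressWarnings(
    head_model(diag(4) + 1e-3, matrix(rnorm(12), 4), letters[1:4],
               matrix(rnorm(12), 4)))
  xt <- matrix(rnorm(16), 4)
  expect_equal(unname(forward_project(toy, xt)$data), (diag(4) + 1e-3) %*% xt)
  expect_error(forward_project(head, matrix(0, 3, 4)), "do not match")
})

test_that("noise injection hits the target SNR exactly and reproducibly", {
  head <- fixture_head(500)
  y <- forward_project(head, make_scenario("three", head))
  for (snr in c(10, -5)) {
    yn <- add_noise(y, snr, seed = 5)
    expect_lt(abs(realized_snr(y, yn) - snr), 0.1)
    ratio <- mean((yn$data - y$data)^2) / mean(y$data^2)
    expect_equal(ratio, 10^(-snr / 10), tolerance = 1e-12)
  }
  expect_identical(add_noise(y, 10, seed = 2)$data,
                   add_noise(y, 10, seed = 2)$data)
  expect_false(identical(add_noise(y, 10, seed = 2)$data,
                         add_noise(y, 10, seed = 3)$data))
  zero <- eeg_signal(matrix(0, 2, 10), fs = 10)
  expect_error(add_noise(zero, 10), "undefined")
})

test_that("synthetic head models are deterministic with sane geometry", {
  hm <- synth_headmodel(200, montage_labels(8), seed = 7)
  expect_equal(dim(hm$leadfield), c(8L, 200L))
  expect_true(all(is.finite(hm$leadfield)))
  expect_true(all(rowSums(abs(hm$leadfield)) > 0))
  expect_identical(hm$leadfield,
                   synth_headmodel(200, montage_labels(8), seed = 7)$leadfield)
  expect_false(identical(hm$leadfield,
                         synth_headmodel(200, montage_labels(8),
                                         seed = 8)$leadfield))
  # nearby vertices have more similar lead-field columns than distant ones
  cc <- cor(hm$leadfield)
  dd <- as.matrix(dist(hm$vertex_coords))
  near <- dd > 0 & dd < 15
  far <- dd > 100
  expect_gt(mean(cc[near]), mean(cc[far]) + 0.5)
  expect_error(synth_headmodel(10), "at least 50")
})

test_that("three-shell series reduces to the homogeneous-sphere closed form", {
  vc <- memdeeg:::.fibonacci_sphere(30) * 70
  ec <- ten_ten_positions(montage_labels(8)) * 92
  L <- three_shell_leadfield(vc, ec, radii = c(80, 85, 92),
                             sigmas = c(0.33, 0.33, 0.33), n_terms = 80)
  # independent oracle: V = sum (2l+1) (b/R)^(l-1) P_l / (4 pi sigma),
  # the textbook surface potential of a radial dipole in a single sphere
  b <- sqrt(rowSums(vc^2)) / 92
  cosg <- (ec / 92) %*% t(vc / sqrt(rowSums(vc^2)))
  V <- matrix(0, nrow(ec), nrow(vc))
  Pp <- matrix(1, nrow(ec), nrow(vc)); Pc <- cosg
  for (l in 1:80) {
    V <- V + (2 * l + 1) * rep(b^(l - 1), each = nrow(ec)) * Pc
    Pn <- ((2 * l + 1) * cosg * Pc - l * Pp) / (l + 1)
    Pp <- Pc; Pc <- Pn
  }
  V <- sweep(V / (4 * pi * 0.33), 1, rowMeans(V / (4 * pi * 0.33)))
  expect_lt(max(abs(L - V)) / max(abs(V)), 1e-12)
  expect_error(three_shell_leadfield(vc * 2, ec), "inside the brain")
})

test_that("montage reduction subsets channels and lead field together", {
  head <- fixture_head(500)
  y <- forward_project(head, make_scenario("one", head))
  red <- reduce_montage(y, head, montage_labels(8))
  expect_equal(dim(red$signal$data), c(8L, ncol(y$data)))
  expect_equal(dim(red$head$leadfield), c(8L, 500L))
  expect_equal(red$signal$labels, montage_labels(8))
  expect_equal(red$signal$data["C3", ], y$data["C3", ])
  expect_equal(red$head$leadfield["O2", ], head$leadfield["O2", ])

  ident <- reduce_montage(y, head, head$electrode_labels)
  expect_equal(ident$signal$data, y$data)

  expect_error(reduce_montage(y, head, c("C3", "C3")), "duplicated")
  expect_error(reduce_montage(y, head, c("C3", "XX9")), "XX9")
})

test_that("packaged montages are nested subsets of the 10-10 layout", {
  full <- montage_labels("full")
  expect_false(anyDuplicated(full) > 0)
  for (n in c(8, 16, 32)) {
    m <- montage_labels(n)
    expect_equal(length(m), n)
    expect_true(all(m %in% full))
  }
  P <- ten_ten_positions()
  expect_lt(max(abs(sqrt(rowSums(P^2)) - 1)), 1e-12)
  # left/right symmetry of homologous pairs
  expect_equal(P["C3", c(2, 3)], P["C4", c(2, 3)])
  expect_equal(P["C3", 1], -P["C4", 1])
  expect_error(ten_ten_positions("Nope1"), "unsupported")
})
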