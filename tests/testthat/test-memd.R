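test_that("radical inverse reproduces the base-2 van der Corput sequence", {
  # brute-force digit reversal oracle
  brute <- function(i, base) {
    digs <- integer(0)
    while (i > 0) { digs <- c(digs, i %% base); i <- i %/% base }
    sum(digs / base^seq_along(digs))
  }
  expect_equal(radical_inverse(1:4, 2), c(0.5, 0.25, 0.75, 0.125))
  for (b in c(2, 3, 5)) {
    expect_equal(radical_inverse(1:20, b),
                 vapply(1:20, brute, numeric(1), base = b))
  }
})

test_that("direction sets are unit-norm, balanced and deterministic", {
  for (p in c(2, 3, 8)) {
    D <- hammersley_directions(4 * p, p)
    expect_equal(dim(D), c(4 * p, p))
    expect_lt(max(abs(sqrt(rowSums(D^2)) - 1)), 1e-12)
  }
  D3 <- hammersley_directions(256, 3)
  # near-uniform sphere coverage: mean direction close to the origin
  expect_lt(sqrt(sum(colMeans(D3)^2)), 0.1)
  expect_identical(hammersley_directions(64, 8), hammersley_directions(64, 8))
  expect_error(hammersley_directions(16, 1), "p >= 2")
  expect_error(hammersley_directions(3, 8), "at least p")
})

test_that("projection is the per-sample inner product", {
  set.seed(3)
  s <- matrix(rnorm(4 * 50), 4)
  e2 <- c(0, 1, 0, 0)
  expect_equal(project_signal(s, e2), s[2, ])
  d <- rnorm(4); d <- d / sqrt(sum(d^2))
  expect_equal(project_signal(s, -d), -project_signal(s, d))
  same <- matrix(rep(s[1, ], 4), 4, byrow = TRUE)
  expect_equal(project_signal(same, rep(1 / 2, 4)), 2 * s[1, ])
  expect_error(project_signal(s, c(1, 0)), "dimension")
})

test_that("multivariate local mean vanishes for rotations, tracks offsets", {
  t <- seq(0, 4, by = 1 / 200)
  n <- length(t)
  core <- seq(round(0.15 * n), round(0.85 * n))
  dirs <- hammersley_directions(32, 2)

  rot <- rbind(cos(2 * pi * 5 * t), sin(2 * pi * 5 * t))
  m <- multivariate_local_mean(rot, dirs)
  expect_lt(max(sqrt(colSums(m[, core]^2))), 0.05)

  s <- rbind(sin(2 * pi * 8 * t), sin(2 * pi * 8 * t))
  m2 <- multivariate_local_mean(s, hammersley_directions(32, 2))
  expect_lt(max(sqrt(colSums(m2[, core]^2))), 0.05)

  off <- s + c(2, -1)
  m3 <- multivariate_local_mean(off, dirs)
  expect_lt(max(abs(m3[1, core] - 2)), 0.1)
  expect_lt(max(abs(m3[2, core] + 1)), 0.1)

  expect_error(multivariate_local_mean(matrix(seq_len(40) / 10, 2, 20),
                                       dirs),
               class = "memdeeg_residual")
})

test_that("the C++ envelope kernel matches the pure-R reference", {
  set.seed(5)
  for (p in c(3, 8)) {
    m <- matrix(rnorm(p * 300), p) + tone(7, fs = 100, dur = 2.99)
    dirs <- hammersley_directions(4 * p, p)
    a <- memdeeg:::.mv_envelopes(m, dirs)
    b <- memdeeg:::.mv_envelopes_r(m, dirs)
    expect_equal(a$mean, b$mean, tolerance = 1e-12)
    expect_equal(a$amplitude, b$amplitude, tolerance = 1e-12)
    expect_equal(a$extrema_deficit, b$extrema_deficit)
  }
})

test_that("memd keeps channels mode-aligned and complete", {
  t <- seq(0, 2, by = 1 / 100)
  s <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + 0.2))
  d <- memd(s, fs = 100, config = memd_config(V = 16))
  expect_gt(cor(d$imfs[[1]][1, ], s[1, ]), 0.99)
  expect_gt(cor(d$imfs[[1]][2, ], s[2, ]), 0.99)
  rec <- Reduce(`+`, d$imfs) + d$residual
  expect_lt(max(abs(rec - s)), 1e-9 * max(abs(s)))
  # every channel has the same number of modes by construction
  expect_true(all(vapply(d$imfs, nrow, integer(1)) == 2L))

  expect_error(memd(matrix(1:10, 1), fs = 10), "p >= 2")
  expect_error(memd(matrix(c(1, NA, 3, 4, 5, 6), 2), fs = 10), "finite")
})

test_that("two-tone mixtures land each tone at a common IMF index", {
  fs <- 200
  hits <- 0L
  total <- 0L
  for (seed in 1:5) {
    s <- two_tone_channels(p = 8, seed = seed)
    d <- memd(s, fs = fs)
    doms <- imf_dominant_freqs(d, fs)   # p x M
    for (f in c(20, 4)) {
      idx <- apply(doms, 1, function(row) which.min(abs(row - f)))
      hits <- hits + max(table(idx))
      total <- total + length(idx)
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("memd is deterministic for fixed input and config", {
  s <- two_tone_channels(p = 4, dur = 2, seed = 9)
  d1 <- memd(s, fs = 200, config = memd_config(V = 16))
  d2 <- memd(s, fs = 200, config = memd_config(V = 16))
  expect_identical(d1$imfs, d2$imfs)
  expect_identical(d1$residual, d2$residual)
})
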