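test_that("extrema detection handles sinusoids, plateaus and constants", {
  t <- seq(0, 1, by = 1 / 100)
  ex <- find_extrema(sin(2 * pi * t))
  expect_equal(nrow(ex$maxima), 1L)
  expect_equal(nrow(ex$minima), 1L)
  expect_equal(ex$n_zero_crossings, 2L)

  ex2 <- find_extrema(c(0, 1, 0, -1, 0))
  expect_equal(ex2$maxima$index, 2L)
  expect_equal(ex2$minima$index, 4L)
  expect_equal(ex2$n_zero_crossings, 2L)

  ex3 <- find_extrema(rep(2, 10))
  expect_equal(nrow(ex3$maxima), 0L)
  expect_equal(nrow(ex3$minima), 0L)
  expect_equal(ex3$n_zero_crossings, 0L)

  # plateau maximum assigned to its midpoint
  ex4 <- find_extrema(c(0, 1, 1, 1, 0, -1, 0))
  expect_equal(ex4$maxima$index, 3L)
})

test_that("envelope local mean recovers offsets and vanishes for tones", {
  x <- tone(5, fs = 200, dur = 2)
  n <- length(x)
  core <- seq(round(0.15 * n), round(0.85 * n))
  lm <- local_mean(x)
  expect_lt(max(abs(lm$mean[core])), 0.02)

  lm2 <- local_mean(x + 3)
  expect_lt(max(abs(lm2$mean[core] - 3)), 0.02)

  # slowly amplitude-modulated tone still has near-zero local mean
  t <- seq(0, 2, by = 1 / 200)
  am <- (1 + 0.3 * sin(2 * pi * 0.5 * t)) * sin(2 * pi * 10 * t)
  lm3 <- local_mean(am)
  expect_lt(max(abs(lm3$mean[core])), 0.05 * max(am))

  expect_error(local_mean(seq(0, 1, length.out = 50)),
               class = "memdeeg_residual")
})

test_that("the multi-RHS natural spline agrees with stats::spline", {
  set.seed(11)
  xk <- sort(sample(1:100, 12))
  Y <- matrix(rnorm(12 * 3), 12)
  out <- memdeeg:::.spline_multi(xk, Y, seq(min(xk), max(xk), by = 0.5))
  for (j in 1:3) {
    ref <- stats::spline(xk, Y[, j], xout = seq(min(xk), max(xk), by = 0.5),
                         method = "natural")$y
    expect_equal(out[, j], ref, tolerance = 1e-12)
  }
})

test_that("sifting decomposes tones and respects completeness", {
  t <- seq(0, 6, by = 1 / 200)
  x <- sin(2 * pi * 10 * t)
  d <- emd(x, fs = 200)
  expect_gte(length(d$imfs), 1L)
  expect_gt(cor(d$imfs[[1]], x), 0.99)
  expect_lt(sum(d$residual^2), 0.01 * sum(x^2))
  # >= 90% of the energy in one mode
  energies <- vapply(d$imfs, function(v) sum(v^2), numeric(1))
  expect_gt(max(energies) / (sum(energies) + sum(d$residual^2)), 0.9)

  dz <- emd(rep(0, 100), fs = 100)
  expect_equal(length(dz$imfs), 0L)
  expect_equal(dz$residual, rep(0, 100))

  x2 <- sin(2 * pi * 4 * t) + sin(2 * pi * 20 * t)
  d2 <- emd(x2, fs = 200)
  doms <- vapply(d2$imfs, dominant_frequency, numeric(1), fs = 200)
  expect_lt(which.min(abs(doms - 20)), which.min(abs(doms - 4)))
  rec <- Reduce(`+`, d2$imfs) + d2$residual
  expect_lt(max(abs(rec - x2)), 1e-9 * max(abs(x2)))

  expect_error(emd(c(1, NA, 3, 4)), "finite")
})

test_that("returned IMFs satisfy the extrema / zero-crossing criterion", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(400) + tone(6, fs = 100, dur = 3.99)
    d <- emd(x, fs = 100)
    M <- length(d$imfs)
    ok <- vapply(d$imfs, function(im) {
      ex <- find_extrema(im)
      abs(nrow(ex$maxima) + nrow(ex$minima) - ex$n_zero_crossings) <= 1L
    }, logical(1))
    # allowed to fail on at most the last (slowest) mode
    expect_true(all(ok[-M]))
  }
})

test_that("instantaneous frequency tracks tones and chirps", {
  fs <- 200
  t <- seq(0, 6, by = 1 / fs)
  tr <- instantaneous_frequency(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(stats::median(tr$freq[tr$valid]) - 10), 0.1)
  expect_lt(max(abs(tr$amplitude[tr$valid] - 1)), 0.05)

  # linear chirp 5 -> 15 Hz over 6 s: f(t) = 5 + (10/6) t
  ph <- 2 * pi * (5 * t + (10 / 6) * t^2 / 2)
  trc <- instantaneous_frequency(sin(ph), fs)
  expect_lt(max(abs(trc$freq[trc$valid] - (5 + (10 / 6) * t[trc$valid]))), 0.5)

  trk <- instantaneous_frequency(rep(1, 100), fs = 100)
  expect_false(any(trk$valid))

  # scaled amplitude
  tra <- instantaneous_frequency(3.5 * sin(2 * pi * 10 * t), fs)
  expect_lt(max(abs(tra$amplitude[tra$valid] - 3.5)), 0.2)
})

test_that("Hilbert spectrum concentrates energy in the right bands", {
  fs <- 200
  t <- seq(0, 4, by = 1 / fs)
  d <- emd(sin(2 * pi * 10 * t), fs = fs)
  H <- hilbert_spectrum(d, freq_bins = 50, fmax = 50)
  band <- rowSums(H)
  expect_equal(which.max(band), 11L)  # 10 Hz in [10, 11) with 1 Hz bins
  # time marginal recovers the IMF energy within 5%
  expect_lt(abs(sum(H) - sum(attr(H, "imf_energy"))) /
              sum(attr(H, "imf_energy")), 0.05)

  x2 <- sin(2 * pi * 4 * t) + sin(2 * pi * 20 * t)
  H2 <- hilbert_spectrum(emd(x2, fs = fs), freq_bins = 25, fmax = 50)
  band2 <- rowSums(H2)
  peaks <- sort(order(band2, decreasing = TRUE)[1:2])
  expect_equal(peaks, c(3L, 11L))     # 4 Hz in [4,6), 20 Hz in [20,22)

  empty <- structure(list(imfs = list(), residual = numeric(100), fs = fs,
                          stoppage = stoppage_config()), class = "imf_set")
  expect_true(all(hilbert_spectrum(empty, freq_bins = 10) == 0))
})
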