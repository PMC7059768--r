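# Shared fixtures, built in code at test time.

tone <- function(f, fs = 200, dur = 4, phase = 0) {
  sin(2 * pi * f * seq(0, dur, by = 1 / fs) + phase)
}

# two-tone multichannel mixture with channel-specific gains + noise
two_tone_channels <- function(p = 8, f1 = 4, f2 = 20, fs = 200, dur = 4,
                              noise_sd = 0.1, seed = 1) {
  t <- seq(0, dur, by = 1 / fs)
  set.seed(seed)
  g1 <- runif(p, 0.5, 2)
  g2 <- runif(p, 0.5, 2)
  s <- outer(g1, sin(2 * pi * f1 * t)) + outer(g2, sin(2 * pi * f2 * t))
  if (noise_sd > 0) s <- s + matrix(rnorm(p * length(t), sd = noise_sd), p)
  s
}

# small cached head models so expensive fixtures are built once
.fixture_env <- new.env()

fixture_head <- function(n = 500, seed = 7) {
  key <- paste0("head_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- synth_headmodel(n, montage_labels("full"),
                                           seed = seed)
  .fixture_env[[key]]
}

# per-IMF-and-channel dominant frequency table for alignment checks
imf_dominant_freqs <- function(mimf, fs) {
  sapply(mimf$imfs, function(im) apply(im, 1, dominant_frequency, fs = fs))
}

make_power_dist <- function(mass, coords, roi = c(0, 1)) {
  structure(list(mass = mass / sum(mass), coords = as.matrix(coords),
                 roi = roi), class = "power_distribution")
}

# dense transportation LP via the boot package's simplex (independent
# oracle for the transportation-simplex implementation)
transport_lp_oracle <- function(a, b, C) {
  m <- length(a)
  n <- length(b)
  A3 <- matrix(0, m + n - 1L, m * n)
  for (i in seq_len(m)) A3[i, (seq_len(n) - 1L) * m + i] <- 1
  for (j in seq_len(n - 1L)) A3[m + j, (j - 1L) * m + seq_len(m)] <- 1
  res <- boot::simplex(a = as.vector(C), A3 = A3, b3 = c(a, b[-n]),
                       maxi = FALSE)
  unname(res$value)
}
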