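# Univariate empirical mode decomposition and Hilbert spectral analysis.
#
# An intrinsic mode function (IMF) satisfies two criteria: the number of
# extrema and zero crossings differ by at most one, and the mean of the
# upper (maxima) and lower (minima) envelopes is approximately zero.
# Sifting subtracts the envelope mean repeatedly until a two-threshold
# stoppage rule on the normalized envelope-mean amplitude is met.

#' Sifting stoppage configuration
#'
#' Two-threshold stoppage rule evaluated on the normalized envelope-mean
#' amplitude eta(t) = |m(t)| / a(t), where m is the envelope mean and a
#' the envelope half-range.  Sifting of a candidate mode stops once the
#' fraction of samples with eta > theta1 is below alpha and eta < theta2
#' everywhere, or after `max_sift` iterations.
#'
#' @param theta1 lower threshold on eta (default 0.05).
#' @param theta2 hard upper threshold on eta (default 0.5).
#' @param alpha tolerated fraction of samples exceeding theta1 (default 0.05).
#' @param max_sift hard cap on sifting iterations per mode (default 100).
#' @return A list of class `stoppage_config`.
#' @export
stoppage_config <- function(theta1 = 0.05, theta2 = 0.5, alpha = 0.05,
                            max_sift = 100L) {
  stopifnot(theta1 > 0, theta2 > theta1, alpha > 0, alpha < 1, max_sift >= 1)
  structure(list(theta1 = theta1, theta2 = theta2, alpha = alpha,
                 max_sift = as.integer(max_sift)),
            class = "stoppage_config")
}

#' Locate local extrema and count zero crossings
#'
#' Strict local extrema are detected by a sign change of the first
#' difference; an extremum spanning a plateau of equal values is assigned
#' to the plateau midpoint.  A zero crossing is a strict sign flip
#' between consecutive (non-negligible) samples; entering a run of
#' (near-)zero samples from a non-zero value also counts as one crossing.
#'
#' @param x numeric vector, length >= 3.
#' @return list with data frames `maxima` and `minima` (columns `index`,
#'   `value`) and the integer `n_zero_crossings`.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  stopifnot(n >= 3L)
  if (!all(is.finite(x))) stop("input must be finite")
  ex <- .extrema_idx(x)
  list(maxima = data.frame(index = ex$max_idx, value = x[ex$max_idx]),
       minima = data.frame(index = ex$min_idx, value = x[ex$min_idx]),
       n_zero_crossings = .count_zero_crossings(x))
}

# Minimal-allocation extrema detector shared by the sifting loops.
.extrema_idx <- function(x) {
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2L)
    return(list(max_idx = integer(0), min_idx = integer(0)))
  ss <- s[nz]
  ch <- which(diff(ss) != 0)
  if (!length(ch))
    return(list(max_idx = integer(0), min_idx = integer(0)))
  # plateau between the end of one slope and the start of the next;
  # extremum index = midpoint of the flat stretch (a single sample when
  # there is no plateau)
  idx <- as.integer(floor((nz[ch] + 1L + nz[ch + 1L]) / 2))
  ismax <- ss[ch] > 0
  list(max_idx = idx[ismax], min_idx = idx[!ismax])
}

.count_zero_crossings <- function(x) {
  scale <- max(abs(x))
  if (scale == 0) return(0L)
  tol <- 1e-12 * scale
  z <- abs(x) <= tol
  sg <- sign(x)
  sg[z] <- 0L
  n <- length(x)
  flips <- sum(sg[-n] * sg[-1L] < 0)
  into_zero <- sum(sg[-n] != 0 & sg[-1L] == 0)
  as.integer(flips + into_zero)
}

# Mirror the first/last two knots about the end samples so that spline
# envelopes do not swing at the boundaries.  `src` maps each (possibly
# mirrored) knot back to the original extremum sample it copies.
.extend_knots <- function(idx, val, n) {
  k <- length(idx)
  nl <- min(2L, k)
  nr <- min(2L, k)
  lsel <- seq_len(nl)
  rsel <- k - seq_len(nr) + 1L          # last, second-to-last
  tt <- c(rev(2 - idx[lsel]), idx, 2 * n - idx[rsel])
  vv <- c(rev(val[lsel]), val, val[rsel])
  src <- c(rev(idx[lsel]), idx, idx[rsel])
  keep <- !duplicated(tt)
  list(t = tt[keep], v = vv[keep], src = src[keep])
}

# Natural cubic spline interpolation with multiple right-hand sides.
# xk: strictly increasing knots (length k >= 2); Y: k x p values;
# xout: evaluation points.  Returns length(xout) x p matrix.  The
# tridiagonal system for the spline curvatures is solved by the Thomas
# algorithm, vectorized across columns.
.spline_multi <- function(xk, Y, xout) {
  k <- length(xk)
  Y <- as.matrix(Y)
  p <- ncol(Y)
  if (k == 2L) {
    w <- (xout - xk[1L]) / (xk[2L] - xk[1L])
    return(outer(1 - w, Y[1L, ]) + outer(w, Y[2L, ]))
  }
  h <- diff(xk)
  slope <- diff(Y) / h
  M <- matrix(0, k, p)
  if (k > 2L) {
    nin <- k - 2L
    a <- h[seq_len(nin)]                  # sub-diagonal
    b <- 2 * (h[seq_len(nin)] + h[seq_len(nin) + 1L])
    cc <- h[seq_len(nin) + 1L]            # super-diagonal
    D <- 6 * (slope[-1L, , drop = FALSE] - slope[-nrow(slope), , drop = FALSE])
    if (nin > 1L) {
      for (i in 2:nin) {
        w <- a[i] / b[i - 1L]
        b[i] <- b[i] - w * cc[i - 1L]
        D[i, ] <- D[i, ] - w * D[i - 1L, ]
      }
    }
    M[nin + 1L, ] <- D[nin, ] / b[nin]
    if (nin > 1L) {
      for (i in (nin - 1L):1L)
        M[i + 1L, ] <- (D[i, ] - cc[i] * M[i + 2L, ]) / b[i]
    }
  }
  j <- findInterval(xout, xk, all.inside = TRUE)
  dx <- xout - xk[j]
  hj <- h[j]
  # cubic Hermite form in terms of curvatures
  A <- (xk[j + 1L] - xout) / hj
  B <- dx / hj
  C1 <- (A^3 - A) * hj^2 / 6
  C2 <- (B^3 - B) * hj^2 / 6
  A * Y[j, , drop = FALSE] + B * Y[j + 1L, , drop = FALSE] +
    C1 * M[j, , drop = FALSE] + C2 * M[j + 1L, , drop = FALSE]
}

.spline_envelope <- function(idx, val, n) {
  kn <- .extend_knots(idx, val, n)
  drop(.spline_multi(kn$t, matrix(kn$v, ncol = 1L), seq_len(n)))
}

#' Local mean of a signal from its extrema envelopes
#'
#' Cubic-spline upper and lower envelopes are fitted through the local
#' maxima and minima (after mirror extension at the boundaries); their
#' pointwise average is the local mean used by the sifting loop.
#'
#' @param x numeric vector.
#' @return list with elements `mean`, `amplitude` (envelope half-range),
#'   `n_maxima`, `n_minima`.  Signals with fewer than two maxima or two
#'   minima raise a condition of class `memdeeg_residual`: they carry no
#'   further oscillation and belong to the residual.
#' @export
local_mean <- function(x) {
  ex <- find_extrema(x)
  if (nrow(ex$maxima) < 2L || nrow(ex$minima) < 2L) {
    cond <- structure(
      class = c("memdeeg_residual", "error", "condition"),
      list(message = "too few extrema for envelope interpolation",
           call = sys.call()))
    stop(cond)
  }
  n <- length(x)
  upper <- .spline_envelope(ex$maxima$index, ex$maxima$value, n)
  lower <- .spline_envelope(ex$minima$index, ex$minima$value, n)
  list(mean = (upper + lower) / 2, amplitude = (upper - lower) / 2,
       n_maxima = nrow(ex$maxima), n_minima = nrow(ex$minima))
}

new_imf_set <- function(imfs, residual, fs, stoppage) {
  structure(list(imfs = imfs, residual = residual, fs = fs,
                 stoppage = stoppage),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) of length %d @ %g Hz\n",
              length(x$imfs), length(x$residual), x$fs))
  invisible(x)
}

#' Empirical mode decomposition by sifting
#'
#' Decomposes a signal into intrinsic mode functions plus a residual,
#' `x = sum(imfs) + residual`, extracted from fast to slow oscillations.
#' Extraction stops when fewer than three extrema remain or `max_imfs`
#' is reached.
#'
#' @param x numeric vector (finite) or a single-channel `eeg_signal`.
#' @param fs sampling rate (Hz); taken from `x` when it is an `eeg_signal`.
#' @param max_imfs maximum number of modes to extract.
#' @param stoppage a [stoppage_config()].
#' @return An object of class `imf_set`: list with `imfs` (list of
#'   numeric vectors), `residual`, `fs` and the stoppage settings used.
#' @examples
#' t <- seq(0, 6, by = 1 / 200)
#' d <- emd(sin(2 * pi * 4 * t) + sin(2 * pi * 20 * t), fs = 200)
#' length(d$imfs)
#' @export
emd <- function(x, fs = 1, max_imfs = 10L, stoppage = stoppage_config()) {
  if (inherits(x, "eeg_signal")) {
    if (nrow(x$data) != 1L)
      stop("emd() is univariate; use memd() for multichannel signals")
    fs <- x$fs
    x <- drop(x$data)
  }
  if (!all(is.finite(x))) stop("input must be finite")
  stopifnot(length(x) >= 4L, max_imfs >= 1L)
  r <- as.numeric(x)
  imfs <- list()
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(r)
    if (nrow(ex$maxima) + nrow(ex$minima) < 3L) break
    h <- r
    for (it in seq_len(stoppage$max_sift)) {
      lm <- tryCatch(local_mean(h), memdeeg_residual = function(e) NULL)
      if (is.null(lm)) break
      eta <- abs(lm$mean) / pmax(lm$amplitude, .Machine$double.eps)
      done <- mean(eta > stoppage$theta1) < stoppage$alpha &&
        all(eta <= stoppage$theta2)
      h <- h - lm$mean
      if (done) {
        # hybrid rule: also require the IMF counting criterion
        ex <- find_extrema(h)
        if (abs(nrow(ex$maxima) + nrow(ex$minima) -
                  ex$n_zero_crossings) <= 1L) break
      }
    }
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  new_imf_set(imfs, r, fs, stoppage)
}

# FFT-based analytic signal (Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous frequency and amplitude of an IMF
#'
#' The analytic signal is formed by the Hilbert transform; the phase is
#' unwrapped and differentiated by central differences, giving
#' f(t) = (1 / 2 pi) d theta / dt in Hz.  Samples within `edge_frac` of
#' either end are flagged invalid (Hilbert edge artifacts), as is the
#' whole track for a constant input.
#'
#' @param imf numeric vector, an (approximately) zero-mean oscillatory mode.
#' @param fs sampling rate in Hz.
#' @param edge_frac fraction of samples invalidated at each edge.
#' @return list of class `inst_freq` with `freq` (Hz), `amplitude`,
#'   `valid` (logical mask) and `fs`.
#' @export
instantaneous_frequency <- function(imf, fs, edge_frac = 0.05) {
  n <- length(imf)
  stopifnot(n >= 4L, fs > 0)
  a <- analytic_signal(imf)
  amp <- Mod(a)
  ph <- signal::unwrap(Arg(a))
  freq <- numeric(n)
  freq[2:(n - 1L)] <- (ph[3:n] - ph[1:(n - 2L)]) / 2
  freq[1L] <- ph[2L] - ph[1L]
  freq[n] <- ph[n] - ph[n - 1L]
  freq <- freq * fs / (2 * pi)
  nedge <- ceiling(edge_frac * n)
  valid <- rep(TRUE, n)
  valid[seq_len(nedge)] <- FALSE
  valid[(n - nedge + 1L):n] <- FALSE
  if (stats::sd(imf) == 0) valid[] <- FALSE
  structure(list(freq = freq, amplitude = amp, valid = valid, fs = fs),
            class = "inst_freq")
}

#' Hilbert spectrum of an IMF set
#'
#' Accumulates squared analytic amplitude into (frequency-bin, time)
#' cells from each IMF's instantaneous-frequency track.  Only samples
#' marked valid contribute.
#'
#' @param imfset an `imf_set`.
#' @param freq_bins number of frequency bins between 0 and `fmax`.
#' @param fmax upper frequency edge in Hz (defaults to Nyquist).
#' @return numeric matrix, `freq_bins` x T, with attributes `freq_breaks`
#'   (bin edges in Hz) and `imf_energy` (valid-sample energy per IMF).
#' @export
hilbert_spectrum <- function(imfset, freq_bins = 64L, fmax = NULL) {
  stopifnot(inherits(imfset, "imf_set"), freq_bins >= 2L)
  T <- length(imfset$residual)
  if (is.null(fmax)) fmax <- imfset$fs / 2
  breaks <- seq(0, fmax, length.out = freq_bins + 1L)
  H <- matrix(0, nrow = freq_bins, ncol = T)
  energy <- numeric(length(imfset$imfs))
  for (i in seq_along(imfset$imfs)) {
    tr <- instantaneous_frequency(imfset$imfs[[i]], imfset$fs)
    ok <- tr$valid & tr$freq >= 0 & tr$freq <= fmax
    if (!any(ok)) next
    bin <- pmin(findInterval(tr$freq[ok], breaks, rightmost.closed = TRUE),
                freq_bins)
    e <- tr$amplitude[ok]^2
    tk <- which(ok)
    for (j in seq_along(tk)) H[bin[j], tk[j]] <- H[bin[j], tk[j]] + e[j]
    energy[i] <- sum(tr$amplitude[tr$valid]^2)
  }
  attr(H, "freq_breaks") <- breaks
  attr(H, "imf_energy") <- energy
  H
}

#' Dominant frequency of a signal by periodogram peak
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return frequency (Hz) of the largest periodogram ordinate.
#' @export
dominant_frequency <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 8L)
  P <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:floor(n / 2)
  freqs <- (half - 1L) * fs / n
  freqs[which.max(P[half])]
}
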