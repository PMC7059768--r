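# Multivariate empirical mode decomposition (MEMD).
#
# A p-variate signal is sifted jointly: the signal is projected onto a
# low-discrepancy set of directions on the unit (p-1)-sphere, an
# envelope is interpolated through the signal samples at each
# projection's maxima, and the mean of the V envelopes is the
# multivariate local mean m(t).  Details d(t) = s(t) - m(t) that satisfy
# the stoppage rule become p-variate IMFs, so every channel receives the
# same number of scale-aligned modes.

#' Radical-inverse (van der Corput) sequence value
#'
#' Digit-reversal of the integer `i` in the given base, mapped to [0, 1).
#'
#' @param i positive integer (vectorized).
#' @param base integer base >= 2.
#' @return numeric vector in [0, 1).
#' @export
radical_inverse <- function(i, base = 2L) {
  vapply(as.integer(i), function(k) {
    f <- 1 / base
    r <- 0
    while (k > 0) {
      r <- r + f * (k %% base)
      k <- k %/% base
      f <- f / base
    }
    r
  }, numeric(1L))
}

.first_primes <- function(k) {
  out <- integer(0)
  cand <- 2L
  while (length(out) < k) {
    if (all(cand %% out != 0L)) out <- c(out, cand)
    cand <- cand + 1L
  }
  out
}

#' Hammersley direction set on the unit sphere in p dimensions
#'
#' A V-point Hammersley set in the (p-1)-dimensional unit hypercube
#' (first coordinate (2i - 1) / (2V), remaining coordinates radical
#' inverses in the first p - 2 prime bases) is mapped to the unit
#' (p-1)-sphere by the inverse-CDF transform of the spherical angles:
#' angle j (polar, density proportional to sin^(p-1-j)) via the Beta
#' quantile identity cos(theta) = 1 - 2 qbeta(u, (m+1)/2, (m+1)/2), and
#' the final azimuth uniformly on [0, 2 pi).  By default the set is
#' made antipodally symmetric (half the points plus their negatives):
#' with maxima-only envelope interpolation this makes every direction's
#' opposite extreme explicitly covered and removes the slow-mode bias
#' an unbalanced set induces in the multivariate local mean.
#' Deterministic in (V, p).
#'
#' @param V number of directions (>= p).
#' @param p ambient dimensionality (>= 2), i.e. the channel count.
#' @param antipodal pair each sampled direction with its negative
#'   (default); `FALSE` gives the plain mapped Hammersley set.
#' @return V x p numeric matrix of unit row vectors.
#' @export
hammersley_directions <- function(V, p, antipodal = TRUE) {
  V <- as.integer(V)
  p <- as.integer(p)
  if (p < 2L) stop("direction sampling requires p >= 2")
  if (V < p) stop("need at least p directions")
  if (antipodal) {
    half <- hammersley_directions(max(as.integer(ceiling(V / 2)), p), p,
                                  antipodal = FALSE)
    return(rbind(half, -half)[seq_len(max(V, 2L * p)), , drop = FALSE])
  }
  u <- matrix(0, nrow = V, ncol = p - 1L)
  u[, 1L] <- (2 * seq_len(V) - 1) / (2 * V)
  if (p > 2L) {
    bases <- .first_primes(p - 2L)
    for (j in 2:(p - 1L)) u[, j] <- radical_inverse(seq_len(V), bases[j - 1L])
  }
  X <- matrix(0, nrow = V, ncol = p)
  # polar angles theta_1 .. theta_{p-2}, then the azimuth
  sin_prod <- rep(1, V)
  if (p > 2L) {
    for (j in seq_len(p - 2L)) {
      m <- p - 1L - j
      th <- acos(1 - 2 * stats::qbeta(u[, j], (m + 1) / 2, (m + 1) / 2))
      X[, j] <- sin_prod * cos(th)
      sin_prod <- sin_prod * sin(th)
    }
  }
  az <- 2 * pi * u[, p - 1L]
  X[, p - 1L] <- sin_prod * cos(az)
  X[, p] <- sin_prod * sin(az)
  X / sqrt(rowSums(X^2))
}

#' Project a multichannel signal onto a direction
#'
#' @param s an `eeg_signal` or p x T numeric matrix.
#' @param direction unit vector of length p.
#' @return numeric vector of length T: the per-sample inner product.
#' @export
project_signal <- function(s, direction) {
  m <- if (inherits(s, "eeg_signal")) s$data else as.matrix(s)
  if (length(direction) != nrow(m))
    stop("direction dimension (", length(direction),
         ") does not match channel count (", nrow(m), ")")
  drop(crossprod(m, direction))
}

#' MEMD configuration
#'
#' @param V number of projection directions; defaults to 64 for p <= 16
#'   and 128 above (`V = NULL` selects by channel count at run time).
#' @param stoppage a [stoppage_config()].
#' @param max_imfs maximum number of multivariate modes.
#' @param seed reserved; the Hammersley direction set is deterministic.
#' @return list of class `memd_config`.
#' @export
memd_config <- function(V = NULL, stoppage = stoppage_config(),
                        max_imfs = 12L, seed = 0L) {
  structure(list(V = V, stoppage = stoppage,
                 max_imfs = as.integer(max_imfs), seed = as.integer(seed)),
            class = "memd_config")
}

# Multivariate envelope statistics for one candidate mode.
# Returns NULL (residual condition) when fewer than 2 projection maxima
# exist in at least half of the directions.  `extrema_deficit` reports
# the share of directions whose projection has < 3 extrema in total,
# which drives decomposition termination.
# Envelope mean/amplitude over a direction set; hot path in C++ with a
# pure-R reference used by the unit tests.
.mv_envelopes <- function(m, dirs) {
  tm <- t(m)
  Q <- tm %*% t(dirs)
  res <- .envelope_mean_cpp(Q, tm)
  if (res$used * 2 < ncol(Q)) return(NULL)
  list(mean = t(res$mean), amplitude = res$amplitude,
       extrema_deficit = res$extrema_deficit)
}

.mv_envelopes_r <- function(m, dirs) {
  p <- nrow(m)
  T <- ncol(m)
  V <- nrow(dirs)
  tm <- t(m)                              # T x p, sampled once
  Q <- tm %*% t(dirs)                     # T x V projections in one call
  env_sum <- matrix(0, T, p)
  e2_sum <- numeric(T)
  used <- 0L
  few_extrema <- 0L
  grid <- seq_len(T)
  for (v in seq_len(V)) {
    ex <- .extrema_idx(Q[, v])
    if (length(ex$max_idx) + length(ex$min_idx) < 3L)
      few_extrema <- few_extrema + 1L
    if (length(ex$max_idx) < 2L) next
    kn <- .extend_knots(ex$max_idx, Q[ex$max_idx, v], T)
    e <- .spline_multi(kn$t, tm[kn$src, , drop = FALSE], grid)
    used <- used + 1L
    env_sum <- env_sum + e
    e2_sum <- e2_sum + rowSums(e^2)
  }
  if (used < V / 2) return(NULL)
  mean_env <- env_sum / used
  amp <- sqrt(pmax(e2_sum / used - rowSums(mean_env^2), 0))
  list(mean = t(mean_env), amplitude = amp,
       extrema_deficit = few_extrema / V)
}

#' Multivariate local mean
#'
#' For each direction, the times of the projection maxima are found and
#' the full p-variate samples at those times are componentwise
#' cubic-spline interpolated to an envelope e_v(t); the local mean is
#' the average of the V envelopes.
#'
#' @param s an `eeg_signal` or p x T matrix.
#' @param directions V x p matrix of unit direction vectors (rows), e.g.
#'   from [hammersley_directions()].
#' @return p x T numeric matrix.  Raises a `memdeeg_residual` condition
#'   when fewer than half the projections have two or more maxima.
#' @export
multivariate_local_mean <- function(s, directions) {
  m <- if (inherits(s, "eeg_signal")) s$data else as.matrix(s)
  if (ncol(directions) != nrow(m))
    stop("direction dimensionality must equal channel count")
  env <- .mv_envelopes(m, directions)
  if (is.null(env)) {
    cond <- structure(
      class = c("memdeeg_residual", "error", "condition"),
      list(message = "too few projection maxima for a multivariate envelope",
           call = sys.call()))
    stop(cond)
  }
  env$mean
}

new_mimf_set <- function(imfs, residual, fs, config, labels) {
  structure(list(imfs = imfs, residual = residual, fs = fs,
                 config = config, labels = labels),
            class = "mimf_set")
}

#' @export
print.mimf_set <- function(x, ...) {
  cat(sprintf("<mimf_set> %d p-variate IMF(s), p = %d, T = %d, %g Hz\n",
              length(x$imfs), nrow(x$residual), ncol(x$residual), x$fs))
  invisible(x)
}

#' Multivariate empirical mode decomposition
#'
#' Joint sifting of a p-channel signal: every channel receives the same
#' number M of scale-aligned IMFs and `Reduce("+", imfs) + residual`
#' reproduces the input to numeric precision.
#'
#' @param s an `eeg_signal` or p x T numeric matrix (p >= 2).
#' @param fs sampling rate in Hz, when `s` is a plain matrix.
#' @param config a [memd_config()].
#' @return An object of class `mimf_set`: `imfs` is a list of p x T
#'   matrices, `residual` a p x T matrix.
#' @examples
#' t <- seq(0, 2, by = 1 / 100)
#' s <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
#' d <- memd(s, fs = 100, config = memd_config(V = 16))
#' length(d$imfs)
#' @export
memd <- function(s, fs = NULL, config = memd_config()) {
  labels <- NULL
  if (inherits(s, "eeg_signal")) {
    fs <- s$fs
    labels <- s$labels
    s <- s$data
  }
  s <- as.matrix(s)
  if (is.null(fs)) stop("fs is required for matrix input")
  if (!all(is.finite(s))) stop("input must be finite")
  p <- nrow(s)
  if (p < 2L) stop("memd() needs p >= 2 channels; use emd() for p = 1")
  V <- config$V
  if (is.null(V)) V <- if (p <= 16L) 64L else 128L
  if (V < p) stop("V must be at least p")
  dirs <- hammersley_directions(V, p)
  stp <- config$stoppage
  r <- s
  imfs <- list()
  while (length(imfs) < config$max_imfs) {
    env0 <- .mv_envelopes(r, dirs)
    if (is.null(env0) || env0$extrema_deficit >= 0.5) break
    h <- r
    env <- env0
    for (it in seq_len(stp$max_sift)) {
      eta <- sqrt(colSums(env$mean^2)) / pmax(env$amplitude,
                                              .Machine$double.eps)
      done <- mean(eta > stp$theta1) < stp$alpha && all(eta <= stp$theta2)
      h <- h - env$mean
      if (done) break
      env <- .mv_envelopes(h, dirs)
      if (is.null(env)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  new_mimf_set(imfs, r, fs, config, labels)
}
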