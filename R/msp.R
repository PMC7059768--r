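# Source reconstruction: multiple sparse priors (MSP) and minimum norm.
#
# MSP models the sensor covariance as
#   Sigma = lambda_0 I + sum_j lambda_j M C_j M'
# where each C_j is a smooth cortical patch (rank-one component
# q_j q_j'), and estimates the non-negative weights lambda by ReML:
# Fisher-scored ascent on the variational free energy of the Gaussian
# model, with a weak log-normal hyperprior and greedy pruning of
# components whose weight collapses.  The conditional mean of the
# sources given the data is
#   xhat = (sum_j lambda_j C_j) M' Sigma^-1 y.

#' Build smooth cortical patch priors
#'
#' Patch centers are spread quasi-uniformly over the vertices by
#' farthest-point sampling; each component is a Gaussian-falloff patch
#' in Euclidean vertex distance (an approximation to geodesic distance
#' on a convex cortex surface), truncated at 3 smoothing lengths and
#' scaled so the implied covariance component q q' has unit trace.
#'
#' @param head a `head_model`.
#' @param n_patches number of components (<= number of vertices).
#' @param smoothing_mm Gaussian spatial scale in mm (> 0).
#' @return object of class `prior_set`: sparse n x J matrix `patches`
#'   (columns q_j), integer `centers`, `smoothing_mm`.
#' @export
build_patches <- function(head, n_patches = 128L, smoothing_mm = 10) {
  stopifnot(inherits(head, "head_model"))
  if (smoothing_mm <= 0) stop("smoothing_mm must be positive")
  n <- nrow(head$vertex_coords)
  n_patches <- as.integer(n_patches)
  if (n_patches > n) stop("more patches than vertices")
  xyz <- head$vertex_coords
  # farthest-point sampling, deterministic from vertex 1
  centers <- integer(n_patches)
  centers[1L] <- 1L
  mind <- sqrt(colSums((t(xyz) - xyz[1L, ])^2))
  if (n_patches > 1L) {
    for (j in 2:n_patches) {
      centers[j] <- which.max(mind)
      dj <- sqrt(colSums((t(xyz) - xyz[centers[j], ])^2))
      mind <- pmin(mind, dj)
    }
  }
  ij <- vector("list", n_patches)
  for (j in seq_len(n_patches)) {
    dj <- sqrt(colSums((t(xyz) - xyz[centers[j], ])^2))
    keep <- which(dj <= 3 * smoothing_mm)
    w <- exp(-dj[keep]^2 / (2 * smoothing_mm^2))
    ij[[j]] <- cbind(i = keep, j = j, x = w / sqrt(sum(w^2)))
  }
  trip <- do.call(rbind, ij)
  patches <- Matrix::sparseMatrix(i = trip[, 1L], j = trip[, 2L],
                                  x = trip[, 3L], dims = c(n, n_patches))
  structure(list(patches = patches, centers = centers,
                 smoothing_mm = smoothing_mm),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat(sprintf("<prior_set> %d patch components, smoothing %g mm\n",
              length(x$centers), x$smoothing_mm))
  invisible(x)
}

new_source_estimate <- function(xhat, method, hyperparameters, free_energy,
                                free_energy_trace, converged, montage, fs, t0) {
  structure(list(xhat = xhat, method = method,
                 hyperparameters = hyperparameters,
                 free_energy = free_energy,
                 free_energy_trace = free_energy_trace,
                 converged = converged, montage = montage, fs = fs, t0 = t0),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %s: %d vertices x %d samples, F = %s\n",
              x$method, nrow(x$xhat), ncol(x$xhat),
              if (is.null(x$free_energy)) "NA" else sprintf("%.2f", x$free_energy)))
  invisible(x)
}

#' Multiple sparse priors inversion
#'
#' ReML / free-energy estimation of the sensor noise weight and the
#' patch-component weights, followed by the conditional mean of the
#' source amplitudes.  The whole segment's sample covariance is the
#' data summary (no temporal projection).  The free-energy trace is
#' non-decreasing by construction (backtracking on the Fisher-scoring
#' step).
#'
#' @param y an `eeg_signal` whose channels match the head model.
#' @param head a `head_model`.
#' @param priors a `prior_set` from [build_patches()]; built with
#'   defaults when `NULL`.
#' @param noise_floor lower bound on the sensor-noise weight, relative
#'   to the average sensor power.
#' @param max_iter maximum ReML iterations.
#' @param tol free-energy increase below which iteration stops.
#' @param prune_tol components with weight below `prune_tol` times the
#'   largest weight are dropped from the ascent (greedy pruning).
#' @return a `source_estimate` with fields `xhat` (n x T), `method`,
#'   `hyperparameters`, `free_energy`, `free_energy_trace`, `converged`.
#' @export
invert_msp <- function(y, head, priors = NULL, noise_floor = 1e-6,
                       max_iter = 512L, tol = 1e-3, prune_tol = 1e-8) {
  stopifnot(inherits(y, "eeg_signal"), inherits(head, "head_model"))
  if (!identical(y$labels, head$electrode_labels))
    stop("signal channels do not match head-model electrodes")
  if (is.null(priors)) priors <- build_patches(head)
  M <- head$leadfield
  d <- nrow(M)
  T <- ncol(y$data)
  n <- ncol(M)
  if (all(y$data == 0)) {
    return(new_source_estimate(matrix(0, n, T), "msp", NULL, NA_real_,
                               numeric(0), TRUE, y$labels, y$fs, y$t0))
  }
  # sensor components: a_j = M qs_j with qs_j = q_j / ||M q_j|| so that
  # each Q_j = a_j a_j' has unit trace
  A0 <- as.matrix(M %*% priors$patches)
  nrm <- sqrt(colSums(A0^2))
  ok <- nrm > 1e-12 * max(nrm)
  A <- sweep(A0[, ok, drop = FALSE], 2L, nrm[ok], "/")
  QS <- priors$patches[, ok, drop = FALSE] %*%
    Matrix::Diagonal(x = 1 / nrm[ok])
  J <- ncol(A)

  # scale-normalized data covariance
  CY <- tcrossprod(y$data) / T
  sc <- mean(diag(CY))
  CY <- CY / sc

  hE <- -32                      # hyperprior mean (log scale)
  hP <- 1 / 256                  # hyperprior precision
  h <- c(log(0.5), rep(log(0.5 / J), J))
  active <- rep(TRUE, J + 1L)

  fcalc <- function(h, active) {
    lam <- exp(h)
    Sig <- diag(max(lam[1L], noise_floor), d)
    if (any(active[-1L])) {
      Aj <- A[, active[-1L], drop = FALSE]
      Sig <- Sig + Aj %*% (lam[-1L][active[-1L]] * t(Aj))
    }
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) {
      Sig <- Sig + diag(1e-10 * mean(diag(Sig)), d)
      ch <- chol(Sig)
      warning("sensor covariance near singular; jitter added")
    }
    iS <- chol2inv(ch)
    F <- -T / 2 * (2 * sum(log(diag(ch))) + sum(iS * CY)) -
      0.5 * hP * sum((h[active] - hE)^2)
    list(F = F, iS = iS)
  }

  st <- fcalc(h, active)
  trace_F <- st$F
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    iS <- st$iS
    act <- which(active[-1L])
    Aa <- A[, act, drop = FALSE]
    lam <- exp(h)
    W <- iS %*% Aa                       # d x Ja
    ISC <- iS %*% CY
    # gradients
    gA <- colSums(Aa * W)                # a' iS a
    gB <- colSums(W * (CY %*% W))        # a' iS CY iS a
    g1 <- -T / 2 * lam[1L + act] * (gA - gB) - hP * (h[1L + act] - hE)
    g0 <- -T / 2 * lam[1L] * (sum(diag(iS)) - sum(iS * ISC)) -
      hP * (h[1L] - hE)
    g <- c(g0, g1)
    # Fisher information
    B <- crossprod(Aa, W)                # a_j' iS a_k
    Ja <- length(act)
    FI <- matrix(0, Ja + 1L, Ja + 1L)
    FI[-1L, -1L] <- T / 2 * (lam[1L + act] %o% lam[1L + act]) * B^2
    w2 <- colSums(W^2)
    FI[1L, -1L] <- FI[-1L, 1L] <- T / 2 * lam[1L] * lam[1L + act] * w2
    FI[1L, 1L] <- T / 2 * lam[1L]^2 * sum(iS^2)
    diag(FI) <- diag(FI) + hP + 1e-8
    dh <- solve(FI, g)
    dh <- pmin(pmax(dh, -4), 4)          # trust region on log weights
    # backtracking to enforce monotone ascent
    step <- 1
    improved <- FALSE
    idx <- c(1L, 1L + act)
    for (k in 1:16) {
      h_try <- h
      h_try[idx] <- h[idx] + step * dh
      st_try <- fcalc(h_try, active)
      if (st_try$F >= trace_F[length(trace_F)] - 1e-10) {
        h <- h_try
        st <- st_try
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    dF <- st$F - trace_F[length(trace_F)]
    trace_F <- c(trace_F, st$F)
    # greedy pruning of collapsed components (noise term kept)
    lam <- exp(h)
    thresh <- prune_tol * max(lam[-1L][active[-1L]], noise_floor)
    active[-1L] <- active[-1L] & lam[-1L] >= thresh
    if (dF < tol && k == 1L) {
      converged <- TRUE
      break
    }
  }

  lam <- exp(h)
  lam[-1L][!active[-1L]] <- 0
  # conditional mean, undoing the covariance scale (amplitudes ~ sqrt(sc))
  Ys <- y$data / sqrt(sc)
  coef <- (lam[-1L] * t(A)) %*% (st$iS %*% Ys)     # J x T
  xhat <- as.matrix(QS %*% coef) * sqrt(sc)
  hp <- c(noise = lam[1L], stats::setNames(lam[-1L], paste0("patch", seq_len(J))))
  new_source_estimate(xhat, "msp", hp, trace_F[length(trace_F)], trace_F,
                      converged, y$labels, y$fs, y$t0)
}

#' Minimum-norm (Tikhonov) inversion
#'
#' `xhat = M' (M M' + lambda I)^-1 y`, the classic smooth baseline for
#' distributed source reconstruction.
#'
#' @param y an `eeg_signal`.
#' @param head a `head_model`.
#' @param regularization non-negative Tikhonov weight, relative to the
#'   mean eigenvalue of `M M'` (absolute `lambda = regularization *
#'   tr(M M') / d`).
#' @return a `source_estimate` (free energy not defined; `NA`).
#' @export
invert_mn <- function(y, head, regularization = 0.1) {
  stopifnot(inherits(y, "eeg_signal"), inherits(head, "head_model"))
  if (!identical(y$labels, head$electrode_labels))
    stop("signal channels do not match head-model electrodes")
  if (regularization < 0) stop("regularization must be non-negative")
  M <- head$leadfield
  G <- tcrossprod(M)
  lam <- regularization * sum(diag(G)) / nrow(G)
  xhat <- crossprod(M, solve(G + diag(lam, nrow(G)), y$data))
  new_source_estimate(xhat, "mn", c(lambda = lam), NA_real_, numeric(0),
                      TRUE, y$labels, y$fs, y$t0)
}
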