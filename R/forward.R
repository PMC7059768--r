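# Synthetic EEG generation: spherical head-model fixture, windowed
# sinusoid sources, forward projection y = M x + noise, and montage
# reduction.

#' Head model (lead field + geometry)
#'
#' @param leadfield d x n numeric matrix mapping unit source amplitudes
#'   at n cortical vertices to potentials at d electrodes.
#' @param vertex_coords n x 3 vertex positions (mm).
#' @param electrode_labels d channel labels.
#' @param electrode_coords d x 3 electrode positions (mm).
#' @param meta optional list of provenance fields.
#' @return object of class `head_model`.
#' @export
head_model <- function(leadfield, vertex_coords, electrode_labels,
                       electrode_coords, meta = list()) {
  leadfield <- as.matrix(leadfield)
  vertex_coords <- as.matrix(vertex_coords)
  electrode_coords <- as.matrix(electrode_coords)
  d <- nrow(leadfield)
  n <- ncol(leadfield)
  if (!all(is.finite(leadfield))) stop("lead field must be finite")
  if (nrow(vertex_coords) != n || ncol(vertex_coords) != 3L)
    stop("vertex_coords must be n x 3")
  if (length(electrode_labels) != d) stop("one label per lead-field row")
  if (anyDuplicated(electrode_labels)) stop("electrode labels must be unique")
  if (any(rowSums(abs(leadfield)) == 0)) stop("lead field has an all-zero row")
  if (d >= n)
    warning("head model has at least as many electrodes as sources (d >= n)")
  rownames(leadfield) <- electrode_labels
  structure(list(leadfield = leadfield, vertex_coords = vertex_coords,
                 electrode_labels = as.character(electrode_labels),
                 electrode_coords = electrode_coords, meta = meta),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d electrodes x %d vertices\n",
              nrow(x$leadfield), ncol(x$leadfield)))
  invisible(x)
}

# Surface-potential expansion coefficients for a radial dipole inside a
# three-shell concentric-spheres conductor.  Radii are scaled by the
# scalp radius; for each Legendre degree l the interior/exterior
# coefficients of the three shells are solved from potential and
# current continuity plus the no-flux outer boundary.  Returns h_l such
# that V(gamma, b) = sum_l l b^(l-1) h_l P_l(cos gamma) / (4 pi sigma1).
.three_shell_hl <- function(n_terms, radii, sigmas) {
  r <- radii / radii[3L]
  s <- sigmas
  h <- numeric(n_terms)
  for (l in seq_len(n_terms)) {
    A <- matrix(0, 5L, 5L)
    rhs <- numeric(5L)
    # unknowns: A1, A2, B2, A3, B3 ; source term b^..(1/r^(l+1)) in shell 1
    A[1L, ] <- c(r[1L]^l, -r[1L]^l, -r[1L]^(-(l + 1)), 0, 0)
    rhs[1L] <- -r[1L]^(-(l + 1))
    A[2L, ] <- c(s[1L] * l * r[1L]^(l - 1),
                 -s[2L] * l * r[1L]^(l - 1),
                 s[2L] * (l + 1) * r[1L]^(-(l + 2)), 0, 0)
    rhs[2L] <- s[1L] * (l + 1) * r[1L]^(-(l + 2))
    A[3L, ] <- c(0, r[2L]^l, r[2L]^(-(l + 1)), -r[2L]^l, -r[2L]^(-(l + 1)))
    A[4L, ] <- c(0, s[2L] * l * r[2L]^(l - 1),
                 -s[2L] * (l + 1) * r[2L]^(-(l + 2)),
                 -s[3L] * l * r[2L]^(l - 1),
                 s[3L] * (l + 1) * r[2L]^(-(l + 2)))
    A[5L, ] <- c(0, 0, 0, l, -(l + 1))   # dV3/dr = 0 at r = 1
    sol <- solve(A, rhs)
    h[l] <- sol[4L] + sol[5L]            # A3 + B3 at the scalp surface
  }
  h
}

#' Analytic three-shell spherical lead field for radial dipoles
#'
#' Scalp potentials from unit-amplitude radial dipoles via the Legendre
#' series solution for a three-layer (brain, skull, scalp) concentric
#' spheres conductor.  Output units are arbitrary but consistent across
#' electrodes and vertices; each lead-field row is average-referenced.
#'
#' @param vertex_coords n x 3 dipole positions (mm), inside the brain shell.
#' @param electrode_coords d x 3 electrode positions on the scalp (mm).
#' @param radii brain/skull/scalp shell radii in mm.
#' @param sigmas conductivities of the three shells (S/m); the default
#'   1 : 1/80 : 1 ratio is the classic skull attenuation.
#' @param n_terms Legendre series truncation.
#' @return d x n lead-field matrix.
#' @export
three_shell_leadfield <- function(vertex_coords, electrode_coords,
                                  radii = c(80, 85, 92),
                                  sigmas = c(0.33, 0.0042, 0.33),
                                  n_terms = 60L) {
  vertex_coords <- as.matrix(vertex_coords)
  electrode_coords <- as.matrix(electrode_coords)
  b <- sqrt(rowSums(vertex_coords^2)) / radii[3L]
  if (any(b >= radii[1L] / radii[3L]))
    stop("all dipoles must lie inside the brain shell")
  vu <- vertex_coords / sqrt(rowSums(vertex_coords^2))
  eu <- electrode_coords / sqrt(rowSums(electrode_coords^2))
  cosg <- eu %*% t(vu)                     # d x n
  hl <- .three_shell_hl(n_terms, radii, sigmas)
  d <- nrow(cosg)
  n <- ncol(cosg)
  Pprev <- matrix(1, d, n)                 # P_0
  P <- cosg                                # P_1
  M <- matrix(0, d, n)
  for (l in seq_len(n_terms)) {
    coef <- l * b^(l - 1) * hl[l] / (4 * pi * sigmas[1L])
    M <- M + P * rep(coef, each = d)
    Pnext <- ((2 * l + 1) * cosg * P - l * Pprev) / (l + 1)
    Pprev <- P
    P <- Pnext
  }
  sweep(M, 1L, rowMeans(M))                # average reference
}

# Fibonacci lattice on the unit sphere.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic spherical head-model fixture
#'
#' Builds a deterministic stand-in for a realistic cortical head model:
#' `n_vertices` quasi-uniform points on a spherical cortex surface
#' (Fibonacci lattice with seeded angular jitter) and an analytic
#' three-shell lead field for radial dipoles at the requested 10-10
#' montage.  Identical arguments give a bit-identical model.
#'
#' @param n_vertices number of cortical source vertices (>= 50).
#' @param montage character vector of supported 10-10 labels (see
#'   [montage_labels()]).
#' @param seed integer seed for the vertex jitter.
#' @param cortex_radius radius (mm) of the source sphere.
#' @param radii,sigmas,n_terms forwarded to [three_shell_leadfield()].
#' @param jitter_mm tangential jitter SD in mm (vertices stay on the
#'   cortex sphere).
#' @return a `head_model`.
#' @export
synth_headmodel <- function(n_vertices = 500L, montage = montage_labels("full"),
                            seed = 1L, cortex_radius = 72,
                            radii = c(80, 85, 92),
                            sigmas = c(0.33, 0.0042, 0.33),
                            n_terms = 60L, jitter_mm = 2) {
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 50L) stop("n_vertices must be at least 50")
  vu <- .fibonacci_sphere(n_vertices)
  if (jitter_mm > 0) {
    vu <- .with_seed(seed, {
      vj <- vu + matrix(stats::rnorm(3L * n_vertices, sd = jitter_mm / cortex_radius),
                        ncol = 3L)
      vj / sqrt(rowSums(vj^2))
    })
  }
  vertex_coords <- vu * cortex_radius
  epos <- ten_ten_positions(montage) * radii[3L]
  lf <- three_shell_leadfield(vertex_coords, epos, radii, sigmas, n_terms)
  head_model(lf, vertex_coords, montage, epos,
             meta = list(kind = "synthetic-three-shell", seed = seed,
                         cortex_radius = cortex_radius, radii = radii,
                         sigmas = sigmas, jitter_mm = jitter_mm))
}

#' Gaussian-windowed sinusoid source waveform
#'
#' `x(t) = exp(-((t - c) / sigma)^2 / 2) * sin(2 pi f t)` sampled on the
#' uniform grid from `t_start` to `t_end`.
#'
#' @param f sinusoid frequency (Hz, `fs > 2 f`).
#' @param c window center (s).
#' @param sigma Gaussian window width (s); 0.12 s in the packaged
#'   simulation scenarios.
#' @param fs sampling rate (Hz).
#' @param t_start,t_end segment limits (s).
#' @return numeric vector of samples.
#' @export
windowed_sinusoid <- function(f, c, sigma = 0.12, fs = 200,
                              t_start = 0, t_end = 6) {
  stopifnot(t_end > t_start, f > 0, sigma > 0, fs > 2 * f)
  t <- seq(t_start, t_end, by = 1 / fs)
  exp(-0.5 * ((t - c) / sigma)^2) * sin(2 * pi * f * t)
}

.scenario_specs <- function(name) {
  switch(name,
    one = data.frame(vertex = 4000L, f = 10, c = 1),
    three = data.frame(vertex = c(4000L, 5020L, 150L),
                       f = c(20, 12, 4), c = c(1, 3, 5)),
    five = data.frame(vertex = c(4000L, 5020L, 150L, 8100L, 2200L),
                      f = c(20, 15, 10, 6, 2), c = 1:5),
    stop("unknown scenario '", name, "' (use one, three or five)"))
}

#' Simulation scenarios with 1, 3 or 5 active sources
#'
#' Source activity on a 0-6 s segment: Gaussian-windowed sinusoids
#' (sigma = 0.12 s) at brain-rhythm frequencies.  The `one` scenario
#' has a 10 Hz source centered at t = 1 s at vertex 4000; `three` has
#' 20/12/4 Hz sources at t = 1/3/5 s at vertices 4000/5020/150; `five`
#' has 20/15/10/6/2 Hz sources at t = 1..5 s at vertices
#' 4000/5020/150/8100/2200.  Vertex numbers refer to an 8196-vertex
#' cortical mesh; on smaller fixture models they are remapped
#' proportionally.
#'
#' @param name `"one"`, `"three"` or `"five"`.
#' @param head a `head_model`.
#' @param fs sampling rate (Hz).
#' @param t_start,t_end segment limits (s).
#' @param sigma Gaussian window width (s).
#' @return object of class `source_activity`: list with `x` (n x T
#'   amplitude matrix), `specs` (data frame with remapped `vertex`, `f`,
#'   `c`, `sigma`), `fs`, `t0`.
#' @export
make_scenario <- function(name, head, fs = 200, t_start = 0, t_end = 6,
                          sigma = 0.12) {
  stopifnot(inherits(head, "head_model"))
  specs <- .scenario_specs(match.arg(name, c("one", "three", "five")))
  n <- ncol(head$leadfield)
  if (n < 8196L) {
    v <- pmax(1L, as.integer(round(specs$vertex * n / 8196)))
    # keep remapped vertices distinct
    while (anyDuplicated(v)) v[duplicated(v)] <- v[duplicated(v)] + 1L
    specs$vertex <- pmin(v, n)
  }
  if (any(specs$vertex > n)) stop("head model has too few vertices")
  specs$sigma <- sigma
  t <- seq(t_start, t_end, by = 1 / fs)
  x <- matrix(0, n, length(t))
  for (i in seq_len(nrow(specs)))
    x[specs$vertex[i], ] <- windowed_sinusoid(specs$f[i], specs$c[i], sigma,
                                              fs, t_start, t_end)
  structure(list(x = x, specs = specs, fs = fs, t0 = t_start),
            class = "source_activity")
}

#' Noiseless forward projection
#'
#' @param head a `head_model`.
#' @param x a `source_activity` or n x T matrix.
#' @return an `eeg_signal` with `y = M x`.
#' @export
forward_project <- function(head, x) {
  stopifnot(inherits(head, "head_model"))
  fs <- 1
  t0 <- 0
  if (inherits(x, "source_activity")) {
    fs <- x$fs
    t0 <- x$t0
    x <- x$x
  }
  if (nrow(x) != ncol(head$leadfield))
    stop("source rows (", nrow(x), ") do not match lead-field columns (",
         ncol(head$leadfield), ")")
  eeg_signal(head$leadfield %*% x, fs = fs, t0 = t0,
             labels = head$electrode_labels)
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' The noise matrix is scaled so that the realized broadband SNR,
#' `10 log10(P_signal / P_noise)` with powers totalled over all channels
#' and samples, equals `snr_db` exactly.
#'
#' @param y an `eeg_signal` (non-zero).
#' @param snr_db target SNR in dB (the simulation studies use 10 and -5).
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return an `eeg_signal` with attribute `snr_db`.
#' @export
add_noise <- function(y, snr_db, seed = 1L) {
  stopifnot(inherits(y, "eeg_signal"))
  psig <- mean(y$data^2)
  if (psig == 0) stop("SNR is undefined for an all-zero signal")
  eps <- .with_seed(seed, matrix(stats::rnorm(length(y$data)), nrow(y$data)))
  alpha <- sqrt(psig / (mean(eps^2) * 10^(snr_db / 10)))
  out <- eeg_signal(y$data + alpha * eps, fs = y$fs, t0 = y$t0,
                    labels = y$labels)
  attr(out, "snr_db") <- snr_db
  out
}

#' Realized broadband SNR of a noisy signal against its clean version
#'
#' @param clean,noisy `eeg_signal` objects on the same grid.
#' @return realized SNR in dB.
#' @export
realized_snr <- function(clean, noisy) {
  e <- noisy$data - clean$data
  10 * log10(mean(clean$data^2) / mean(e^2))
}

#' Reduce a recording and head model to a montage
#'
#' Subsets (and reorders) the channels of a signal and the rows of the
#' lead field to the requested montage labels.
#'
#' @param y an `eeg_signal`.
#' @param head the matching `head_model`.
#' @param montage character vector of labels, a subset of the head
#'   model's electrodes (e.g. `montage_labels(8)`).
#' @return list with elements `signal` and `head`.
#' @export
reduce_montage <- function(y, head, montage) {
  stopifnot(inherits(y, "eeg_signal"), inherits(head, "head_model"))
  montage <- as.character(montage)
  if (anyDuplicated(montage))
    stop("duplicated label in montage request: ",
         montage[duplicated(montage)][1L])
  unknown <- setdiff(montage, head$electrode_labels)
  if (length(unknown))
    stop("label(s) not in head model: ", paste(unknown, collapse = ", "))
  if (!identical(y$labels, head$electrode_labels))
    stop("signal channels do not match head-model electrodes")
  idx <- match(montage, head$electrode_labels)
  sig <- eeg_signal(y$data[idx, , drop = FALSE], fs = y$fs, t0 = y$t0,
                    labels = montage)
  hm <- head_model(head$leadfield[idx, , drop = FALSE], head$vertex_coords,
                   montage, head$electrode_coords[idx, , drop = FALSE],
                   meta = head$meta)
  list(signal = sig, head = hm)
}

#' Write / read a head model as delimited text
#'
#' Three tab-separated files sharing a prefix: `<prefix>_leadfield.tsv`
#' (first column electrode label), `<prefix>_vertices.tsv` (x, y, z in
#' mm) and `<prefix>_electrodes.tsv` (label, x, y, z).  The same format
#' is used to load externally supplied lead fields.
#'
#' @param head a `head_model`.
#' @param prefix path prefix for the three files.
#' @return `write_headmodel` the prefix, invisibly; `read_headmodel` a
#'   `head_model`.
#' @export
write_headmodel <- function(head, prefix) {
  stopifnot(inherits(head, "head_model"))
  utils::write.table(data.frame(label = head$electrode_labels,
                                head$leadfield, check.names = FALSE),
                     paste0(prefix, "_leadfield.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(head$vertex_coords, paste0(prefix, "_vertices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("x", "y", "z"))
  utils::write.table(data.frame(label = head$electrode_labels,
                                head$electrode_coords),
                     paste0(prefix, "_electrodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("label", "x", "y", "z"))
  invisible(prefix)
}

#' @rdname write_headmodel
#' @export
read_headmodel <- function(prefix) {
  lf <- utils::read.table(paste0(prefix, "_leadfield.tsv"), sep = "\t")
  vx <- utils::read.table(paste0(prefix, "_vertices.tsv"), sep = "\t",
                          header = TRUE)
  el <- utils::read.table(paste0(prefix, "_electrodes.tsv"), sep = "\t",
                          header = TRUE)
  head_model(as.matrix(lf[, -1L]), as.matrix(vx), as.character(lf[[1L]]),
             as.matrix(el[, -1L]), meta = list(kind = "loaded", prefix = prefix))
}
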